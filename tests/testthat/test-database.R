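make_descriptors <- function(sizes, seeds = seq_along(sizes)) {
  lapply(seq_along(sizes), function(i)
    compute_descriptor(make_fixture("random_walk", sizes[i], seed = seeds[i],
                                    entry_id = sprintf("rw%02d", i))))
}

test_that("descriptor distance is Euclidean and version-checked", {
  ds <- make_descriptors(c(10, 10))
  expect_identical(descriptor_distance(ds[[1]], ds[[1]]), 0)
  v <- as.numeric(ds[[1]])
  shifted <- gauss_descriptor(v + c(3, rep(0, 29)), entry_id = "shift")
  expect_equal(descriptor_distance(ds[[1]], shifted), 3, tolerance = 1e-12)
  alien <- gauss_descriptor(v, entry_id = "alien", version = "other-v9")
  expect_error(descriptor_distance(ds[[1]], alien), "version")
})

test_that("descriptor distances satisfy the metric axioms", {
  ds <- make_descriptors(rep(10, 6), seeds = 1:6)
  for (trip in list(c(1, 2, 3), c(2, 4, 5), c(1, 5, 6), c(3, 4, 6))) {
    d12 <- descriptor_distance(ds[[trip[1]]], ds[[trip[2]]])
    d13 <- descriptor_distance(ds[[trip[1]]], ds[[trip[3]]])
    d23 <- descriptor_distance(ds[[trip[2]]], ds[[trip[3]]])
    expect_gte(d12, 0)
    expect_equal(d12, descriptor_distance(ds[[trip[2]]], ds[[trip[1]]]))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("significance is the strict survival fraction of the background", {
  bg <- sort(c(1, 2, 2, 3, 5))
  expect_identical(significance(0, bg), 1)
  expect_identical(significance(10, bg), 0)
  expect_identical(significance(2, bg), 2 / 5)   # strictly greater only
  D <- seq(0, 6, by = 0.25)
  expect_true(all(diff(significance(D, bg)) <= 0))
  expect_error(significance(1, numeric(0)), "empty")
})

test_that("build_database collects valid chains and the all-pairs background", {
  dir <- fixture_pdb_dir(c(10, 12, 14))
  db <- build_database(dir)
  expect_identical(length(db$entries), 3L)
  expect_length(db$background, choose(3, 2))
  expect_identical(db$header$version, pattern_version())
  # deterministic rebuild
  db2 <- build_database(dir)
  expect_identical(db$background, db2$background)
  expect_identical(lapply(db$entries, as.numeric),
                   lapply(db2$entries, as.numeric))
})

test_that("chains of 7 or fewer nucleotides are skipped with a warning", {
  dir <- fixture_pdb_dir(c(10, 12, 14))
  write_backbone_pdb(make_fixture("random_walk", 7, seed = 99,
                                  entry_id = "short"),
                     file.path(dir, "short.pdb"))
  expect_warning(db <- build_database(dir), "more than 7")
  expect_identical(length(db$entries), 3L)
  expect_false("short_A" %in% names(db$entries))
})

test_that("update equals a full rebuild on the union set", {
  dir_a <- fixture_pdb_dir(c(10, 12, 14), seeds = 1:3)
  dir_b <- withr::local_tempdir()
  for (i in 4:5)
    write_backbone_pdb(make_fixture("random_walk", 10 + i, seed = i,
                                    entry_id = sprintf("rw%02d", i)),
                       file.path(dir_b, sprintf("rw%02d.pdb", i)))
  db_a <- build_database(dir_a)
  db_up <- update_database(db_a, dir_b)
  db_full <- build_database(c(dir_a, dir_b))
  expect_identical(sort(names(db_up$entries)), sort(names(db_full$entries)))
  expect_equal(sort(db_up$background), sort(db_full$background),
               tolerance = 1e-12)
  expect_length(db_up$background, choose(5, 2))
})

test_that("updating with an already-present entry leaves the database unchanged", {
  dir <- fixture_pdb_dir(c(10, 12, 14))
  db <- build_database(dir)
  warns <- capture_warnings(db2 <- update_database(db, dir))
  expect_length(warns, 3L)  # one per duplicate entry
  expect_match(warns, "already in database", all = TRUE)
  expect_identical(names(db2$entries), names(db$entries))
  expect_identical(db2$background, db$background)
})

test_that("updating with an invalid chain warns and leaves entries unchanged", {
  dir <- fixture_pdb_dir(c(10, 12))
  db <- build_database(dir)
  short_dir <- withr::local_tempdir()
  write_backbone_pdb(make_fixture("random_walk", 6, seed = 1,
                                  entry_id = "tiny"),
                     file.path(short_dir, "tiny.pdb"))
  expect_warning(db2 <- update_database(db, short_dir), "more than 7")
  expect_identical(names(db2$entries), names(db$entries))
})

test_that("databases persist through the JSON store", {
  dir <- fixture_pdb_dir(c(10, 12, 14))
  path <- withr::local_tempfile(fileext = ".json")
  db <- build_database(dir, path = path)
  back <- read_database(path)
  expect_identical(names(back$entries), names(db$entries))
  expect_equal(back$background, db$background, tolerance = 1e-12)
  expect_identical(back$header$version, db$header$version)
  # refuse databases from a different pattern enumeration
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$header$version <- "other-v9"
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  expect_error(read_database(path), "pattern set")
})

test_that("scan returns correctly thresholded, ordered, truncated hits", {
  dir <- fixture_pdb_dir(c(10, 11, 12, 13, 14, 15), seeds = 1:6)
  db <- build_database(dir)
  q <- db$entries[["rw01_A"]]
  hits <- scan_database(q, db, cutoff = 1e6, top_n = 100)
  # naive reference: full sort of all distances
  naive <- sort(vapply(db$entries, descriptor_distance, numeric(1), d2 = q))
  expect_identical(hits$entry_id[1], "rw01_A")
  expect_identical(hits$distance[1], 0)
  expect_equal(hits$distance, unname(naive), tolerance = 1e-12)
  expect_true(all(diff(hits$distance) >= 0))
  # thresholding drops far entries; truncation respects top_n
  mid <- stats::median(naive)
  hits2 <- scan_database(q, db, cutoff = mid, top_n = 2)
  expect_true(all(hits2$distance <= mid))
  expect_lte(nrow(hits2), 2L)
  expect_identical(hits2$distance, hits$distance[seq_len(nrow(hits2))])
  # cutoff below all distances: empty result, not an error
  strict <- scan_database(db$entries[["rw02_A"]], db, cutoff = 1e-9)
  expect_identical(nrow(strict), 1L)  # the entry itself at distance 0
})

test_that("scan honours the server defaults of cutoff 0.5 and top 10", {
  expect_identical(formals(scan_database)$cutoff, 0.5)
  expect_identical(formals(scan_database)$top_n, 10L)
})

test_that("scan breaks distance ties by entry id", {
  ds <- make_descriptors(c(10, 10), seeds = c(1, 1))
  # two ids with identical descriptors
  db <- build_database(fixture_pdb_dir(c(10, 10, 12), seeds = c(1, 1, 3)))
  q <- db$entries[[1]]
  hits <- scan_database(q, db, cutoff = 1e6, top_n = 10)
  tied <- hits$entry_id[hits$distance < 1e-12]
  expect_identical(tied, sort(tied))
})
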