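test_that("planar zigzag lies exactly in z = 0 with exact step length", {
  z <- make_fixture("planar_zigzag", n_points = 10)
  expect_true(all(z$points[, 3] == 0))
  steps <- sqrt(rowSums(diff(z$points)^2))
  expect_equal(steps, rep(6, 9), tolerance = 1e-12)
})

test_that("random walks have exact 6 A steps and are seed-deterministic", {
  rw1 <- make_fixture("random_walk", n_points = 12, seed = 1)
  rw2 <- make_fixture("random_walk", n_points = 12, seed = 1)
  rw3 <- make_fixture("random_walk", n_points = 12, seed = 2)
  expect_identical(rw1$points, rw2$points)
  expect_gt(max(abs(rw1$points - rw3$points)), 1)
  steps <- sqrt(rowSums(diff(rw1$points)^2))
  expect_equal(steps, rep(6, 11), tolerance = 1e-9)
})

test_that("helix follows the prescribed radius and rise", {
  h <- make_fixture("helix", n_points = 20, radius = 9.4, rise = 2.81)
  expect_equal(sqrt(rowSums(h$points[, 1:2]^2)), rep(9.4, 20))
  expect_equal(diff(h$points[, 3]), rep(2.81, 19))
})

test_that("mirror pair is an exact z-reflection", {
  mp <- make_fixture("mirror_pair", n_points = 15, seed = 3)
  expect_equal(mp$mirrored$points[, 1:2], mp$original$points[, 1:2])
  expect_equal(mp$mirrored$points[, 3], -mp$original$points[, 3])
})

test_that("perturbed copies stay near the base curve", {
  h <- make_fixture("helix", n_points = 20)
  p <- make_fixture("perturbed_copy", n_points = 20, seed = 5, sigma = 0.3)
  rms <- sqrt(mean((p$points - h$points)^2))
  expect_lt(rms, 1)
  expect_gt(rms, 0.05)
})

test_that("fixtures pass validate_curve iff they have at least 8 points", {
  for (n in c(8L, 12L)) {
    expect_s3_class(validate_curve(make_fixture("random_walk", n, seed = 1)),
                    "backbone_curve")
  }
  for (n in c(2L, 7L)) {
    expect_error(validate_curve(make_fixture("planar_zigzag", n)),
                 "more than 7")
  }
})

test_that("PDB write/parse round trip preserves coordinates to 3 decimals", {
  rw <- make_fixture("random_walk", n_points = 10, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(rw, path)
  back <- read_backbone(path)
  expect_equal(back$points, round(rw$points, 3), tolerance = 1e-9)
  expect_identical(n_points(back), 10L)
})

test_that("multi-model fixture writes parse back model by model", {
  curves <- list(make_fixture("helix", 10),
                 make_fixture("random_walk", 10, seed = 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_backbone_pdb(curves, path)
  m1 <- read_backbone(path, model = 1)
  m2 <- read_backbone(path, model = 2)
  expect_equal(m1$points, round(curves[[1]]$points, 3), tolerance = 1e-9)
  expect_equal(m2$points, round(curves[[2]]$points, 3), tolerance = 1e-9)
})

test_that("invalid fixture specifications are rejected", {
  expect_error(make_fixture("random_walk", n_points = 1), "at least 2")
  expect_error(make_fixture("helix", radius = -1), "invalid")
  expect_error(make_fixture("perturbed_copy", sigma = -0.1), "invalid")
})
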