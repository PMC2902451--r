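test_that("a hand-written three-residue file reads back in order", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(c(atom_line(1, 1, 0, 0, 0),
                    atom_line(2, 2, 1, 0, 0),
                    atom_line(3, 3, 1, 1, 0),
                    "END"), path)
  cur <- read_backbone(path)
  expect_equal(cur$points,
               rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_identical(cur$residue_labels, c("U1", "U2", "U3"))
})

test_that("only the first model is used unless another is requested", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(c("MODEL        1",
                    atom_line(1, 1, 0, 0, 0),
                    atom_line(2, 2, 1, 0, 0),
                    atom_line(3, 3, 1, 1, 0),
                    "ENDMDL",
                    "MODEL        2",
                    atom_line(1, 1, 9, 9, 9),
                    atom_line(2, 2, 8, 9, 9),
                    atom_line(3, 3, 8, 8, 9),
                    "ENDMDL",
                    "END"), path)
  expect_equal(read_backbone(path)$points[1, ], c(0, 0, 0))
  expect_equal(read_backbone(path, model = 2)$points[1, ], c(9, 9, 9))
  expect_error(read_backbone(path, model = 3), "model")
})

test_that("nucleotides without a P atom are bridged by one segment", {
  path <- withr::local_tempfile(fileext = ".pdb")
  # residue 2 carries only a C4' atom: its neighbours get joined directly
  write_pdb_lines(c(atom_line(1, 1, 0, 0, 0),
                    atom_line(2, 2, 3, 0, 0, elety = " C4'"),
                    atom_line(3, 3, 6, 0, 1),
                    "END"), path)
  cur <- read_backbone(path)
  expect_identical(n_points(cur), 2L)
  expect_equal(cur$points, rbind(c(0, 0, 0), c(6, 0, 1)))
})

test_that("chain selection defaults to the first chain with P atoms", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(c(atom_line(1, 1, 0, 0, 0, chain = "B"),
                    atom_line(2, 2, 6, 0, 0, chain = "B"),
                    atom_line(3, 1, 0, 5, 5, chain = "C"),
                    atom_line(4, 2, 6, 5, 5, chain = "C"),
                    "END"), path)
  expect_equal(read_backbone(path)$points[1, ], c(0, 0, 0))
  expect_equal(read_backbone(path, chain = "C")$points[1, ], c(0, 5, 5))
  expect_error(read_backbone(path, chain = "Z"), "chain 'Z'")
})

test_that("altloc B records and non-polymer P-bearing residues are excluded", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(c(atom_line(1, 1, 0, 0, 0, alt = "A"),
                    atom_line(2, 1, 9, 9, 9, alt = "B"),
                    atom_line(3, 2, 6, 0, 0),
                    # modified nucleotide inside the chain: kept
                    atom_line(4, 3, 12, 0, 0, record = "HETATM",
                              resid = "1MA"),
                    # free phosphate ion: excluded
                    atom_line(5, 90, 40, 40, 40, record = "HETATM",
                              resid = "PO4"),
                    "END"), path)
  cur <- read_backbone(path)
  expect_identical(n_points(cur), 3L)
  expect_equal(cur$points[1, ], c(0, 0, 0))
  expect_equal(cur$points[3, ], c(12, 0, 0))
})

test_that("missing files and P-free structures raise errors", {
  expect_error(read_backbone(file.path(tempdir(), "nope.pdb")), "not found")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_lines(c(atom_line(1, 1, 0, 0, 0, elety = " C4'"),
                    atom_line(2, 2, 6, 0, 0, elety = " C4'"),
                    "END"), path)
  expect_error(read_backbone(path), "no phosphorus")
})

test_that("the minimum-length rule accepts 8 points and rejects 7 or fewer", {
  expect_s3_class(validate_curve(make_fixture("random_walk", 8, seed = 1)),
                  "backbone_curve")
  expect_error(validate_curve(make_fixture("random_walk", 7, seed = 1)),
               "more than 7")
  expect_error(validate_curve(make_fixture("planar_zigzag", 2)),
               "more than 7")
})

test_that("backbone_curve enforces finiteness and distinct consecutive points", {
  expect_error(backbone_curve(rbind(c(0, 0, 0), c(0, 0, NA))), "finite")
  expect_error(backbone_curve(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "zero-length")
  expect_error(backbone_curve(matrix(0, 2, 2)), "n x 3")
})
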