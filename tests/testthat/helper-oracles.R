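# Independent oracles and small utilities shared across the test files.

# Monte-Carlo oracle for the signed crossing probability of two segments:
# project both segments along many uniformly random directions, test for a
# proper 2D crossing and attach the right-hand-rule sign from the 3D
# geometry at the crossing.  Entirely independent of the closed-form
# solid-angle kernel it is used to check.
mc_segment_writhe <- function(p1, p2, p3, p4, n_dirs = 2e5, seed = 1) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n_dirs), ncol = 3)
  d <- d / sqrt(rowSums(d^2))
  ref <- matrix(rep(c(1, 0, 0), each = n_dirs), ncol = 3)
  swap <- abs(d[, 1]) > 0.9
  ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  u <- cbind(d[, 2] * ref[, 3] - d[, 3] * ref[, 2],
             d[, 3] * ref[, 1] - d[, 1] * ref[, 3],
             d[, 1] * ref[, 2] - d[, 2] * ref[, 1])
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(d[, 2] * u[, 3] - d[, 3] * u[, 2],
             d[, 3] * u[, 1] - d[, 1] * u[, 3],
             d[, 1] * u[, 2] - d[, 2] * u[, 1])
  pr <- function(p) cbind(u %*% p, v %*% p)
  a1 <- pr(p1); a2 <- pr(p2); a3 <- pr(p3); a4 <- pr(p4)
  ori <- function(a, b, c)
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
    (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  crossing <- (ori(a1, a2, a3) * ori(a1, a2, a4) < 0) &
              (ori(a3, a4, a1) * ori(a3, a4, a2) < 0)
  t1 <- p2 - p1; t2 <- p4 - p3
  cr <- c(t1[2] * t2[3] - t1[3] * t2[2],
          t1[3] * t2[1] - t1[1] * t2[3],
          t1[1] * t2[2] - t1[2] * t2[1])
  # 3D points that project onto the crossing; their offset along the view
  # direction decides which strand is on top (right-hand rule)
  s <- ori(a3, a4, a1) / (ori(a3, a4, a1) - ori(a3, a4, a2))
  tt <- ori(a1, a2, a3) / (ori(a1, a2, a3) - ori(a1, a2, a4))
  x <- outer(rep(1, n_dirs), p1) + s %o% t1
  y <- outer(rep(1, n_dirs), p3) + tt %o% t2
  h <- rowSums((x - y) * d)
  eps <- sign(c(d %*% cr)) * sign(h)
  val <- ifelse(crossing, eps, 0)
  c(mean = mean(val), se = stats::sd(val) / sqrt(n_dirs))
}

# Expected sign flip of each of the 29 invariants under mirror reflection:
# -1 when the pattern has an odd number of plain (non-absolute) W chords.
mirror_parity <- function() {
  pats <- chord_patterns()
  ifelse((pats$order - pats$n_abs) %% 2L == 1L, -1, 1)
}

# Random symmetric writhe-like matrix (zero diagonal and first
# off-diagonals, entries in [-1, 1]) for invariant algebra tests.
random_writhe_like <- function(n, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i + 1L) W[i, j] <- W[j, i] <- runif(1, -0.5, 0.5)
  W
}

# Directory of synthetic PDB fixtures: `sizes` random walks (plus an
# optional too-short chain), returns the directory path.
fixture_pdb_dir <- function(sizes, seeds = seq_along(sizes), dir = NULL) {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (i in seq_along(sizes)) {
    id <- sprintf("rw%02d", i)
    write_backbone_pdb(
      make_fixture("random_walk", n_points = sizes[i], seed = seeds[i],
                   entry_id = id),
      file.path(dir, paste0(id, ".pdb")))
  }
  dir
}

# Hand-written PDB text fixtures (raw records, independent of the
# package's own writer).
write_pdb_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

atom_line <- function(serial, resno, x, y, z, elety = " P  ", chain = "A",
                      resid = "  U", record = "ATOM  ", alt = " ") {
  sprintf("%s%5d %s%s%s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
          record, serial, elety, alt, resid, chain, resno, x, y, z)
}
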