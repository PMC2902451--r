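# The 29 Gauss integrals and the 30-dimensional descriptor.

as_writhe_matrix <- function(W) {
  W <- unclass(as.matrix(W))
  if (nrow(W) != ncol(W)) stop("writhe matrix must be square")
  W
}

#' Gauss integrals of a writhe matrix
#'
#' Evaluates, for every chord pattern, the sum over strictly increasing
#' segment-index tuples i1 < ... < i2k of the product over chords (a, b) of
#' `W[ia, ib]` (or `|W[ia, ib]|` for absolute-value chords).  All 29
#' invariants are computed together by prefix-sum recurrences in O(n^3)
#' time overall; results are identical (to rounding) to the brute-force
#' tuple enumeration of [brute_force_invariant()].
#'
#' @param W A `writhe_matrix` (or plain symmetric matrix).
#' @return Named numeric vector of length 29 in the fixed
#'   [chord_patterns()] order.
#' @export
gauss_invariants <- function(W) {
  W <- as_writhe_matrix(W)
  setNames(cpp_gauss_invariants(W), descriptor_names()[-1L])
}

#' Single Gauss integral for one chord pattern
#'
#' @param W A writhe matrix.
#' @param pattern Pattern index (1-29), pattern name (see
#'   [chord_patterns()]), or a pattern list element.
#' @return The invariant value (scalar).
#' @export
invariant <- function(W, pattern) {
  idx <- resolve_pattern(pattern)
  unname(gauss_invariants(W)[idx])
}

resolve_pattern <- function(pattern) {
  pats <- pattern_list()
  if (is.list(pattern)) {
    nm <- pattern_name(pattern$pairs, pattern$abs_flags)
    idx <- match(nm, vapply(pats, `[[`, character(1), "name"))
  } else if (is.character(pattern)) {
    idx <- match(pattern, vapply(pats, `[[`, character(1), "name"))
  } else {
    idx <- as.integer(pattern)
    if (is.na(idx) || idx < 1L || idx > length(pats)) idx <- NA_integer_
  }
  if (is.na(idx)) stop("unknown chord pattern")
  idx
}

#' Brute-force Gauss integral by literal tuple enumeration
#'
#' Reference oracle for [gauss_invariants()]: enumerates every strictly
#' increasing 2k-tuple of segment indices with `utils::combn()` and sums
#' the chord products directly.  Cost is O(n^(2k)), so matrices are limited
#' to 16 segments.
#'
#' @param W A writhe matrix (<= 16 segments).
#' @param pattern As in [invariant()].
#' @return The invariant value (scalar).
#' @export
brute_force_invariant <- function(W, pattern) {
  W <- as_writhe_matrix(W)
  n <- nrow(W)
  if (n > 16L)
    stop("brute-force enumeration refused for more than 16 segments")
  p <- pattern_list()[[resolve_pattern(pattern)]]
  k <- p$order
  if (n < 2L * k) return(0)
  tuples <- utils::combn(n, 2L * k)
  total <- 0
  for (col in seq_len(ncol(tuples))) {
    tup <- tuples[, col]
    prod_val <- 1
    for (ch in seq_len(k)) {
      w <- W[tup[p$pairs[1L, ch]], tup[p$pairs[2L, ch]]]
      if (p$abs_flags[ch]) w <- abs(w)
      prod_val <- prod_val * w
    }
    total <- total + prod_val
  }
  total
}

#' Compute the 30-dimensional Gauss-integral descriptor of a chain
#'
#' Component 1 is the backbone-length measure (by default the number of P
#' atoms N; optionally the arc length in Angstrom); components 2-30 are the
#' 29 Gauss integrals of orders 1-3 in the fixed [chord_patterns()] order.
#' The descriptor is invariant under rigid motions and uniform scaling of
#' the curve (the length component under scaling only when counting atoms),
#' and is the shape signature used for all database comparisons.
#'
#' @param curve A [backbone_curve()] with more than 7 points.
#' @param length_measure `"count"` (number of P atoms, the default) or
#'   `"arc"` (backbone arc length in Angstrom).
#' @return An object of class `gauss_descriptor`: a named numeric
#'   30-vector with attributes `entry_id` and `version`.
#' @export
#' @examples
#' helix <- make_fixture("helix", n_points = 20)
#' compute_descriptor(helix)
compute_descriptor <- function(curve, length_measure = c("count", "arc")) {
  length_measure <- match.arg(length_measure)
  curve <- validate_curve(curve)
  W <- cpp_writhe_matrix(curve$points)
  len <- if (length_measure == "count") n_points(curve) else arc_length(curve)
  v <- c(len, cpp_gauss_invariants(W))
  gauss_descriptor(v, entry_id = curve$entry_id)
}

#' Construct a Gauss descriptor from raw components
#'
#' @param vector Numeric vector of 30 finite components.
#' @param entry_id Text label of the chain.
#' @param version Pattern-enumeration version tag; must match
#'   [pattern_version()] of this build.
#' @return A `gauss_descriptor`.
#' @export
gauss_descriptor <- function(vector, entry_id = "query",
                             version = pattern_version()) {
  vector <- as.numeric(vector)
  if (length(vector) != 30L)
    stop("a Gauss descriptor has exactly 30 components")
  if (!all(is.finite(vector)))
    stop("non-finite descriptor components")
  structure(setNames(vector, descriptor_names()),
            entry_id = as.character(entry_id)[1L],
            version = version,
            class = "gauss_descriptor")
}

#' @export
print.gauss_descriptor <- function(x, digits = 4, ...) {
  cat(sprintf("Gauss descriptor '%s' (pattern set %s)\n",
              attr(x, "entry_id"), attr(x, "version")))
  cat(sprintf("  length measure: %g;  writhe I12 = %.*f;  ACN I|12| = %.*f\n",
              x[[1L]], digits, x[[2L]], digits, x[[3L]]))
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(signif(v, digits), ...)
  invisible(x)
}

#' Export descriptors as tab-separated text
#'
#' One line per entry: `entry_id` followed by the 30 components at full
#' precision; a `#`-prefixed header records the pattern version and the
#' component names.  The format round-trips through [read_descriptors()].
#'
#' @param descriptors A `gauss_descriptor` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  if (inherits(descriptors, "gauss_descriptor"))
    descriptors <- list(descriptors)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# rnagauss descriptors; pattern_version=",
                      pattern_version()),
               paste0("# entry_id\t", paste(descriptor_names(),
                                            collapse = "\t"))), con)
  for (d in descriptors) {
    stopifnot(inherits(d, "gauss_descriptor"))
    writeLines(paste(c(attr(d, "entry_id"),
                       sprintf("%.17g", as.numeric(d))), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read descriptors from the tab-separated interchange format
#'
#' @param path File written by [write_descriptors()].
#' @return A named list of `gauss_descriptor` objects.
#' @export
read_descriptors <- function(path) {
  lines <- readLines(path)
  hdr <- grep("pattern_version=", lines, value = TRUE)
  version <- if (length(hdr))
    sub(".*pattern_version=", "", hdr[1L]) else pattern_version()
  if (version != pattern_version())
    stop(sprintf("descriptor file uses pattern set '%s'; this build is '%s'",
                 version, pattern_version()))
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    d <- gauss_descriptor(as.numeric(parts[-1L]), entry_id = parts[1L],
                          version = version)
    out[[parts[1L]]] <- d
  }
  out
}
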