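# Segment writhe and the pairwise writhe matrix.

#' Signed crossing probability of two line segments
#'
#' The probability of seeing the two segments' projections cross, averaged
#' over all projection directions uniformly distributed on the sphere, with
#' the sign of the crossing given by the right-hand rule.  Computed in
#' closed form as the signed area of the spherical quadrilateral spanned by
#' the four inter-endpoint directions, divided by 2*pi (each crossing
#' occurs for two antipodal caps of directions).  The value lies in
#' \[-1, 1\]; coplanar configurations and segments sharing an endpoint give
#' exactly 0.
#'
#' @param a_start,a_end Endpoints (3-vectors, Angstrom) of the first segment.
#' @param b_start,b_end Endpoints of the second segment.
#' @return A dimensionless signed probability in \[-1, 1\].
#' @export
#' @examples
#' segment_writhe(c(0, 0, 0), c(1, 0, 0), c(0.5, -0.5, 0.5), c(0.5, 0.5, 0.5))
segment_writhe <- function(a_start, a_end, b_start, b_end) {
  cpp_segment_writhe(as.numeric(a_start), as.numeric(a_end),
                     as.numeric(b_start), as.numeric(b_end))
}

#' Pairwise segment-writhe matrix of a backbone curve
#'
#' Entry (i, j) is [segment_writhe()] of backbone segments i and j (segment
#' i joins P atoms i and i+1).  The matrix is symmetric with zeros on the
#' diagonal and first off-diagonals: adjacent segments share an endpoint,
#' so their average signed crossing vanishes.
#'
#' @param curve A validated [backbone_curve()] (>= 8 points).
#' @return An object of class `writhe_matrix`: the (N-1) x (N-1) numeric
#'   matrix with attribute `entry_id`.
#' @export
writhe_matrix <- function(curve) {
  curve <- validate_curve(curve)
  W <- cpp_writhe_matrix(curve$points)
  attr(W, "entry_id") <- curve$entry_id
  class(W) <- c("writhe_matrix", class(W))
  W
}

#' @export
print.writhe_matrix <- function(x, ...) {
  cat(sprintf("Writhe matrix of '%s': %d segments, writhe %.4f, ACN %.4f\n",
              attr(x, "entry_id") %||% "?", nrow(x),
              sum(x[upper.tri(x)]), sum(abs(x[upper.tri(x)]))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
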