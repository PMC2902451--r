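# Synthetic backbone curves with known topological properties.
#
# Every other module is testable offline with these: a planar zigzag (all
# Gauss integrals exactly zero), an A-form-like helix, a fixed-step random
# walk, mirror pairs (sign flips of chiral invariants) and jittered copies
# (cluster structure for ROC tests).

#' Generate a synthetic backbone curve
#'
#' Deterministic for a given `seed`.  Kinds:
#' \describe{
#'   \item{`planar_zigzag`}{Points alternate in the z = 0 plane with exact
#'     P-P step `step`; a planar curve, so all 29 Gauss integrals vanish.}
#'   \item{`helix`}{Right-handed helix (r cos kt, r sin kt, ct) with
#'     A-form-like defaults: radius 9.4 A, twist 32.7 deg and rise 2.81 A
#'     per residue.}
#'   \item{`random_walk`}{Isotropic random walk with exact step length
#'     `step` (6 A, a typical P-P distance); not self-avoiding.}
#'   \item{`mirror_pair`}{A list of two curves: a seeded random walk and
#'     its reflection through the z = 0 plane.}
#'   \item{`perturbed_copy`}{`base` (default: the helix) with isotropic
#'     Gaussian jitter of standard deviation `sigma` added to every
#'     coordinate.}
#' }
#'
#' @param kind One of `"planar_zigzag"`, `"helix"`, `"random_walk"`,
#'   `"mirror_pair"`, `"perturbed_copy"`.
#' @param n_points Number of P atoms (>= 8 to pass [validate_curve()]).
#' @param seed Integer seed for the stochastic kinds.
#' @param step Step length in Angstrom for zigzag and random walk.
#' @param radius,twist,rise Helix geometry (Angstrom, degrees, Angstrom).
#' @param sigma Jitter standard deviation in Angstrom for
#'   `perturbed_copy`.
#' @param base Optional `backbone_curve` to perturb.
#' @param entry_id Label; defaults to the kind.
#' @return A [backbone_curve()], or a list of two for `"mirror_pair"`.
#' @export
#' @examples
#' make_fixture("helix", n_points = 20)
make_fixture <- function(kind = c("planar_zigzag", "helix", "random_walk",
                                  "mirror_pair", "perturbed_copy"),
                         n_points = 20L, seed = 1L, step = 6,
                         radius = 9.4, twist = 32.7, rise = 2.81,
                         sigma = 0.3, base = NULL, entry_id = NULL) {
  kind <- match.arg(kind)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be at least 2")
  if (step <= 0 || radius <= 0 || sigma < 0) stop("invalid fixture geometry")
  if (is.null(entry_id)) entry_id <- kind
  pts <- switch(kind,
    planar_zigzag = {
      # 3-4-5 proportions keep the step exactly `step` in the z = 0 plane
      cbind(x = (seq_len(n_points) - 1L) * 0.8 * step,
            y = (seq_len(n_points) %% 2L) * 0.6 * step,
            z = 0)
    },
    helix = {
      t <- seq_len(n_points) - 1L
      ang <- t * twist * pi / 180
      cbind(radius * cos(ang), radius * sin(ang), rise * t)
    },
    random_walk = {
      set.seed(seed)
      dirs <- matrix(rnorm(3L * (n_points - 1L)), ncol = 3L)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(rbind(c(0, 0, 0), dirs * step), 2L, cumsum)
    },
    mirror_pair = {
      cur <- make_fixture("random_walk", n_points = n_points, seed = seed,
                          step = step, entry_id = paste0(entry_id, "_plus"))
      return(list(original = cur,
                  mirrored = reflect_curve(
                    cur, entry_id = paste0(entry_id, "_minus"))))
    },
    perturbed_copy = {
      if (is.null(base))
        base <- make_fixture("helix", n_points = n_points, radius = radius,
                             twist = twist, rise = rise)
      set.seed(seed)
      base$points + matrix(rnorm(length(base$points), sd = sigma),
                           ncol = 3L)
    })
  backbone_curve(pts, entry_id = entry_id)
}

#' Reflect a backbone curve through the z = 0 plane
#'
#' Mirror image of the curve.  Under reflection every writhe factor W
#' changes sign, so Gauss integrals with an odd number of plain-W chords
#' flip sign while all-absolute invariants are unchanged.
#'
#' @param curve A [backbone_curve()].
#' @param entry_id Label of the mirrored curve.
#' @return A [backbone_curve()].
#' @export
reflect_curve <- function(curve, entry_id = paste0(curve$entry_id, "_mirror")) {
  p <- curve$points
  p[, 3L] <- -p[, 3L]
  backbone_curve(p, curve$residue_labels, entry_id)
}

#' Apply a rigid motion to a backbone curve
#'
#' @param curve A [backbone_curve()].
#' @param rotation 3 x 3 rotation matrix (default: identity).
#' @param translation Length-3 offset (default: none).
#' @param entry_id Label of the transformed curve.
#' @return A [backbone_curve()].
#' @export
transform_curve <- function(curve, rotation = diag(3), translation = c(0, 0, 0),
                            entry_id = curve$entry_id) {
  p <- curve$points %*% t(rotation)
  p <- sweep(p, 2L, -as.numeric(translation))
  backbone_curve(p, curve$residue_labels, entry_id)
}

#' Random rotation matrix
#'
#' Uniform (Haar) random rotation, for invariance testing.
#'
#' @param seed Optional integer seed.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
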