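# Extraction of P-atom backbone traces from PDB files.
#
# The polygonal curve through the phosphorus atoms (P1, P2, ..., PN) of one
# RNA chain is the sole structural input of the method.  bio3d does the PDB
# parsing; this module selects model/chain, filters to P atoms and wraps the
# result in a `backbone_curve` object.

# P-containing residues that are never part of the polymer backbone
# (free phosphate/nucleotide ligands, cofactors) plus solvent.
.nonpolymer_resid <- c(
  "HOH", "DOD", "PO4", "PO3", "2HP", "PI", "SO4",
  "ATP", "ADP", "AMP", "GTP", "GDP", "GMP", "CTP", "CDP", "C5P",
  "UTP", "UDP", "U5P", "TTP", "NAD", "NDP", "FAD", "FMN", "SAM", "COA")

#' Construct a backbone curve
#'
#' An ordered polygonal space curve through the phosphorus atoms of one RNA
#' chain: one 3D point per observed nucleotide, in chain order, coordinates
#' in Angstrom.
#'
#' @param points Numeric n x 3 matrix of P-atom coordinates.
#' @param residue_labels Optional character vector parallel to `points`
#'   (residue name + number); defaults to the point index.
#' @param entry_id Text label for the chain (conventionally pdbid_chain).
#' @return An object of class `backbone_curve`.
#' @export
#' @examples
#' backbone_curve(cbind(0:9 * 4.8, rep(c(0, 3.6), 5), 0), entry_id = "zigzag")
backbone_curve <- function(points, residue_labels = NULL, entry_id = "curve") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L)
    stop("`points` must be an n x 3 coordinate matrix")
  if (nrow(points) < 2L)
    stop("a backbone curve needs at least two points")
  if (!all(is.finite(points)))
    stop("non-finite coordinates in backbone curve")
  if (is.null(residue_labels))
    residue_labels <- as.character(seq_len(nrow(points)))
  if (length(residue_labels) != nrow(points))
    stop("`residue_labels` must parallel `points`")
  steps <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                           points[-nrow(points), , drop = FALSE])^2))
  if (any(steps < 1e-9))
    stop("zero-length segment: consecutive P atoms coincide")
  structure(list(entry_id = as.character(entry_id)[1L],
                 points = unname(points),
                 residue_labels = as.character(residue_labels)),
            class = "backbone_curve")
}

#' @export
print.backbone_curve <- function(x, ...) {
  cat(sprintf("Backbone curve '%s': %d P atoms (%d segments)\n",
              x$entry_id, nrow(x$points), nrow(x$points) - 1L))
  cat(sprintf("  arc length %.1f A, mean P-P step %.2f A\n",
              arc_length(x), arc_length(x) / (nrow(x$points) - 1L)))
  invisible(x)
}

#' Number of points of a backbone curve
#' @param x A `backbone_curve`.
#' @return Integer count of P atoms.
#' @export
n_points <- function(x) nrow(x$points)

#' Arc length of a backbone curve
#' @param x A `backbone_curve`.
#' @return Total polygon length in Angstrom.
#' @export
arc_length <- function(x) {
  p <- x$points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Read the P-atom backbone of one RNA chain from a PDB file
#'
#' Extracts the phosphorus-atom trace of the selected (or first) chain of
#' the selected (or first) model, in file order.  Nucleotides lacking a P
#' atom are skipped and the gap is bridged by a straight segment between the
#' neighbouring observed P atoms, so the curve stays one connected polygon.
#' Alternate locations other than ' '/'A' are ignored; modified nucleotides
#' carrying a P atom are kept; waters, ions and P-containing ligands
#' (e.g. free phosphate, NTPs, cofactors) are excluded.
#'
#' @param pdb_path Path to a PDB-format file.
#' @param chain Optional chain identifier.  Default: the first chain (in
#'   file order) containing at least one P atom.
#' @param model Model ordinal, >= 1.  Default: first model.
#' @param entry_id Label for the curve; defaults to `<file stem>_<chain>`.
#' @return A [backbone_curve()].
#' @seealso [validate_curve()] for the minimum-length rule.
#' @export
read_backbone <- function(pdb_path, chain = NULL, model = 1L,
                          entry_id = NULL) {
  if (!file.exists(pdb_path))
    stop("PDB file not found: ", pdb_path)
  model <- as.integer(model)
  if (is.na(model) || model < 1L)
    stop("`model` must be a positive integer")
  pdb <- suppressWarnings(
    bio3d::read.pdb(pdb_path, multi = TRUE, verbose = FALSE))
  atoms <- pdb$atom
  nmodel <- nrow(pdb$xyz)
  if (model > nmodel)
    stop(sprintf("model %d requested but file has %d model(s)", model, nmodel))

  is_p <- trimws(atoms$elety) == "P" &
    (is.na(atoms$alt) | atoms$alt %in% c("", " ", "A")) &
    !(trimws(atoms$resid) %in% .nonpolymer_resid)
  if (!any(is_p))
    stop("no phosphorus backbone atoms found in ", pdb_path)

  chains_avail <- unique(atoms$chain[is_p])
  if (is.null(chain)) {
    chain <- chains_avail[1L]
  } else if (!(chain %in% chains_avail)) {
    stop(sprintf("chain '%s' with P atoms not present (available: %s)",
                 chain, paste(chains_avail, collapse = ", ")))
  }
  sel <- which(is_p & atoms$chain %in% chain)
  # one P per residue: keep the first occurrence in file order
  reskey <- paste(atoms$resno[sel], atoms$insert[sel], sep = "_")
  sel <- sel[!duplicated(reskey)]

  xyz_row <- pdb$xyz[model, , drop = TRUE]
  idx <- rep((sel - 1L) * 3L, each = 3L) + seq_len(3L)
  pts <- matrix(xyz_row[idx], ncol = 3L, byrow = TRUE)
  labels <- paste0(trimws(atoms$resid[sel]), atoms$resno[sel])
  if (is.null(entry_id)) {
    stem <- tools::file_path_sans_ext(basename(pdb_path))
    entry_id <- paste0(stem, "_", ifelse(is.na(chain), "?", chain))
  }
  backbone_curve(pts, labels, entry_id)
}

#' Enforce the minimum chain length of the descriptor
#'
#' The third-order Gauss integrals superpose six backbone segments, so the
#' descriptor is defined only for chains with more than 7 nucleotides
#' (i.e. at least 8 P atoms, giving at least 7 segments).
#'
#' @param curve A [backbone_curve()].
#' @return The curve, unchanged, if it has >= 8 points; otherwise an error.
#' @export
validate_curve <- function(curve) {
  stopifnot(inherits(curve, "backbone_curve"))
  if (n_points(curve) <= 7L)
    stop(sprintf(paste0("chain '%s' has %d P atoms; the Gauss-integral ",
                        "descriptor requires more than 7 nucleotides"),
                 curve$entry_id, n_points(curve)))
  curve
}

#' Write a backbone curve as a minimal PDB file
#'
#' One `ATOM` record per residue holding the P atom; lists of curves are
#' written as consecutive `MODEL`/`ENDMDL` blocks.  The output round-trips
#' through [read_backbone()] at PDB coordinate precision (3 decimals).
#'
#' @param curve A [backbone_curve()] or a list of them (multi-model).
#' @param path Output file path.
#' @param chain Chain identifier to write (default `"A"`).
#' @return `path`, invisibly.
#' @export
write_backbone_pdb <- function(curve, path, chain = "A") {
  curves <- if (inherits(curve, "backbone_curve")) list(curve) else curve
  stopifnot(all(vapply(curves, inherits, logical(1), "backbone_curve")))
  multi <- length(curves) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(curves)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    p <- curves[[m]]$points
    lines <- sprintf(
      "ATOM  %5d  P     U %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           P",
      seq_len(nrow(p)), chain, seq_len(nrow(p)), p[, 1], p[, 2], p[, 3])
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
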