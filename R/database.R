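# Descriptor distance, empirical significance, and the descriptor database.

#' Euclidean distance between two Gauss descriptors
#'
#' The structural distance D of the method: the Euclidean norm of the
#' difference of the two 30-dimensional vectors.  Descriptors must come
#' from the same pattern enumeration (version tags must match).
#'
#' @param d1,d2 `gauss_descriptor` objects.
#' @return Non-negative scalar distance.
#' @export
descriptor_distance <- function(d1, d2) {
  stopifnot(inherits(d1, "gauss_descriptor"), inherits(d2, "gauss_descriptor"))
  if (!identical(attr(d1, "version"), attr(d2, "version")))
    stop("descriptor pattern versions differ; recompute with one build")
  sqrt(sum((as.numeric(d1) - as.numeric(d2))^2))
}

#' Empirical significance of a distance
#'
#' The probability pD of observing a distance larger than `D` among the
#' all-pairs background distances of the database: the strict survival
#' fraction `#(background > D) / background_size`.  A small complement
#' 1 - pD flags an uncommonly similar pair.
#'
#' @param D Non-negative distance (vectorised).
#' @param db A `gauss_db` from [build_database()], or a numeric vector of
#'   background distances.
#' @return pD in \[0, 1\], one value per element of `D`.
#' @export
significance <- function(D, db) {
  bg <- if (inherits(db, "gauss_db")) db$background else as.numeric(db)
  if (length(bg) == 0L) stop("empty background distance distribution")
  # background is sorted: strict survival via binary search
  vapply(as.numeric(D), function(d) {
    (length(bg) - findInterval(d, bg)) / length(bg)
  }, numeric(1))
}

db_entry_matrix <- function(db) {
  do.call(rbind, lapply(db$entries, as.numeric))
}

new_gauss_db <- function(entries, background) {
  structure(list(
    header = list(version = pattern_version(),
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S",
                                   tz = "UTC"),
                  n_entries = length(entries)),
    entries = entries,
    background = unname(sort(background))),
    class = "gauss_db")
}

#' @export
print.gauss_db <- function(x, ...) {
  cat(sprintf(paste0("Gauss-integral descriptor database: %d entries, ",
                     "%d background distances\n"),
              length(x$entries), length(x$background)))
  cat(sprintf("  pattern set %s, created %s\n",
              x$header$version, x$header$created))
  if (length(x$background))
    cat(sprintf("  background distance median %.3f (range %.3f - %.3f)\n",
                stats::median(x$background), min(x$background),
                max(x$background)))
  invisible(x)
}

#' Build a descriptor database from PDB files
#'
#' Computes the Gauss descriptor of one chain per file (first chain with P
#' atoms unless `chain` is given), skipping - with a warning - chains whose
#' descriptor is undefined (7 or fewer P atoms) or that fail to parse, and
#' stores the all-pairs Euclidean distances as the significance background.
#'
#' @param pdb_paths Character vector of PDB files (or a directory, which is
#'   expanded to its `*.pdb`/`*.ent` files).
#' @param path Optional file to persist the database to (written
#'   atomically via a temporary file; see [write_database()]).
#' @param chain Optional chain id applied to every file.
#' @return A `gauss_db` with elements `header`, `entries` (named list of
#'   descriptors) and `background` (sorted distances).
#' @export
build_database <- function(pdb_paths, path = NULL, chain = NULL) {
  pdb_paths <- expand_pdb_paths(pdb_paths)
  entries <- list()
  for (f in pdb_paths) {
    d <- try_descriptor(f, chain)
    if (!is.null(d)) entries[[attr(d, "entry_id")]] <- d
  }
  if (length(entries) < 2L)
    stop("need at least two valid chains to build a database")
  mat <- do.call(rbind, lapply(entries, as.numeric))
  background <- as.numeric(stats::dist(mat))
  db <- new_gauss_db(entries, background)
  if (!is.null(path)) write_database(db, path)
  db
}

expand_pdb_paths <- function(paths) {
  out <- character(0)
  for (p in paths) {
    if (dir.exists(p)) {
      out <- c(out, list.files(p, pattern = "\\.(pdb|ent)$",
                               full.names = TRUE))
    } else {
      out <- c(out, p)
    }
  }
  sort(out)
}

try_descriptor <- function(f, chain = NULL) {
  d <- tryCatch(
    compute_descriptor(read_backbone(f, chain = chain)),
    error = function(e) {
      warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  d
}

#' Incrementally update a descriptor database
#'
#' Adds descriptors for chains not already present (by entry id) and
#' extends the background with the distances of each new entry to all
#' entries already in the (growing) database - so the result equals a full
#' rebuild on the union of inputs.  Already-present ids and invalid chains
#' are skipped with a warning.
#'
#' @param db A `gauss_db`.
#' @param new_paths PDB files or directories to add.
#' @param path Optional file to persist the updated database to.
#' @param chain Optional chain id applied to every file.
#' @return The updated `gauss_db`.
#' @export
update_database <- function(db, new_paths, path = NULL, chain = NULL) {
  stopifnot(inherits(db, "gauss_db"))
  if (!identical(db$header$version, pattern_version()))
    stop(sprintf("database pattern set '%s' does not match this build ('%s')",
                 db$header$version, pattern_version()))
  entries <- db$entries
  background <- db$background
  for (f in expand_pdb_paths(new_paths)) {
    d <- try_descriptor(f, chain)
    if (is.null(d)) next
    id <- attr(d, "entry_id")
    if (id %in% names(entries)) {
      warning(sprintf("entry '%s' already in database; skipped", id),
              call. = FALSE)
      next
    }
    if (length(entries)) {
      old <- do.call(rbind, lapply(entries, as.numeric))
      background <- c(background,
                      sqrt(rowSums(sweep(old, 2L, as.numeric(d))^2)))
    }
    entries[[id]] <- d
  }
  out <- new_gauss_db(entries, background)
  if (!is.null(path)) write_database(out, path)
  out
}

#' Persist a descriptor database to a single JSON file
#'
#' Plain-text columnar store: a header with the pattern-enumeration
#' version, the id -> 30-component descriptor map, and the sorted
#' background distances, all at full precision.  Writing is atomic (to a
#' temporary file, then renamed).
#'
#' @param db A `gauss_db`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "gauss_db"))
  payload <- list(header = db$header,
                  entries = lapply(db$entries, as.numeric),
                  background = db$background)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  # 17 significant digits: doubles round-trip exactly through the store
  jsonlite::write_json(payload, tmp, digits = I(17), auto_unbox = TRUE)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("cannot write database to ", path)
  }
  invisible(path)
}

#' Load a descriptor database written by [write_database()]
#'
#' @param path Database file.
#' @return A `gauss_db`.  Fails if the file's pattern-enumeration version
#'   differs from this build's.
#' @export
read_database <- function(path) {
  if (!file.exists(path)) stop("database file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$header$version, pattern_version()))
    stop(sprintf("database pattern set '%s' does not match this build ('%s')",
                 payload$header$version, pattern_version()))
  entries <- lapply(names(payload$entries), function(id)
    gauss_descriptor(payload$entries[[id]], entry_id = id,
                     version = payload$header$version))
  names(entries) <- names(payload$entries)
  db <- new_gauss_db(entries, as.numeric(payload$background))
  db$header$created <- payload$header$created
  db
}

#' Scan a descriptor database for structures similar to a query
#'
#' Returns every database entry whose descriptor lies within `cutoff`
#' Euclidean distance of the query, sorted by ascending distance (ties
#' broken by entry id), truncated to the `top_n` best hits, each annotated
#' with its empirical significance pD.  The defaults (cutoff 0.5, top 10)
#' are the server defaults of the method.
#'
#' @param query A `gauss_descriptor`, a [backbone_curve()], or a PDB path.
#' @param db A `gauss_db`.
#' @param cutoff Maximum distance retained (> 0).
#' @param top_n Maximum number of hits (>= 1).
#' @return A data frame of class `gauss_scan` with columns `entry_id`,
#'   `distance`, `p_value`, and attributes `cutoff`, `top_n`, `query_id`.
#' @export
scan_database <- function(query, db, cutoff = 0.5, top_n = 10L) {
  stopifnot(inherits(db, "gauss_db"))
  if (length(db$entries) == 0L) stop("database has no entries")
  if (!is.finite(cutoff) || cutoff < 0) stop("`cutoff` must be >= 0")
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L) stop("`top_n` must be >= 1")
  if (is.character(query)) query <- read_backbone(query)
  if (inherits(query, "backbone_curve")) query <- compute_descriptor(query)
  stopifnot(inherits(query, "gauss_descriptor"))
  if (!identical(attr(query, "version"), db$header$version))
    stop("query descriptor pattern set does not match the database")

  mat <- db_entry_matrix(db)
  dvec <- sqrt(rowSums(sweep(mat, 2L, as.numeric(query))^2))
  ids <- names(db$entries)
  keep <- which(dvec <= cutoff)
  ord <- keep[order(dvec[keep], ids[keep])]
  ord <- head(ord, top_n)
  hits <- data.frame(entry_id = ids[ord],
                     distance = dvec[ord],
                     p_value = if (length(ord))
                       significance(dvec[ord], db) else numeric(0),
                     stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  structure(hits, cutoff = cutoff, top_n = top_n,
            query_id = attr(query, "entry_id"),
            class = c("gauss_scan", "data.frame"))
}

#' @export
print.gauss_scan <- function(x, digits = 4, ...) {
  cat(sprintf("Database scan: query '%s', cutoff %g, top %d\n",
              attr(x, "query_id"), attr(x, "cutoff"), attr(x, "top_n")))
  if (nrow(x) == 0L) {
    cat("  no entries within the cutoff distance\n")
  } else {
    df <- as.data.frame(x)
    df$distance <- round(df$distance, digits)
    df$p_value <- round(df$p_value, digits)
    print(df, row.names = FALSE, ...)
  }
  invisible(x)
}
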