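# Chord-pattern enumeration behind the 29 Gauss integrals.
#
# A pattern of order k is a perfect matching of the positions 1..2k of a
# strictly increasing segment-index tuple, each chord contributing one
# W (or |W|) factor.  The component order of the descriptor is frozen:
# (order, matching in lexicographic order, abs-flag combination), and is
# versioned in every descriptor and database header.

#' Version tag of the pattern enumeration
#'
#' Identifies the fixed ordering of the 29 chord patterns (and hence the
#' meaning of descriptor components 2-30).  Descriptors and databases carry
#' this tag and refuse to be mixed across versions.
#'
#' @return A single string.
#' @export
#' @examples
#' pattern_version()
pattern_version <- function() "gi30-v1"

# All perfect matchings of positions 1..2k as a list of 2 x k matrices,
# in lexicographic order of the canonical pair list.
all_matchings <- function(k) {
  pos <- seq_len(2L * k)
  rec <- function(free) {
    if (length(free) == 0L) return(list(matrix(integer(0), nrow = 2L)))
    a <- free[1L]
    out <- list()
    for (b in free[-1L]) {
      rest <- setdiff(free, c(a, b))
      for (m in rec(rest)) out[[length(out) + 1L]] <- cbind(c(a, b), m)
    }
    out
  }
  rec(pos)
}

pattern_name <- function(pairs, abs_flags) {
  chords <- vapply(seq_len(ncol(pairs)), function(i) {
    s <- paste0(pairs[1L, i], pairs[2L, i])
    if (abs_flags[i]) paste0("|", s, "|") else s
  }, character(1))
  paste0("I", paste(chords, collapse = ","))
}

build_patterns <- function() {
  pats <- list()
  add <- function(order, pairs, abs_flags) {
    pats[[length(pats) + 1L]] <<- list(
      order = order, pairs = pairs, abs_flags = abs_flags,
      name = pattern_name(pairs, abs_flags))
  }
  # order 1: plain writhe and average crossing number
  m1 <- matrix(c(1L, 2L), nrow = 2L)
  add(1L, m1, FALSE)
  add(1L, m1, TRUE)
  # order 2: 3 matchings x abs variants (none, first, second, both)
  for (m in all_matchings(2L))
    for (fl in list(c(FALSE, FALSE), c(TRUE, FALSE),
                    c(FALSE, TRUE), c(TRUE, TRUE)))
      add(2L, m, fl)
  # order 3: all 15 matchings, plain W
  for (m in all_matchings(3L))
    add(3L, m, c(FALSE, FALSE, FALSE))
  pats
}

.pattern_cache <- new.env(parent = emptyenv())

pattern_list <- function() {
  if (is.null(.pattern_cache$pats)) .pattern_cache$pats <- build_patterns()
  .pattern_cache$pats
}

#' The 29 chord patterns defining the Gauss integrals
#'
#' Returns the fixed enumeration of chord patterns whose invariants make up
#' descriptor components 2-30: order 1 appears as the writhe `I12` and the
#' average crossing number `I|12|`; each of the three order-2 matchings
#' appears with every combination of absolute-value chords; the fifteen
#' order-3 matchings appear with plain `W` factors only.
#'
#' @param as_list If `TRUE`, return the internal list representation (one
#'   element per pattern with fields `order`, `pairs` (2 x k matrix of
#'   matched positions), `abs_flags` and `name`) instead of a data frame.
#' @return A data frame with columns `index`, `order`, `pairing`, `n_abs`
#'   and `name`, or a list when `as_list = TRUE`.
#' @export
#' @examples
#' head(chord_patterns())
chord_patterns <- function(as_list = FALSE) {
  pats <- pattern_list()
  if (as_list) return(pats)
  data.frame(
    index = seq_along(pats),
    order = vapply(pats, `[[`, integer(1), "order"),
    pairing = vapply(pats, function(p)
      paste0("(", p$pairs[1L, ], ",", p$pairs[2L, ], ")", collapse = ""),
      character(1)),
    n_abs = vapply(pats, function(p) sum(p$abs_flags), integer(1)),
    name = vapply(pats, `[[`, character(1), "name"),
    stringsAsFactors = FALSE)
}

#' Component names of the 30-dimensional descriptor
#'
#' @return Character vector of length 30: the backbone-length component
#'   `N` followed by the 29 invariant names in pattern order.
#' @export
descriptor_names <- function() {
  c("N", vapply(pattern_list(), `[[`, character(1), "name"))
}
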