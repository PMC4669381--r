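#' Nucleotide-specific alignment scoring schemes
#'
#' U-indel-edited reads differ from the pre-edited reference only by
#' insertions/deletions of T (U in RNA).  A scoring scheme therefore
#' carries *per-base* gap opening and extension penalties: a gap over base
#' `b` (in the read or the reference) is charged `gap_open[b] +
#' len * gap_extend[b]`; a value of `NA` bans gaps over that base.
#'
#' Two presets cover the two working modes:
#' * `scheme_strict()` — "T, -" and "-, T" gaps cost zero, A/C/G gaps are
#'   disallowed and no mismatches are tolerated; an alignment exists iff
#'   the read differs from the reference by U-indels only.
#' * `scheme_mapping()` — a permissive mode mirroring a short-read mapper
#'   patched with base-specific gap penalties: gap penalties 10/10 for
#'   A/C/G, 1/1 for T, mismatch penalty 18.
#'
#' @param match_score Score of an identical aligned pair.
#' @param mismatch_penalty Penalty (positive) of a mismatched pair.
#' @param gap_open,gap_extend Named numeric vectors over `A`,`C`,`G`,`T`;
#'   `NA` disallows gaps over that base.
#' @param max_mismatches Maximum mismatches tolerated by [map_read()].
#' @param allow_terminal_gap Whether read ends may overhang / be clipped
#'   without penalty.
#' @return An object of class `uindel_scheme`.
#' @export
scoring_scheme <- function(match_score = 1,
                           mismatch_penalty = 18,
                           gap_open = c(A = 10, C = 10, G = 10, T = 1),
                           gap_extend = c(A = 10, C = 10, G = 10, T = 1),
                           max_mismatches = 0,
                           allow_terminal_gap = TRUE) {
  bases <- c("A", "C", "G", "T")
  gap_open <- gap_open[bases]
  gap_extend <- gap_extend[bases]
  stopifnot(match_score > 0, mismatch_penalty >= 0,
            all(is.na(gap_open) | gap_open >= 0),
            all(is.na(gap_extend) | gap_extend >= 0))
  structure(list(match_score = as.integer(match_score),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open = gap_open,
                 gap_extend = gap_extend,
                 max_mismatches = as.integer(max_mismatches),
                 allow_terminal_gap = isTRUE(allow_terminal_gap)),
            class = "uindel_scheme")
}

#' @rdname scoring_scheme
#' @export
scheme_strict <- function(max_mismatches = 0) {
  scoring_scheme(match_score = 1, mismatch_penalty = 18,
                 gap_open = c(A = NA, C = NA, G = NA, T = 0),
                 gap_extend = c(A = NA, C = NA, G = NA, T = 0),
                 max_mismatches = max_mismatches)
}

#' @rdname scoring_scheme
#' @export
scheme_mapping <- function(max_mismatches = 2) {
  scoring_scheme(match_score = 1, mismatch_penalty = 18,
                 gap_open = c(A = 10, C = 10, G = 10, T = 1),
                 gap_extend = c(A = 10, C = 10, G = 10, T = 1),
                 max_mismatches = max_mismatches)
}

#' @export
print.uindel_scheme <- function(x, ...) {
  cat("<uindel_scheme> match ", x$match_score, ", mismatch -",
      x$mismatch_penalty, ", max mismatches ", x$max_mismatches, "\n",
      sep = "")
  go <- ifelse(is.na(x$gap_open), "banned", x$gap_open)
  ge <- ifelse(is.na(x$gap_extend), "banned", x$gap_extend)
  cat("  gap open  ", paste(names(x$gap_open), go, sep = "=", collapse = " "),
      "\n  gap extend", paste(names(x$gap_extend), ge, sep = "=",
                              collapse = " "), "\n")
  invisible(x)
}

# integer penalty vectors for the C++ core (-1 = banned)
scheme_penalties <- function(scheme) {
  go <- as.integer(ifelse(is.na(scheme$gap_open), -1L, scheme$gap_open))
  ge <- as.integer(ifelse(is.na(scheme$gap_extend), -1L, scheme$gap_extend))
  list(gap_open = go, gap_extend = ge)
}
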