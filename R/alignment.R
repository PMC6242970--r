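# Affine-gap global alignment (R surface over the compiled Gotoh kernel).

#' Alignment scoring scheme
#'
#' Defaults: match +2, mismatch -3, gap open -5, gap extend -1. A gap of
#' length L costs `gap_open + L * gap_extend`. Any consistent scheme works
#' for outcome classification; this one is pinned for reproducibility.
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores (penalties
#'   negative).
#' @return A named list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2L, mismatch = -3L,
                              gap_open = -5L, gap_extend = -1L) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "alignment_scoring")
}

#' Global alignment of a molecule against a candidate reference
#'
#' Optimal global (end-to-end) alignment under affine gap scoring, with a
#' deterministic traceback (ties prefer match/mismatch over deletion over
#' insertion, and gap extension over gap opening). Indel events are reported
#' in 0-based reference coordinates and left-normalised, i.e. shifted to
#' their leftmost equivalent placement within repeats -- the convention the
#' lesion classifier uses when attributing events to cut junctions.
#'
#' @param query Molecule sequence.
#' @param reference Candidate reference sequence.
#' @param scoring An [alignment_scoring()].
#' @return A list of class `alignment_result`: `score`, `n_match`,
#'   `n_mismatch`, `normalized_identity` (matches / (matches + mismatches)),
#'   and `events`, a tibble with `type` (`"insertion"`/`"deletion"`),
#'   `ref_pos`, `length`, `seq`.
#' @export
#' @examples
#' align_global("ACGTACGT", "ACGTTACGT")$events
align_global <- function(query, reference, scoring = alignment_scoring()) {
  stopifnot(is.character(query), length(query) == 1L, nchar(query) > 0L,
            is.character(reference), length(reference) == 1L,
            nchar(reference) > 0L)
  raw <- align_global_cpp(query, reference, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
  aligned_cols <- raw$n_match + raw$n_mismatch
  structure(
    list(score = raw$score,
         n_match = raw$n_match,
         n_mismatch = raw$n_mismatch,
         normalized_identity = if (aligned_cols > 0)
           raw$n_match / aligned_cols else 0,
         events = as_tibble(raw$events)),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %d, identity %.4f, %d indel event(s)\n",
              x$score, x$normalized_identity, nrow(x$events)))
  invisible(x)
}
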