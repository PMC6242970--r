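# Lesion classification: assign each molecule to one of seven repair-outcome
# classes by global alignment against candidate references built from the
# two predicted cut junctions.

#' Construct an amplicon reference with two annotated cut junctions
#'
#' `cut_a` is the SpCas9 cut junction, `cut_b` the partner-Cas9 junction;
#' both are 0-based split points (number of reference bases to the left of
#' the blunt break) and must satisfy `0 < cut_a < cut_b < nchar(sequence)`.
#'
#' @param sequence Reference (wild-type) amplicon sequence.
#' @param cut_a,cut_b Cut junctions.
#' @param ref_id Identifier (default `"amplicon"`).
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(sequence, cut_a, cut_b, ref_id = "amplicon") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  cut_a <- as.integer(cut_a); cut_b <- as.integer(cut_b)
  if (!(cut_a > 0L && cut_a < cut_b && cut_b < nchar(sequence)))
    abort("cut junctions must satisfy 0 < cut_a < cut_b < length(sequence)")
  structure(list(ref_id = ref_id, sequence = sequence,
                 cut_a = cut_a, cut_b = cut_b),
            class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon_reference> %s: %d nt, cuts at %d and %d\n",
              x$ref_id, nchar(x$sequence), x$cut_a, x$cut_b))
  invisible(x)
}

#' Build the three candidate references for classification
#'
#' The wild type; the precise deletion (the exact junction of the two
#' blunt break points, removing `[cut_a, cut_b)`); and the inversion (the
#' intervening segment reinserted in reverse complement).
#'
#' @param ref An [amplicon_reference()].
#' @return A named list `wild_type`, `precise_deletion`, `inversion`.
#' @export
build_candidate_references <- function(ref) {
  stopifnot(inherits(ref, "amplicon_reference"))
  s <- ref$sequence; n <- nchar(s)
  left <- substr(s, 1L, ref$cut_a)
  mid <- substr(s, ref$cut_a + 1L, ref$cut_b)
  right <- substr(s, ref$cut_b + 1L, n)
  list(wild_type = s,
       precise_deletion = paste0(left, right),
       inversion = paste0(left, revcomp(mid), right))
}

# Distance from an indel event to a cut junction. A deletion occupies the
# reference interval [pos, pos + length); an insertion sits at the split
# point pos. Both are compared against the junction split point.
event_cut_distance <- function(type, ref_pos, length, cut) {
  del <- type == "deletion"
  lo <- ref_pos
  hi <- ifelse(del, ref_pos + length, ref_pos)
  ifelse(cut < lo, lo - cut, ifelse(cut > hi, cut - hi, 0L))
}

#' Classify one molecule into a repair-outcome class
#'
#' The molecule is aligned globally against the three candidate references;
#' the best-scoring candidate (ties: wild type, then precise deletion, then
#' inversion) determines the branch:
#'
#' * best = precise deletion: no indel events -> `PRECISE_DELETION`; any
#'   indel event (necessarily junction-borne) -> `IMPRECISE_DELETION`.
#' * best = inversion: `INVERSION`.
#' * best = wild type: a deletion event spanning both cuts ->
#'   `IMPRECISE_DELETION`; otherwise indel events within `window` of
#'   `cut_a` only -> `SP_INDEL`, of `cut_b` only -> `PARTNER_INDEL`, of
#'   both -> `BOTH_INDEL`; no indel event near either cut -> `UNEDITED`
#'   provided identity passes `unedited_identity_min` (substitution-only
#'   changes never count as lesions).
#'
#' Molecules whose best-candidate gap-excluded identity falls below
#' `min_identity` are `UNCLASSIFIED` and excluded from class tallies.
#'
#' @param molecule Molecule sequence.
#' @param ref An [amplicon_reference()].
#' @param candidates Candidate references (defaults to
#'   [build_candidate_references()] of `ref`).
#' @param window Indel-attribution half-window around each cut junction in
#'   bp (default 5).
#' @param scoring An [alignment_scoring()].
#' @param min_identity Identity floor below which a molecule is
#'   `UNCLASSIFIED` (default 0.75).
#' @param unedited_identity_min Identity floor for the `UNEDITED` call
#'   (default 0.9).
#' @return A one-row tibble: `lesion_class`, `best_candidate`, `score`,
#'   `identity`, `n_events`, and `events` (list column).
#' @export
classify_molecule <- function(molecule, ref,
                              candidates = build_candidate_references(ref),
                              window = 5L,
                              scoring = alignment_scoring(),
                              min_identity = 0.75,
                              unedited_identity_min = 0.9) {
  stopifnot(inherits(ref, "amplicon_reference"))
  window <- as.integer(window)
  cand_names <- c("WT", "PRECISE", "INVERSION")
  cand_seqs <- c(candidates$wild_type, candidates$precise_deletion,
                 candidates$inversion)

  # Exact equality against a candidate is the maximal possible score.
  hit <- match(molecule, cand_seqs)
  if (!is.na(hit)) {
    aln <- list(score = scoring$match * nchar(molecule),
                n_match = nchar(molecule), n_mismatch = 0L,
                normalized_identity = 1,
                events = tibble(type = character(), ref_pos = integer(),
                                length = integer(), seq = character()))
    best <- hit
  } else {
    alns <- lapply(cand_seqs, function(cs) align_global(molecule, cs, scoring))
    scores <- vapply(alns, `[[`, numeric(1), "score")
    best <- which.max(scores)   # first maximum: WT > PRECISE > INVERSION
    aln <- alns[[best]]
  }

  cls <- classify_from_alignment(cand_names[best], aln, ref, window,
                                 min_identity, unedited_identity_min)
  tibble(lesion_class = cls,
         best_candidate = cand_names[best],
         score = aln$score,
         identity = aln$normalized_identity,
         n_events = nrow(aln$events),
         events = list(aln$events))
}

classify_from_alignment <- function(best, aln, ref, window,
                                    min_identity, unedited_identity_min) {
  if (aln$normalized_identity < min_identity) return("UNCLASSIFIED")
  ev <- aln$events
  if (best == "PRECISE")
    return(if (nrow(ev) == 0L) "PRECISE_DELETION" else "IMPRECISE_DELETION")
  if (best == "INVERSION") return("INVERSION")
  # best = WT: attribute events to the cut junctions
  if (nrow(ev) > 0L) {
    # A deletion that removes at least half of the intervening segment is a
    # segmental (imprecise) deletion, whether it spans both cuts or lies
    # strictly between them with shifted junctions; smaller events are
    # attributed to the nearest cut window below.
    seg_overlap <- ifelse(
      ev$type == "deletion",
      pmax(0L, pmin(ev$ref_pos + ev$length, ref$cut_b) -
                 pmax(ev$ref_pos, ref$cut_a)),
      0L)
    if (any(seg_overlap >= (ref$cut_b - ref$cut_a) / 2))
      return("IMPRECISE_DELETION")
    da <- event_cut_distance(ev$type, ev$ref_pos, ev$length, ref$cut_a)
    db <- event_cut_distance(ev$type, ev$ref_pos, ev$length, ref$cut_b)
    near_a <- any(da <= window)
    near_b <- any(db <= window)
    if (near_a && near_b) return("BOTH_INDEL")
    if (near_a) return("SP_INDEL")
    if (near_b) return("PARTNER_INDEL")
    # indels far from both cuts: sequencing/PCR noise
  }
  if (aln$normalized_identity >= unedited_identity_min) "UNEDITED"
  else "UNCLASSIFIED"
}

#' Classify a sample of molecules
#'
#' Applies [classify_molecule()] to every molecule and, unless
#' `large_deletion_mode` is on, reclassifies molecules below the
#' identity threshold as `UNCLASSIFIED` (the alignment-score filter; counts
#' still sum to the number of input molecules).
#'
#' @param molecules Tibble with `molecule_id` and `sequence` columns (e.g.
#'   the output of [consolidate_umis()], where `umi` serves as the id), or a
#'   character vector of sequences.
#' @param ref An [amplicon_reference()].
#' @param window Indel-attribution half-window (default 5).
#' @param scoring An [alignment_scoring()].
#' @param large_deletion_mode Disable the identity filter (default `FALSE`).
#' @param min_identity Identity threshold for the filter (default 0.9).
#' @return A tibble of class `lesion_calls`: one row per molecule with
#'   `molecule_id`, `lesion_class`, `best_candidate`, `score`, `identity`,
#'   `n_events`, `events`. The reference is attached as attribute `"ref"`.
#' @export
classify_sample <- function(molecules, ref, window = 5L,
                            scoring = alignment_scoring(),
                            large_deletion_mode = FALSE,
                            min_identity = 0.9) {
  if (is.character(molecules))
    molecules <- tibble(molecule_id = paste0("mol", seq_along(molecules)),
                        sequence = molecules)
  if (!"molecule_id" %in% names(molecules) && "umi" %in% names(molecules))
    molecules <- dplyr::rename(molecules, molecule_id = "umi")
  stopifnot(all(c("molecule_id", "sequence") %in% names(molecules)))

  if (nrow(molecules) == 0L) {
    calls <- tibble(molecule_id = character(), lesion_class = character(),
                    best_candidate = character(), score = numeric(),
                    identity = numeric(), n_events = integer(),
                    events = list())
    attr(calls, "ref") <- ref
    class(calls) <- c("lesion_calls", class(calls))
    return(calls)
  }
  floor_id <- if (large_deletion_mode) 0 else min_identity
  rows <- lapply(seq_len(nrow(molecules)), function(i) {
    classify_molecule(molecules$sequence[i], ref, window = window,
                      scoring = scoring, min_identity = floor_id)
  })
  calls <- bind_rows(rows)
  calls <- dplyr::bind_cols(tibble(molecule_id = molecules$molecule_id), calls)
  attr(calls, "ref") <- ref
  class(calls) <- c("lesion_calls", class(calls))
  calls
}

#' Tally lesion calls into a count table
#'
#' All seven classes plus `UNCLASSIFIED` are always present; counts sum to
#' the number of molecules.
#'
#' @param calls A `lesion_calls` tibble.
#' @param sample_id Sample identifier (default `"sample"`).
#' @return A tibble of class `lesion_count_table` with `sample_id`, `class`,
#'   `count`.
#' @export
lesion_count_table <- function(calls, sample_id = "sample") {
  levels <- c(LESION_CLASSES, "UNCLASSIFIED")
  counts <- table(factor(calls$lesion_class, levels = levels))
  out <- tibble(sample_id = sample_id, class = levels,
                count = as.integer(counts))
  class(out) <- c("lesion_count_table", class(out))
  out
}

#' Per-position indel catalog of a sample
#'
#' One row per (lesion class, event type, reference position, length)
#' combination with the number of molecules carrying it, the alignment-level
#' analogue of per-base lesion cataloguing; used for positional background
#' subtraction. Coordinates are those of the best candidate reference of
#' each molecule.
#'
#' @param calls A `lesion_calls` tibble.
#' @return A tibble with `class`, `candidate`, `type`, `ref_pos`, `length`,
#'   `count`.
#' @export
indel_catalog <- function(calls) {
  keep <- vapply(calls$events, nrow, integer(1)) > 0L
  if (!any(keep))
    return(tibble(class = character(), candidate = character(),
                  type = character(), ref_pos = integer(),
                  length = integer(), count = integer()))
  ev <- purrr::map2_dfr(
    calls$events[keep],
    seq_len(nrow(calls))[keep],
    function(e, i) mutate(e, class = calls$lesion_class[i],
                          candidate = calls$best_candidate[i]))
  count(ev, .data$class, .data$candidate, .data$type, .data$ref_pos,
        .data$length, name = "count")
}
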