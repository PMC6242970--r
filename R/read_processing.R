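# Read processing: quality filtering, UMI extraction, grouping, and
# consensus consolidation of PCR duplicates.

phred_scores <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Quality-filter merged reads
#'
#' Keeps reads whose mean Phred score is strictly above `mean_min` and whose
#' minimum per-base score is strictly above `base_min` (both thresholds read
#' as strict inequalities). Order is preserved; per-call counters are
#' attached as the `"counters"` attribute.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (Phred+33).
#' @param mean_min Mean-quality threshold (default 30).
#' @param base_min Per-base threshold (default 24).
#' @return The filtered tibble, with `attr(., "counters")` holding
#'   `reads_in`, `reads_kept`, `reads_dropped`.
#' @export
quality_filter <- function(reads, mean_min = 30, base_min = 24) {
  stopifnot(mean_min >= 0, base_min >= 0)
  check_read_table(reads)
  if (nrow(reads) == 0L) {
    attr(reads, "counters") <- c(reads_in = 0L, reads_kept = 0L,
                                 reads_dropped = 0L)
    return(reads)
  }
  scores <- phred_scores(reads$quality)
  keep <- vapply(scores,
                 function(s) mean(s) > mean_min && min(s) > base_min,
                 logical(1))
  out <- reads[keep, , drop = FALSE]
  attr(out, "counters") <- c(reads_in = nrow(reads),
                             reads_kept = sum(keep),
                             reads_dropped = sum(!keep))
  out
}

#' Extract UMIs from raw reads
#'
#' Splits each read into its unique molecular identifier (taken from the
#' configured end) and the remaining payload, with matching qualities.
#' Reads too short to leave a non-empty payload are skipped and counted.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param umi_length UMI length in nucleotides (default 10).
#' @param umi_end `"5prime"` (default) or `"3prime"`.
#' @return Tibble with `read_id`, `umi`, `sequence` (payload), `quality`
#'   (payload); skipped-read counters in `attr(., "counters")`.
#' @export
extract_umis <- function(reads, umi_length = 10L, umi_end = c("5prime", "3prime")) {
  umi_end <- match.arg(umi_end)
  umi_length <- as.integer(umi_length)
  stopifnot(umi_length > 0L)
  check_read_table(reads)
  len <- nchar(reads$sequence)
  ok <- len > umi_length
  kept <- reads[ok, , drop = FALSE]
  klen <- len[ok]
  if (umi_end == "5prime") {
    umi <- substr(kept$sequence, 1L, umi_length)
    payload <- substr(kept$sequence, umi_length + 1L, klen)
    qual <- substr(kept$quality, umi_length + 1L, klen)
  } else {
    umi <- substr(kept$sequence, klen - umi_length + 1L, klen)
    payload <- substr(kept$sequence, 1L, klen - umi_length)
    qual <- substr(kept$quality, 1L, klen - umi_length)
  }
  out <- tibble(read_id = kept$read_id, umi = umi,
                sequence = payload, quality = qual)
  attr(out, "counters") <- c(reads_in = nrow(reads),
                             reads_kept = nrow(out),
                             reads_too_short = sum(!ok))
  out
}

#' Group UMI-tagged reads by exact UMI match
#'
#' @param umi_reads Tibble with `umi` and `sequence` columns (payloads).
#' @return Tibble with one row per (umi, payload sequence): `umi`,
#'   `sequence`, `count`, plus per-UMI group size `group_size`.
#' @export
group_by_umi <- function(umi_reads) {
  if (nrow(umi_reads) == 0L)
    return(tibble(umi = character(), sequence = character(),
                  count = integer(), group_size = integer()))
  tal <- count(umi_reads, .data$umi, .data$sequence, name = "count")
  tal <- group_by(tal, .data$umi)
  tal <- mutate(tal, group_size = sum(.data$count))
  ungroup(tal)
}

#' Consolidate UMI groups to one molecule each
#'
#' For each UMI, the plurality payload sequence is emitted as the molecule's
#' consensus if and only if it was observed, base-for-base identical, at
#' least `min_support` times; otherwise the UMI yields no molecule. Ties on
#' the count are broken toward the lexicographically smallest sequence. One
#' molecule per UMI, maximum.
#'
#' @param umi_reads Tibble of UMI-tagged reads (from [extract_umis()]) or a
#'   tally from [group_by_umi()].
#' @param min_support Minimum identical observations (default 4).
#' @return Tibble with `umi`, `sequence`, `support`; counters
#'   (`umi_groups`, `molecules`, `groups_rejected`) in
#'   `attr(., "counters")`.
#' @export
consolidate_umis <- function(umi_reads, min_support = 4L) {
  min_support <- as.integer(min_support)
  stopifnot(min_support >= 1L)
  tal <- if ("count" %in% names(umi_reads)) umi_reads else group_by_umi(umi_reads)
  n_groups <- length(unique(tal$umi))
  if (nrow(tal) == 0L) {
    out <- tibble(umi = character(), sequence = character(),
                  support = integer())
    attr(out, "counters") <- c(umi_groups = 0L, molecules = 0L,
                               groups_rejected = 0L)
    return(out)
  }
  tal <- arrange(tal, .data$umi, dplyr::desc(.data$count), .data$sequence)
  best <- tal[!duplicated(tal$umi), , drop = FALSE]
  best <- filter(best, .data$count >= min_support)
  out <- tibble(umi = best$umi, sequence = best$sequence,
                support = best$count)
  attr(out, "counters") <- c(umi_groups = n_groups,
                             molecules = nrow(out),
                             groups_rejected = n_groups - nrow(out))
  out
}

#' Filter lesion calls by alignment identity
#'
#' Translates the read-mapping quality filter into alignment terms: when
#' `large_deletion_mode` is off, molecules whose best-candidate normalised
#' identity (gap-excluded: matches / (matches + mismatches)) falls below
#' `min_identity` are dropped. Segmental-deletion alignments score poorly
#' under mapping but have near-perfect gap-excluded identity, so the filter
#' is still meaningful; `large_deletion_mode = TRUE` bypasses it entirely.
#'
#' @param calls A `lesion_calls` tibble (from [classify_sample()]), with an
#'   `identity` column.
#' @param min_identity Identity threshold (default 0.9).
#' @param large_deletion_mode Bypass the filter (default `FALSE`).
#' @return The filtered calls tibble.
#' @export
alignment_score_filter <- function(calls, min_identity = 0.9,
                                   large_deletion_mode = FALSE) {
  if (large_deletion_mode) return(calls)
  filter(calls, .data$identity >= min_identity)
}
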