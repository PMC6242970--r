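# Quantification: rates, background subtraction, precise-deletion fraction,
# logit / Benjamini-Hochberg helpers, GUIDE-seq specificity summaries.

#' Convert lesion counts to per-class percentages
#'
#' Each class percentage is `100 * count / total`; the total lesion rate
#' (the summed percentage of the six edited classes) is available through
#' [total_lesion_rate()] or [glance()].
#'
#' @param counts A `lesion_count_table` (long tibble with `sample_id`,
#'   `class`, `count`).
#' @return A tibble of class `rate_table`: `sample_id`, `class`, `count`,
#'   `pct`. Errors when the total count is zero.
#' @export
compute_rates <- function(counts) {
  stopifnot(all(c("sample_id", "class", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("negative counts")
  total <- sum(counts$count)
  if (total == 0) abort("cannot compute rates from an all-zero count table")
  out <- mutate(as_tibble(counts), pct = 100 * .data$count / total)
  attr(out, "total") <- total
  class(out) <- c("rate_table", class(out))
  out
}

#' Total lesion rate of a rate table
#'
#' The summed percentage of the six edited classes (equivalently
#' `100 - unedited% - unclassified%`). Uses corrected percentages when
#' present.
#'
#' @param rates A `rate_table`.
#' @return A single percentage.
#' @export
total_lesion_rate <- function(rates) {
  col <- if ("pct_corrected" %in% names(rates)) "pct_corrected" else "pct"
  sum(rates[[col]][rates$class %in% edited_classes()])
}

#' Subtract negative-control background from a treated rate table
#'
#' Per class, the corrected rate is
#' `max(0, treated - mean(controls))` -- the mean background lesion rate of
#' the (typically triplicate) negative-control group, floored at zero.
#'
#' @param treated A `rate_table`.
#' @param controls A list of `rate_table`s (>= 1; a single table may be
#'   passed directly).
#' @return `treated` with an added `pct_corrected` column.
#' @export
subtract_background <- function(treated, controls) {
  if (inherits(controls, "rate_table")) controls <- list(controls)
  stopifnot(length(controls) >= 1L)
  schema <- sort(treated$class)
  bg <- lapply(controls, function(ctl) {
    if (!identical(sort(ctl$class), schema))
      abort("control rate table classes do not match the treated table")
    ctl$pct[match(treated$class, ctl$class)]
  })
  bg_mean <- Reduce(`+`, bg) / length(bg)
  out <- mutate(treated, pct_corrected = pmax(0, .data$pct - bg_mean))
  class(out) <- unique(c("rate_table", class(out)))
  out
}

#' Positional background subtraction for indel catalogs
#'
#' Matches background lesions by (class, candidate, event type, reference
#' position, length) exactly and subtracts the mean control count, floored
#' at zero.
#'
#' @param treated An [indel_catalog()] tibble.
#' @param controls List of control catalogs.
#' @return `treated` with an added `count_corrected` column.
#' @export
subtract_background_positions <- function(treated, controls) {
  if (is.data.frame(controls)) controls <- list(controls)
  stopifnot(length(controls) >= 1L)
  key <- c("class", "candidate", "type", "ref_pos", "length")
  bg <- bind_rows(controls)
  if (nrow(bg)) {
    bg <- group_by(bg, across(all_of(key)))
    bg <- summarise(bg, bg_count = sum(.data$count) / length(controls),
                    .groups = "drop")
    out <- left_join(treated, bg, by = key)
  } else {
    out <- mutate(treated, bg_count = 0)
  }
  out$bg_count[is.na(out$bg_count)] <- 0
  out <- mutate(out, count_corrected = pmax(0, .data$count - .data$bg_count))
  select(out, -"bg_count")
}

#' Precise-deletion fraction of all lesions
#'
#' The precise-deletion percentage divided by the summed percentage of all
#' six edited classes. Returns `NA` when the sample carries no lesions.
#' Corrected percentages are used when present (the default reading of
#' "rate divided by the total lesions"); set `use_corrected = FALSE` for raw
#' rates.
#'
#' @param rates A `rate_table`.
#' @param use_corrected Prefer `pct_corrected` when available (default
#'   `TRUE`).
#' @return A fraction in `[0, 1]`, or `NA` when undefined.
#' @export
precise_deletion_fraction <- function(rates, use_corrected = TRUE) {
  col <- if (use_corrected && "pct_corrected" %in% names(rates))
    "pct_corrected" else "pct"
  lesions <- sum(rates[[col]][rates$class %in% edited_classes()])
  if (lesions <= 0) return(NA_real_)
  rates[[col]][rates$class == "PRECISE_DELETION"] / lesions
}

#' Logit transform of a lesion fraction
#'
#' `ln(p / (1 - p))`, with boundary values clamped to
#' `[eps, 1 - eps]`. When `total` (the number of molecules behind the
#' fraction) is supplied, `eps` defaults to `1 / (2 * total)`; with neither
#' supplied, exact 0 and 1 produce infinities.
#'
#' @param p Fraction(s) in `[0, 1]`.
#' @param total Optional molecule count used to derive the clamp.
#' @param eps Optional explicit clamp.
#' @return Numeric vector of logits.
#' @export
#' @examples
#' logit_transform(0.5)  # 0
#' logit_transform(0.9)  # log(9)
logit_transform <- function(p, total = NULL, eps = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("fractions must lie in [0, 1]")
  if (is.null(eps)) eps <- if (!is.null(total)) 1 / (2 * total) else 0
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' GUIDE-seq specificity ratio
#'
#' On-target unique read count divided by the sum of unique reads over all
#' computationally identified off-target sites. `Inf` marks perfect
#' specificity (no off-target reads but on-target signal); `NA` marks the
#' undefined case of no reads anywhere.
#'
#' @param on_count Unique reads at the target site.
#' @param off_counts Integer vector of unique reads at off-target sites
#'   (may be empty).
#' @return A single number (possibly `Inf` or `NA`).
#' @export
#' @examples
#' specificity_ratio(100, c(20, 30))  # 2
specificity_ratio <- function(on_count, off_counts = integer()) {
  stopifnot(on_count >= 0, all(off_counts >= 0))
  off <- sum(off_counts)
  if (off == 0) {
    if (on_count > 0) return(Inf)
    return(NA_real_)
  }
  on_count / off
}

#' Fold improvement of a specificity ratio over a reference nuclease
#'
#' @param ratio_variant Specificity ratio of the variant (may be `Inf`).
#' @param ratio_reference Specificity ratio of the reference; must be a
#'   positive finite number.
#' @return `ratio_variant / ratio_reference` (`Inf` propagates).
#' @export
fold_improvement <- function(ratio_variant, ratio_reference) {
  if (!is.finite(ratio_reference) || ratio_reference <= 0)
    abort("reference specificity ratio must be positive and finite")
  ratio_variant / ratio_reference
}

#' Summarise a GUIDE-seq site table into specificity ratios
#'
#' @param table Tibble with columns `site_id`, `is_on_target` (logical),
#'   `unique_reads`, and optionally `nuclease` (one summary row per
#'   nuclease).
#' @param reference_nuclease Optional nuclease id whose ratio anchors the
#'   `fold_improvement` column.
#' @return A tibble with `nuclease`, `on_target_reads`, `off_target_reads`,
#'   `n_off_target_sites`, `specificity_ratio`, and (when a reference is
#'   given) `fold_improvement`.
#' @export
specificity_summary <- function(table, reference_nuclease = NULL) {
  stopifnot(all(c("site_id", "is_on_target", "unique_reads") %in% names(table)))
  if (!"nuclease" %in% names(table)) table$nuclease <- "nuclease"
  out <- group_by(table, .data$nuclease)
  out <- summarise(
    out,
    on_target_reads = sum(.data$unique_reads[.data$is_on_target]),
    off_target_reads = sum(.data$unique_reads[!.data$is_on_target]),
    n_off_target_sites = sum(!.data$is_on_target),
    specificity_ratio = specificity_ratio(
      sum(.data$unique_reads[.data$is_on_target]),
      .data$unique_reads[!.data$is_on_target]),
    .groups = "drop")
  if (!is.null(reference_nuclease)) {
    refrow <- out$specificity_ratio[out$nuclease == reference_nuclease]
    if (length(refrow) != 1L)
      abort("reference nuclease not found in the table")
    out <- mutate(out, fold_improvement =
                    vapply(.data$specificity_ratio,
                           fold_improvement, numeric(1),
                           ratio_reference = refrow))
  }
  out
}
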