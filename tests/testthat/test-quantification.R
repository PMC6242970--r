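mk_counts <- function(counts, sample_id = "s1") {
  classes <- c(lesion_classes(), "UNCLASSIFIED")
  stopifnot(length(counts) == length(classes))
  out <- tibble::tibble(sample_id = sample_id, class = classes,
                        count = as.integer(counts))
  class(out) <- c("lesion_count_table", class(out))
  out
}

test_that("rates are percentages of total molecules", {
  counts <- mk_counts(c(90, 0, 0, 0, 10, 0, 0, 0))
  r <- compute_rates(counts)
  expect_equal(r$pct[r$class == "PRECISE_DELETION"], 10)
  expect_equal(sum(r$pct), 100)
  expect_equal(total_lesion_rate(r), 10)
  expect_equal(r$pct * attr(r, "total") / 100, r$count)
  all_wt <- mk_counts(c(50, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(total_lesion_rate(compute_rates(all_wt)), 0)
  expect_error(compute_rates(mk_counts(rep(0, 8))), "zero")
})

test_that("background subtraction averages controls and floors at zero", {
  treated <- compute_rates(mk_counts(c(80, 0, 0, 0, 10, 5, 0, 5)))
  # control precise rates of 1.0%, 1.2% and 0.8% (counts out of 1000)
  ctl <- function(k) compute_rates(mk_counts(c(1000 - k, 0, 0, 0, k, 0, 0, 0)))
  corr <- subtract_background(treated, list(ctl(10), ctl(12), ctl(8)))
  expect_equal(corr$pct_corrected[corr$class == "PRECISE_DELETION"], 9)
  # treated below background floors at zero
  low <- compute_rates(mk_counts(c(199, 0, 0, 0, 1, 0, 0, 0)))
  hi_ctl <- compute_rates(mk_counts(c(98, 0, 0, 0, 2, 0, 0, 0)))
  corr2 <- subtract_background(low, list(hi_ctl))
  expect_equal(corr2$pct_corrected[corr2$class == "PRECISE_DELETION"], 0)
  # schema mismatch errors
  bad <- compute_rates(mk_counts(c(1, 0, 0, 0, 1, 0, 0, 0)))
  bad$class[1] <- "SOMETHING_ELSE"
  expect_error(subtract_background(treated, list(bad)), "classes")
})

test_that("self-subtraction is identically zero and never negative", {
  set.seed(71)
  for (i in 1:5) {
    counts <- mk_counts(rmultinom(1, 500, runif(8)))
    r <- compute_rates(counts)
    self <- subtract_background(r, list(r, r, r))
    expect_equal(self$pct_corrected, rep(0, 8))
    other <- compute_rates(mk_counts(rmultinom(1, 500, runif(8))))
    corr <- subtract_background(r, list(other))
    expect_true(all(corr$pct_corrected >= 0))
    expect_true(all(corr$pct_corrected <= corr$pct))
  }
})

test_that("positional background subtraction matches events exactly", {
  treated <- tibble::tibble(class = "SP_INDEL", candidate = "WT",
                            type = "deletion", ref_pos = c(80L, 81L),
                            length = c(2L, 1L), count = c(10L, 4L))
  ctl <- tibble::tibble(class = "SP_INDEL", candidate = "WT",
                        type = "deletion", ref_pos = 80L, length = 2L,
                        count = 6L)
  out <- subtract_background_positions(treated, list(ctl, ctl))
  expect_equal(out$count_corrected[out$ref_pos == 80], 4)   # 10 - mean(6,6)
  expect_equal(out$count_corrected[out$ref_pos == 81], 4)   # unmatched
})

test_that("precise-deletion fraction is precise over all lesions", {
  r <- compute_rates(mk_counts(c(90, 1, 0, 0, 9, 0, 0, 0)))
  expect_equal(precise_deletion_fraction(r), 0.9)
  only <- compute_rates(mk_counts(c(50, 0, 0, 0, 50, 0, 0, 0)))
  expect_equal(precise_deletion_fraction(only), 1)
  none <- compute_rates(mk_counts(c(100, 0, 0, 0, 0, 0, 0, 0)))
  expect_true(is.na(precise_deletion_fraction(none)))
  expect_true(precise_deletion_fraction(r) >= 0 &&
                precise_deletion_fraction(r) <= 1)
})

test_that("logit transform has the closed form and antisymmetry", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.9), log(9))
  p <- c(0.1, 0.25, 0.6, 0.99)
  expect_equal(logit_transform(p), -logit_transform(1 - p))
  # boundary clamp from the molecule count
  expect_equal(logit_transform(0, total = 100), log((1 / 200) / (1 - 1 / 200)))
  expect_error(logit_transform(1.2), "\\[0, 1\\]")
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(72)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in p
  expect_error(bh_adjust(c(0.1, 1.5)), "\\[0, 1\\]")
})

test_that("specificity ratios handle boundary cases with markers", {
  expect_equal(specificity_ratio(100, c(20, 30)), 2)
  expect_identical(specificity_ratio(50, integer()), Inf)
  expect_equal(specificity_ratio(0, 10), 0)
  expect_true(is.na(specificity_ratio(0, integer())))
  expect_equal(fold_improvement(8, 2), 4)
  expect_equal(fold_improvement(2, 2), 1)
  expect_identical(fold_improvement(Inf, 2), Inf)
  expect_error(fold_improvement(1, 0), "positive")
})

test_that("GUIDE-seq tables summarise to per-nuclease ratios", {
  tbl <- tibble::tibble(
    nuclease = rep(c("SpCas9WT", "fusion"), each = 3),
    site_id = paste0("s", 1:6),
    is_on_target = rep(c(TRUE, FALSE, FALSE), 2),
    unique_reads = c(100L, 20L, 30L, 90L, 5L, 4L))
  out <- specificity_summary(tbl, reference_nuclease = "SpCas9WT")
  expect_equal(out$specificity_ratio[out$nuclease == "SpCas9WT"], 2)
  expect_equal(out$specificity_ratio[out$nuclease == "fusion"], 10)
  expect_equal(out$fold_improvement[out$nuclease == "fusion"], 5)
})
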