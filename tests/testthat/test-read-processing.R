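mk_read <- function(seq, scores, id = "r1") {
  tibble::tibble(read_id = id, sequence = seq,
                 quality = intToUtf8(scores + 33L))
}

test_that("quality thresholds are strict inequalities", {
  r_hi <- mk_read(strrep("A", 10), rep(40L, 10))
  r_edge <- mk_read(strrep("A", 10), c(24L, rep(40L, 9)))
  r_mean <- mk_read("ACGT", rep(30L, 4))
  reads <- dplyr::bind_rows(r_hi, r_edge, r_mean)
  kept <- quality_filter(reads)
  expect_identical(kept$read_id, "r1")  # only the all-Q40 read survives
  cc <- attr(kept, "counters")
  expect_identical(unname(cc["reads_in"]), 3L)
  expect_identical(unname(cc["reads_kept"] + cc["reads_dropped"]), 3L)
})

test_that("quality filtering is idempotent and handles empty input", {
  set.seed(21)
  reads <- tibble::tibble(
    read_id = paste0("r", 1:50),
    sequence = vapply(1:50, function(i) random_seq(30), character(1)),
    quality = vapply(1:50, function(i)
      intToUtf8(sample(20:41, 30, replace = TRUE) + 33L), character(1)))
  once <- quality_filter(reads)
  twice <- quality_filter(once)
  expect_identical(twice$read_id, once$read_id)
  expect_identical(twice$sequence, once$sequence)
  expect_identical(unname(attr(twice, "counters")["reads_dropped"]), 0L)
  empty <- quality_filter(reads[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("UMI extraction slices the configured end and round-trips", {
  r <- mk_read(paste0("ACGTACGTAC", "TTTGGGCCCAAA"), rep(40L, 22))
  u <- extract_umis(r, umi_length = 10)
  expect_identical(u$umi, "ACGTACGTAC")
  expect_identical(u$sequence, "TTTGGGCCCAAA")
  expect_identical(paste0(u$umi, u$sequence), r$sequence)
  expect_identical(nchar(u$quality), nchar(u$sequence))

  u3 <- extract_umis(r, umi_length = 3, umi_end = "3prime")
  expect_identical(u3$umi, "AAA")
  expect_identical(paste0(u3$sequence, u3$umi), r$sequence)
})

test_that("reads no longer than the UMI are rejected and counted", {
  r <- mk_read(strrep("A", 10), rep(40L, 10))
  u <- extract_umis(r, umi_length = 10)
  expect_identical(nrow(u), 0L)
  expect_identical(unname(attr(u, "counters")["reads_too_short"]), 1L)
})

test_that("UMI grouping tallies exactly and conserves reads", {
  reads <- tibble::tibble(
    read_id = paste0("r", 1:3),
    umi = c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC"),
    sequence = c("ACGT", "ACGT", "TTTT"),
    quality = rep("FFFF", 3))
  g <- group_by_umi(reads)
  expect_identical(sort(unique(g$group_size)), c(1L, 2L))
  expect_identical(sum(g$count), 3L)
  expect_identical(nrow(group_by_umi(reads[0, ])), 0L)
})

test_that("consolidation enforces the minimum-support rule", {
  mk <- function(umi, seqs) tibble::tibble(
    read_id = seq_along(seqs), umi = umi, sequence = seqs,
    quality = strrep("F", nchar(seqs)))
  expect_identical(
    consolidate_umis(mk("AAAAAAAAAA", rep("ACGTACGT", 5)))$support, 5L)
  expect_identical(
    nrow(consolidate_umis(mk("AAAAAAAAAA", rep("ACGTACGT", 3)))), 0L)
  # plurality with competing sequences in one group
  mixed <- mk("AAAAAAAAAA", c(rep("AAAACCCC", 4), rep("GGGGTTTT", 5)))
  res <- consolidate_umis(mixed)
  expect_identical(res$sequence, "GGGGTTTT")
  expect_identical(res$support, 5L)
  # count tie breaks toward the lexicographically smallest sequence
  tied <- mk("AAAAAAAAAA", c(rep("TTTT", 4), rep("CCCC", 4)))
  expect_identical(consolidate_umis(tied)$sequence, "CCCC")
  # one molecule per UMI even when two sequences pass the threshold
  expect_identical(nrow(consolidate_umis(mixed)), 1L)
})

test_that("under-duplicated molecules are never emitted", {
  for (seed in 1:3) {
    lib <- simulate_library(sim_config(n_molecules = 40, error_rate = 0,
                                       copy_range = c(1L, 3L), seed = seed))
    mols <- consolidate_umis(extract_umis(lib$reads))
    expect_identical(nrow(mols), 0L)
  }
})

test_that("error-free duplicated libraries are recovered exactly", {
  lib <- simulate_library(sim_config(n_molecules = 60, error_rate = 0,
                                     copy_range = c(4L, 9L), seed = 11))
  mols <- consolidate_umis(extract_umis(lib$reads))
  expect_identical(nrow(mols), length(unique(lib$truth$umi)))
  expect_setequal(mols$sequence, lib$truth$true_sequence)
  expect_setequal(mols$umi, lib$truth$umi)
})

test_that("identity filter drops junk molecules unless in large-deletion mode", {
  set.seed(22)
  ref <- simulate_reference()
  good <- ref$sequence
  junk <- random_seq(200)
  calls <- classify_sample(c(good, junk), ref, large_deletion_mode = TRUE)
  kept <- alignment_score_filter(calls, 0.9, large_deletion_mode = FALSE)
  expect_identical(kept$molecule_id, "mol1")
  bypass <- alignment_score_filter(calls, 0.9, large_deletion_mode = TRUE)
  expect_identical(nrow(bypass), 2L)
})
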