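test_that("reference simulation is deterministic with sane composition", {
  r1 <- simulate_reference(seed = 81)
  r2 <- simulate_reference(seed = 81)
  expect_identical(r1$sequence, r2$sequence)
  expect_identical(nchar(r1$sequence), 200L)
  expect_true(r1$cut_a > 0 && r1$cut_a < r1$cut_b &&
                r1$cut_b < nchar(r1$sequence))
  # GC tracks the requested fraction at large n
  big <- simulate_reference(length = 1e5, gc = 0.5, cut_a = 100, cut_b = 200,
                            seed = 82)
  gc <- mean(strsplit(big$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.01)
  # homopolymer runs are capped
  runs <- rle(strsplit(r1$sequence, "")[[1]])
  expect_lte(max(runs$lengths), 3L)
  expect_error(simulate_reference(length = 100, cut_a = 90, cut_b = 50),
               "cut")
})

test_that("simulated molecules have the defining geometry of their class", {
  ref <- simulate_reference(seed = 83)
  set.seed(84)
  expect_identical(simulate_molecule("UNEDITED", ref)$sequence, ref$sequence)
  p <- simulate_molecule("PRECISE_DELETION", ref)
  expect_identical(nchar(p$sequence), 140L)
  expect_identical(
    p$sequence,
    paste0(substr(ref$sequence, 1, 80), substr(ref$sequence, 141, 200)))
  inv <- simulate_molecule("INVERSION", ref)$sequence
  expect_identical(nchar(inv), 200L)
  expect_identical(substr(inv, 1, 80), substr(ref$sequence, 1, 80))
  imp <- simulate_molecule("IMPRECISE_DELETION", ref)$sequence
  expect_false(identical(nchar(imp), 140L) &&
                 identical(imp, p$sequence))
})

test_that("library simulation is deterministic and conserves reads", {
  cfg <- sim_config(n_molecules = 40, error_rate = 0.001,
                    copy_range = c(5L, 5L), seed = 85)
  l1 <- simulate_library(cfg)
  l2 <- simulate_library(cfg)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  expect_identical(nrow(l1$reads), 200L)            # 40 molecules x 5 copies
  expect_identical(sum(l1$truth$copies), nrow(l1$reads))
  expect_true(all(nchar(l1$reads$sequence) ==
                    nchar(l1$truth$true_sequence[rep(1:40, each = 5)]) + 10L))
  expect_true(all(nchar(l1$reads$quality) == nchar(l1$reads$sequence)))
})

test_that("empirical class frequencies track the mixture", {
  lib <- simulate_library(sim_config(n_molecules = 4000, error_rate = 0,
                                     copy_range = c(1L, 1L), seed = 86))
  freq <- table(factor(lib$truth$class, levels = lesion_classes())) / 4000
  mix <- sim_config()$mixture[lesion_classes()]
  expect_true(all(abs(freq - mix) < 0.025))
})

test_that("written FASTQ round-trips through the reader", {
  lib <- simulate_library(sim_config(n_molecules = 10, copy_range = c(2L, 2L),
                                     seed = 87))
  f <- tempfile(fileext = ".fastq")
  write_fastq(lib$reads, f)
  back <- read_fastq(f)
  expect_identical(back$sequence, lib$reads$sequence)
  expect_identical(back$quality, lib$reads$quality)
})

test_that("planted genomes are recovered exactly and BED round-trips", {
  sim <- simulate_genome_with_sites(4, "SaCas9", "canonical",
                                    genome_length = 10000, seed = 88)
  found <- enumerate_composite_sites(sim$genome, "SaCas9", "canonical")
  expect_identical(nrow(found), 4L)
  key <- function(d) sort(paste(d$sp_start, d$sp_strand, d$partner_start,
                                d$partner_strand, d$orientation, d$spacing_x))
  expect_identical(key(found), key(sim$truth))

  f <- tempfile(fileext = ".bed")
  write_composite_sites_bed(found, f)
  back <- read_composite_sites_bed(f)
  expect_identical(back$sp_start, found$sp_start)
  expect_identical(back$partner_start, found$partner_start)
  expect_identical(back$orientation, found$orientation)
  expect_identical(back$spacing_x, found$spacing_x)

  none <- simulate_genome_with_sites(0, "SaCas9", "canonical",
                                     genome_length = 3000, seed = 89)
  expect_identical(
    nrow(enumerate_composite_sites(none$genome, "SaCas9", "canonical")), 0L)
  expect_error(
    simulate_genome_with_sites(50, "SaCas9", genome_length = 2000, seed = 90),
    "packing")
})

test_that("zero-error generator output closes the loop through the classifier", {
  sim <- simulate_library(sim_config(n_molecules = 150, error_rate = 0,
                                     copy_range = c(1L, 1L), seed = 91))
  calls <- classify_sample(
    tibble::tibble(molecule_id = sim$truth$molecule_id,
                   sequence = sim$truth$true_sequence), sim$ref)
  expect_identical(calls$lesion_class, sim$truth$class)
})
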