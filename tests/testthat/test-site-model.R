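test_that("IUPAC PAM matching follows the ambiguity classes", {
  expect_true(match_pam("AGG", "NGG"))
  expect_true(match_pam("GAAT", "GRRT"))
  expect_false(match_pam("GCGT", "GRRT"))
  expect_true(match_pam("TTGAGT", "NNGRRT"))
  expect_false(match_pam("NGG", "NGG"))  # a genome N matches nothing
  expect_error(match_pam("AG", "NGG"), "length")
  expect_error(match_pam("AGG", "XGG"), "IUPAC")
})

test_that("blunt cut junctions sit 3 bp 5' of the PAM on either strand", {
  expect_identical(predict_cut_junction(100L, 120L, "+"), 117L)
  expect_identical(predict_cut_junction(100L, 120L, "-"), 103L)
  expect_identical(predict_cut_junction(200L, 221L, "+"), 218L)
})

test_that("guide-site enumeration finds planted sites and nothing else", {
  expect_identical(nrow(enumerate_guide_sites(
    c(chr = strrep("A", 50)), "SpCas9")), 0L)

  g <- c(chr = paste0("TTTT", strrep("A", 20), "TGG", "TTT"))  # 30 nt
  s <- enumerate_guide_sites(g, "SpCas9")
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 4L)
  expect_identical(s$strand, "+")
  expect_identical(s$pam_seq, "TGG")
  expect_identical(s$cut_junction, 21L)  # proto [4,24), cut at 24 - 3
})

test_that("sites containing ambiguity letters are discarded", {
  g <- c(chr = paste0("TTTT", strrep("A", 10), "N", strrep("A", 9), "TGG", "TTT"))
  expect_identical(nrow(enumerate_guide_sites(g, "SpCas9")), 0L)
})

test_that("expanded-PAM duplicates are reported once", {
  # the PAM TGG at start 4 matches both NNG and NGN; neighbouring starts
  # read the same Gs under one pattern each
  g <- c(chr = paste0("TTTT", strrep("A", 20), "TGG", "TTT"))
  s <- enumerate_guide_sites(g, "SpCas9", c("NNG", "NGN"))
  expect_identical(sum(s$start == 4L), 1L)
  expect_false(any(duplicated(paste(s$contig, s$start, s$strand))))
})

test_that("guide-site counts are strand-symmetric", {
  set.seed(31)
  g <- random_seq(4000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  for (enz in c("SpCas9", "SaCas9", "NmCas9")) {
    n1 <- nrow(enumerate_guide_sites(c(chr = g), enz))
    n2 <- nrow(enumerate_guide_sites(c(chr = rc), enz))
    expect_identical(n1, n2)
  }
})

test_that("guide-site scan agrees with the regex oracle", {
  set.seed(32)
  g <- random_seq(5000)
  for (enz in c("SpCas9", "SaCas9", "NmCas9")) {
    e <- cas9_presets(enz)
    pams <- if (enz == "SpCas9") "NGG" else
      paste0(strrep("N", e$pam_length - nchar(e$pam_search_core)),
             e$pam_search_core)
    impl <- enumerate_guide_sites(c(chr = g), enz)
    orac <- oracle_guide_sites(g, e$protospacer_length, pams)
    expect_setequal(paste(impl$start, impl$strand),
                    paste(orac$start, orac$strand))
  }
})

test_that("cut junction sits cut_offset inside the PAM-proximal edge", {
  set.seed(33)
  g <- c(chr = random_seq(5000))
  for (enz in c("SpCas9", "SaCas9", "NmCas9")) {
    s <- enumerate_guide_sites(g, enz)
    off <- cas9_presets(enz)$cut_offset
    d <- ifelse(s$strand == "+", s$proto_end - s$cut_junction,
                s$cut_junction - s$proto_start)
    expect_true(all(d == off))
  }
})

test_that("a planted SpCas9/SaCas9 pair is found with its exact spacing", {
  set.seed(34)
  # 80-nt contig: SpCas9 site, 15-nt spacer, SaCas9 site, both + strand
  sp_site <- paste0(random_seq(20), "AGG")
  sa_site <- paste0(random_seq(21), "TTGAGT")
  contig <- paste0("TTTTT", sp_site, strrep("T", 15), sa_site, "TTTTT")
  hits <- enumerate_composite_sites(c(chr = contig), "SaCas9", "canonical")
  # background T-runs cannot harbour extra sites, but the random protospacer
  # can; restrict to the planted coordinates
  planted <- hits[hits$sp_start == 5 & hits$partner_start == 43, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$spacing_x, 15L)
  expect_identical(planted$orientation, "D1")

  none <- enumerate_composite_sites(c(chr = contig), "SaCas9", "canonical",
                                    spacing_range = c(20L, 30L))
  expect_identical(nrow(none[none$sp_start == 5 & none$partner_start == 43, ]),
                   0L)
})

test_that("composite enumeration equals the brute-force oracle", {
  set.seed(35)
  g <- random_seq(6000)
  for (partner in c("SaCas9", "NmCas9")) {
    spec <- oracle_partner_spec(partner)
    for (mode in c("canonical", "expanded")) {
      spacing <- if (mode == "canonical") c(10L, 30L) else c(10L, 100L)
      impl <- enumerate_composite_sites(c(chr = g), partner, mode)
      orac <- oracle_composites(g, oracle_sp_pams(mode), spec$proto_len,
                                spec$pams, spacing)
      expect_identical(impl_composite_key(impl), composite_key(orac))
    }
  }
})

test_that("composite counts are reverse-complement invariant and monotone", {
  set.seed(36)
  g <- random_seq(6000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  n_can <- nrow(enumerate_composite_sites(c(chr = g), "SaCas9", "canonical"))
  n_exp <- nrow(enumerate_composite_sites(c(chr = g), "SaCas9", "expanded"))
  expect_identical(
    n_can, nrow(enumerate_composite_sites(c(chr = rc), "SaCas9", "canonical")))
  expect_identical(
    n_exp, nrow(enumerate_composite_sites(c(chr = rc), "SaCas9", "expanded")))
  expect_gte(n_exp, n_can)
  # expanded results contain every canonical composite
  can <- enumerate_composite_sites(c(chr = g), "SaCas9", "canonical")
  exp <- enumerate_composite_sites(c(chr = g), "SaCas9", "expanded")
  expect_true(all(impl_composite_key(can) %in% impl_composite_key(exp)))
})

test_that("targeting-range comparison handles empty and planted genomes", {
  r <- compare_targeting_range(c(chr = strrep("A", 2000)), "SaCas9")
  expect_identical(r$n_sp_only_ngg, 0L)
  expect_identical(r$n_composite_canonical, 0L)
  expect_true(is.na(r$ratio_canonical))
  expect_error(compare_targeting_range(Biostrings::DNAStringSet(), "SaCas9"),
               "empty")

  set.seed(37)
  g <- random_seq(4000)
  r2 <- compare_targeting_range(c(chr = g), "SaCas9")
  expect_gte(r2$n_composite_expanded, r2$n_composite_canonical)
  expect_identical(r2$n_sp_only_ngg,
                   nrow(enumerate_guide_sites(c(chr = g), "SpCas9")))
})

test_that("orientation labels are remappable", {
  set.seed(38)
  g <- random_seq(3000)
  swapped <- c(downstream_same = "D2", downstream_opposite = "D1",
               upstream_same = "D3", upstream_opposite = "D4")
  a <- enumerate_composite_sites(c(chr = g), "SaCas9", "canonical",
                                 orientations = "D1")
  b <- enumerate_composite_sites(c(chr = g), "SaCas9", "canonical",
                                 orientations = "D2",
                                 orientation_map = swapped)
  expect_identical(paste(a$sp_start, a$partner_start),
                   paste(b$sp_start, b$partner_start))
  expect_error(
    enumerate_composite_sites(c(chr = g), "SaCas9", orientations = "D9"),
    "orientation")
})
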