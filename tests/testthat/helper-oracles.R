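# Independent oracles used to cross-check the package implementation.
# They deliberately share no code with the package: sites are found with
# Perl regular expressions, pairs by exhaustive O(n^2) comparison, and
# alignment scores by a plain-R dynamic program.

ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                  H = "[ACT]", V = "[ACG]", N = "[ACGT]")

oracle_iupac_regex <- function(pattern) {
  paste(ORACLE_IUPAC[strsplit(pattern, "")[[1]]], collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                     "")[[1]]), collapse = "")
}

# All guide-site starts (0-based, full protospacer+PAM interval) on both
# strands, via overlapping regex matches.
oracle_guide_sites <- function(seq, proto_len, pam_patterns) {
  hits <- list()
  for (pam in pam_patterns) {
    fwd <- paste0("(?=(", strrep("[ACGT]", proto_len),
                  oracle_iupac_regex(pam), "))")
    m <- gregexpr(fwd, seq, perl = TRUE)[[1]]
    if (m[1] != -1L)
      hits[[length(hits) + 1L]] <- data.frame(start = as.integer(m) - 1L,
                                              strand = "+")
    rev <- paste0("(?=(", oracle_iupac_regex(oracle_revcomp(pam)),
                  strrep("[ACGT]", proto_len), "))")
    m <- gregexpr(rev, seq, perl = TRUE)[[1]]
    if (m[1] != -1L)
      hits[[length(hits) + 1L]] <- data.frame(start = as.integer(m) - 1L,
                                              strand = "-")
  }
  if (!length(hits)) return(data.frame(start = integer(), strand = character()))
  unique(do.call(rbind, hits))
}

# Exhaustive pairing of every SpCas9 site with every partner site:
# brute-force O(n * m) comparison, vectorised over the SpCas9 sites.
oracle_composites <- function(seq, sp_pams, partner_proto_len, partner_pams,
                              spacing, orientations = c("D1", "D2")) {
  sp <- oracle_guide_sites(seq, 20L, sp_pams)
  pa <- oracle_guide_sites(seq, partner_proto_len, partner_pams)
  if (!nrow(sp) || !nrow(pa))
    return(data.frame(sp_start = integer(), sp_strand = character(),
                      partner_start = integer(), partner_strand = character(),
                      orientation = character(), spacing_x = integer()))
  sp_len <- 23L
  pa_len <- partner_proto_len + nchar(partner_pams[1])
  sp_start <- sp$start; sp_end <- sp$start + sp_len
  out <- vector("list", nrow(pa))
  for (i in seq_len(nrow(pa))) {
    p_start <- pa$start[i]; p_end <- p_start + pa_len
    gap <- pmax(p_start - sp_end, sp_start - p_end)
    keep <- which(gap >= spacing[1] & gap <= spacing[2])
    if (!length(keep)) next
    right_of_sp <- p_start >= sp_end[keep]
    downstream <- ifelse(sp$strand[keep] == "+", right_of_sp, !right_of_sp)
    same <- sp$strand[keep] == pa$strand[i]
    label <- ifelse(downstream, ifelse(same, "D1", "D2"),
                    ifelse(same, "D3", "D4"))
    sel <- label %in% orientations
    if (!any(sel)) next
    out[[i]] <- data.frame(sp_start = sp_start[keep][sel],
                           sp_strand = sp$strand[keep][sel],
                           partner_start = p_start,
                           partner_strand = pa$strand[i],
                           orientation = label[sel],
                           spacing_x = gap[keep][sel])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(sp_start = integer(), sp_strand = character(),
                      partner_start = integer(), partner_strand = character(),
                      orientation = character(), spacing_x = integer()))
  do.call(rbind, out)
}

oracle_partner_spec <- function(partner) {
  # enforced partner patterns at full PAM length, as the scan defines them
  switch(partner,
         SaCas9 = list(proto_len = 21L, pams = "NNGRRT"),
         NmCas9 = list(proto_len = 24L, pams = "NNNNGATT"))
}

oracle_sp_pams <- function(mode) {
  if (mode == "expanded") c("NNG", "NGN") else "NGG"
}

composite_key <- function(df) {
  sort(paste(df$sp_start, df$sp_strand, df$partner_start, df$partner_strand,
             df$orientation, df$spacing_x))
}

# Plain-R affine-gap global alignment score (Gotoh, score only).
oracle_align_score <- function(query, ref, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -1) {
  q <- strsplit(query, "")[[1]]; r <- strsplit(ref, "")[[1]]
  n <- length(q); m <- length(r)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- gap_open + (j - 1) * gap_extend
  for (i in 2:(n + 1)) Y[i, 1] <- gap_open + (i - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (q[i - 1] == r[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(X[i, j - 1] + gap_extend,
                     max(M[i, j - 1], Y[i, j - 1]) + gap_open + gap_extend)
      Y[i, j] <- max(Y[i - 1, j] + gap_extend,
                     max(M[i - 1, j], X[i - 1, j]) + gap_open + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

impl_composite_key <- function(sites) {
  composite_key(data.frame(sp_start = sites$sp_start,
                           sp_strand = sites$sp_strand,
                           partner_start = sites$partner_start,
                           partner_strand = sites$partner_strand,
                           orientation = sites$orientation,
                           spacing_x = sites$spacing_x))
}
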