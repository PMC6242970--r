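# Synthetic data: amplicon references, molecules drawn from a repair-outcome
# mixture, UMI-tagged PCR-duplicated libraries, and genomes with planted
# composite sites. Every generator is a pure function of its arguments and
# the R random number generator state (or an explicit seed).

random_dna <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# Break homopolymer runs longer than max_run by resampling every
# (max_run + 1)-th base of the run. Keeps indel placements unambiguous
# enough that left-normalised events stay within the attribution window.
cap_homopolymers <- function(chars, max_run = 3L) {
  repeat {
    r <- rle(chars)
    bad <- which(r$lengths > max_run)
    if (!length(bad)) break
    ends <- cumsum(r$lengths)
    for (b in bad) {
      start <- ends[b] - r$lengths[b] + 1L
      fix <- seq(start + max_run, ends[b], by = max_run + 1L)
      for (i in fix)
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  chars
}

#' Simulate an amplicon reference with two cut junctions
#'
#' Generates a random sequence of the requested length and GC content with
#' homopolymer runs capped at `max_homopolymer` (so that simulated indel
#' events have essentially unambiguous placement), annotated with the two
#' cut junctions.
#'
#' @param length Reference length in nt (default 200).
#' @param gc GC fraction (default 0.5).
#' @param cut_a,cut_b Cut junctions (defaults 80 and 140).
#' @param seed Optional integer seed.
#' @param ref_id Identifier.
#' @param max_homopolymer Maximum homopolymer run length (default 3).
#' @return An [amplicon_reference()].
#' @export
simulate_reference <- function(length = 200L, gc = 0.5, cut_a = 80L,
                               cut_b = 140L, seed = NULL,
                               ref_id = "sim_amplicon", max_homopolymer = 3L) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  if (!(cut_a > 0 && cut_a < cut_b && cut_b < length))
    abort("cut junctions must satisfy 0 < cut_a < cut_b < length")
  chars <- strsplit(random_dna(length, gc), "")[[1]]
  chars <- cap_homopolymers(chars, max_homopolymer)
  amplicon_reference(paste(chars, collapse = ""), cut_a, cut_b, ref_id)
}

# Left-normalised placement of a deletion of [pos, pos + len) (0-based).
normalize_deletion <- function(chars, pos, len) {
  while (pos > 0L && chars[pos] == chars[pos + len]) pos <- pos - 1L
  pos
}

# Left-normalised placement of an insertion at split point pos (0-based).
normalize_insertion <- function(chars, pos, ins) {
  len <- length(ins)
  while (pos > 0L && ins[len] == chars[pos]) {
    ins <- c(chars[pos], ins[-len])
    pos <- pos - 1L
  }
  pos
}

# Draw a truncated geometric indel length in 1..max_len.
draw_indel_length <- function(geom_prob, max_len) {
  min(1L + rgeom(1L, geom_prob), max_len)
}

# Place one indel event whose left-normalised position stays within
# `window` of `cut` and farther than `window` from `other_cut`.
draw_cut_indel <- function(chars, cut, other_cut, window, geom_prob, max_len) {
  n <- length(chars)
  for (try in 1:100) {
    len <- draw_indel_length(geom_prob, max_len)
    if (runif(1) < 0.5) {
      s <- sample.int(len + 1L, 1L) - 1L      # 0..len: event contains the cut
      pos <- cut - s
      if (pos < 1L || pos + len > n - 1L) next
      npos <- normalize_deletion(chars, pos, len)
      d_cut <- event_cut_distance("deletion", npos, len, cut)
      d_other <- event_cut_distance("deletion", npos, len, other_cut)
      if (d_cut <= window && d_other > window)
        return(list(type = "deletion", pos = pos, len = len, ins = NULL))
    } else {
      pos <- cut + sample(-2:2, 1L)
      if (pos < 1L || pos > n - 1L) next
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      npos <- normalize_insertion(chars, pos, ins)
      d_cut <- event_cut_distance("insertion", npos, len, cut)
      d_other <- event_cut_distance("insertion", npos, len, other_cut)
      if (d_cut <= window && d_other > window)
        return(list(type = "insertion", pos = pos, len = len, ins = ins))
    }
  }
  abort("could not place an indel within the attribution window")
}

apply_indel <- function(chars, ev) {
  if (ev$type == "deletion") {
    if (ev$len >= 1L) chars <- chars[-seq(ev$pos + 1L, ev$pos + ev$len)]
    chars
  } else {
    append(chars, ev$ins, after = ev$pos)
  }
}

#' Simulate one molecule of a given repair-outcome class
#'
#' Precise deletions join the two blunt cut junctions exactly; imprecise
#' deletions shift the junction by per-end offsets drawn uniformly from
#' `-imprecise_max_offset..imprecise_max_offset` (resampled while the two
#' offsets are equal, since equal shifts yield a product that differs from
#' the precise junction only by substitutions and is therefore outside the
#' indel-based imprecise class); single- and double-cut indel classes place
#' a truncated-geometric-length insertion or deletion at the respective
#' cut(s), accepting only placements whose left-normalised event stays
#' within `window` of the cut; inversions reinsert the intervening segment
#' in exact reverse complement.
#'
#' Uses the current RNG state; seed the caller for reproducibility.
#'
#' @param class One of [lesion_classes()].
#' @param ref An [amplicon_reference()].
#' @param window Indel placement half-window (default 5, matching the
#'   classifier's attribution window).
#' @param indel_geom_prob Geometric length parameter (default 0.3).
#' @param max_indel Maximum indel length (default 20).
#' @param imprecise_max_offset Maximum junction offset (default 10).
#' @return A list with `sequence` and `detail` (a human-readable event
#'   description).
#' @export
simulate_molecule <- function(class, ref, window = 5L, indel_geom_prob = 0.3,
                              max_indel = 20L, imprecise_max_offset = 10L) {
  stopifnot(class %in% LESION_CLASSES)
  chars <- strsplit(ref$sequence, "")[[1]]
  ca <- ref$cut_a; cb <- ref$cut_b; n <- length(chars)

  if (class == "UNEDITED")
    return(list(sequence = ref$sequence, detail = ""))
  if (class == "PRECISE_DELETION")
    return(list(sequence = paste(c(chars[seq_len(ca)], chars[(cb + 1L):n]),
                                 collapse = ""),
                detail = sprintf("del:%d-%d", ca, cb)))
  if (class == "INVERSION")
    return(list(sequence = paste(c(chars[seq_len(ca)],
                                   rev(chartr("ACGT", "TGCA",
                                              chars[(ca + 1L):cb])),
                                   chars[(cb + 1L):n]), collapse = ""),
                detail = sprintf("inv:%d-%d", ca, cb)))
  if (class == "IMPRECISE_DELETION") {
    repeat {
      da <- sample(-imprecise_max_offset:imprecise_max_offset, 1L)
      db <- sample(-imprecise_max_offset:imprecise_max_offset, 1L)
      if (da != db && ca + da >= 1L && cb + db <= n - 1L) break
    }
    return(list(sequence = paste(c(chars[seq_len(ca + da)],
                                   chars[(cb + db + 1L):n]), collapse = ""),
                detail = sprintf("del:%d-%d", ca + da, cb + db)))
  }

  events <- list()
  if (class %in% c("SP_INDEL", "BOTH_INDEL"))
    events <- c(events, list(draw_cut_indel(chars, ca, cb, window,
                                            indel_geom_prob, max_indel)))
  if (class %in% c("PARTNER_INDEL", "BOTH_INDEL"))
    events <- c(events, list(draw_cut_indel(chars, cb, ca, window,
                                            indel_geom_prob, max_indel)))
  # apply right-most first so earlier coordinates stay valid
  events <- events[order(vapply(events, `[[`, integer(1), "pos"),
                         decreasing = TRUE)]
  out <- chars
  for (ev in events) out <- apply_indel(out, ev)
  detail <- paste(vapply(events, function(e)
    sprintf("%s:%d:%d", e$type, e$pos, e$len), character(1)),
    collapse = ";")
  list(sequence = paste(out, collapse = ""), detail = detail)
}

#' Simulation configuration for UMI-tagged amplicon libraries
#'
#' Defaults describe the study-scale conditions the package is tested
#' against: a 200-nt amplicon cut at 80 and 140, a mixture dominated by
#' precise deletions, per-base substitution error of 0.1%, PCR copy counts
#' uniform on 4--30, 10-nt UMIs, and constant Q37 qualities.
#'
#' @param reference An [amplicon_reference()] or a list with `length`, `gc`,
#'   `cut_a`, `cut_b` passed to [simulate_reference()].
#' @param mixture Named probability vector over [lesion_classes()]; must sum
#'   to 1.
#' @param n_molecules Number of molecules (default 500).
#' @param error_rate Per-base substitution error applied independently to
#'   every read copy (default 0.001).
#' @param copy_range Inclusive integer range of per-molecule PCR copy
#'   counts, drawn uniformly (default `c(4, 30)`); use `c(k, k)` for fixed
#'   copies.
#' @param umi_length UMI length (default 10).
#' @param quality_char Constant Phred+33 quality character (default `"F"`,
#'   Q37).
#' @param window,indel_geom_prob,max_indel,imprecise_max_offset Molecule
#'   simulation parameters, see [simulate_molecule()].
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(reference = list(length = 200L, gc = 0.5,
                                        cut_a = 80L, cut_b = 140L),
                       mixture = c(UNEDITED = 0.20, PRECISE_DELETION = 0.60,
                                   IMPRECISE_DELETION = 0.05,
                                   SP_INDEL = 0.05, PARTNER_INDEL = 0.05,
                                   BOTH_INDEL = 0.025, INVERSION = 0.025),
                       n_molecules = 500L, error_rate = 0.001,
                       copy_range = c(4L, 30L), umi_length = 10L,
                       quality_char = "F", window = 5L,
                       indel_geom_prob = 0.3, max_indel = 20L,
                       imprecise_max_offset = 10L, seed = NULL) {
  if (!all(names(mixture) %in% LESION_CLASSES))
    abort("mixture names must be lesion classes")
  if (abs(sum(mixture) - 1) > 1e-8) abort("mixture must sum to 1")
  if (error_rate < 0 || error_rate > 1) abort("error_rate must lie in [0, 1]")
  stopifnot(length(copy_range) == 2L, copy_range[1] >= 1L,
            copy_range[1] <= copy_range[2])
  structure(list(reference = reference, mixture = mixture,
                 n_molecules = as.integer(n_molecules),
                 error_rate = error_rate,
                 copy_range = as.integer(copy_range),
                 umi_length = as.integer(umi_length),
                 quality_char = quality_char, window = as.integer(window),
                 indel_geom_prob = indel_geom_prob,
                 max_indel = as.integer(max_indel),
                 imprecise_max_offset = as.integer(imprecise_max_offset),
                 seed = seed),
            class = "sim_config")
}

add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    chars <- strsplit(s, "")[[1]]
    for (i in pos)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a UMI-tagged amplicon sequencing library
#'
#' Draws molecules from the configured repair-outcome mixture, assigns each
#' a random UMI (collisions possible and recorded), replicates each
#' molecule according to the copy-count distribution, applies independent
#' per-base substitution errors to every read copy, and emits constant-
#' quality FASTQ-style records (UMI at the 5' end of the read) together
#' with the per-molecule truth table.
#'
#' @param config A [sim_config()].
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`),
#'   `truth` (tibble: `molecule_id`, `umi`, `class`, `true_sequence`,
#'   `copies`, `detail`), and `ref` (the [amplicon_reference()] used).
#' @export
simulate_library <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ref <- config$reference
  if (!inherits(ref, "amplicon_reference"))
    ref <- simulate_reference(length = ref$length, gc = ref$gc %||% 0.5,
                              cut_a = ref$cut_a, cut_b = ref$cut_b)

  n <- config$n_molecules
  classes <- sample(names(config$mixture), n, replace = TRUE,
                    prob = config$mixture)
  mols <- lapply(classes, simulate_molecule, ref = ref,
                 window = config$window,
                 indel_geom_prob = config$indel_geom_prob,
                 max_indel = config$max_indel,
                 imprecise_max_offset = config$imprecise_max_offset)
  umis <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), config$umi_length, replace = TRUE),
          collapse = ""), character(1))
  copies <- if (config$copy_range[1] == config$copy_range[2])
    rep(config$copy_range[1], n)
  else
    sample(seq(config$copy_range[1], config$copy_range[2]), n, replace = TRUE)

  truth <- tibble(
    molecule_id = sprintf("mol%05d", seq_len(n)),
    umi = umis,
    class = classes,
    true_sequence = vapply(mols, `[[`, character(1), "sequence"),
    copies = as.integer(copies),
    detail = vapply(mols, `[[`, character(1), "detail"))

  idx <- rep.int(seq_len(n), copies)
  copy_no <- sequence(copies)
  raw <- paste0(truth$umi[idx], truth$true_sequence[idx])
  seqs <- add_substitution_errors(raw, config$error_rate)
  reads <- tibble(
    read_id = sprintf("%s_copy%03d", truth$molecule_id[idx], copy_no),
    sequence = seqs,
    quality = strrep(config$quality_char, nchar(seqs)))

  list(reads = reads, truth = truth, ref = ref)
}

# ---- genomes with planted composite sites ----------------------------------

partner_pam_example <- function(enzyme) {
  # A concrete PAM sequence matching the canonical pattern.
  switch(enzyme$name,
         SaCas9 = "TTGAGT",    # NNGRRT
         NmCas9 = "TTTTGATT",  # NNNNGATT
         abort("no example PAM for this enzyme"))
}

#' Simulate a genome with planted composite target sites
#'
#' Generates a random background contig, plants `n_composites` composite
#' sites (SpCas9 site, intervening spacer, partner site) at well-separated
#' positions with orientations and spacings drawn from the requested sets,
#' then scrubs the background of accidental composites under the queried
#' parameter window: background partner-PAM cores are destroyed, and an
#' enumerate-and-mask loop mutates (to A/T) a PAM base of every remaining
#' spurious composite until the scan recovers exactly the planted truth.
#' Planted PAM intervals are protected from mutation.
#'
#' @param n_composites Number of composite sites to plant (default 10).
#' @param partner Partner enzyme (`"SaCas9"` or `"NmCas9"`).
#' @param mode `"canonical"` or `"expanded"` (the parameter window being
#'   scrubbed against).
#' @param spacing_range Spacing window; `NULL` for the mode default.
#' @param orientations Orientations to draw from and scrub against
#'   (default `c("D1", "D2")`).
#' @param genome_length Contig length in nt (default 20000).
#' @param gc Background GC fraction (default 0.5).
#' @param seed Optional integer seed.
#' @param contig_name Contig identifier.
#' @param max_scrub_iter Iteration cap for the mask loop (default 60).
#' @return A list with `genome` (named character vector of one contig) and
#'   `truth` (tibble of planted composites in `composite_sites` column
#'   layout).
#' @export
simulate_genome_with_sites <- function(n_composites = 10L,
                                       partner = "SaCas9",
                                       mode = c("canonical", "expanded"),
                                       spacing_range = NULL,
                                       orientations = c("D1", "D2"),
                                       genome_length = 20000L, gc = 0.5,
                                       seed = NULL,
                                       contig_name = "sim_contig",
                                       max_scrub_iter = 60L) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  partner <- as_cas9_enzyme(partner)
  sp <- cas9_presets("SpCas9")
  if (is.null(spacing_range)) spacing_range <- default_spacing_range(mode)
  spacing_range <- as.integer(spacing_range)
  n_composites <- as.integer(n_composites)
  genome_length <- as.integer(genome_length)

  sp_len <- sp$protospacer_length + sp$pam_length
  pa_len <- partner$protospacer_length + partner$pam_length
  cassette_max <- sp_len + spacing_range[2] + pa_len
  margin <- spacing_range[2] + sp_len + 200L
  stride <- cassette_max + margin
  if (n_composites > 0L && n_composites * stride + margin > genome_length)
    abort("infeasible packing: genome too short for the requested composites")

  chars <- strsplit(random_dna(genome_length, gc), "")[[1]]
  protected <- integer(0)
  truth <- list()

  if (n_composites > 0L) {
    slots <- margin + (seq_len(n_composites) - 1L) * stride
    for (i in seq_len(n_composites)) {
      # In expanded mode any planted G spawns a second, one-base-shifted
      # SpCas9 site (the same G read as NNG instead of NGN), so the SpCas9
      # PAM carries a single required G and the spacing is pinned to the
      # window's upper edge, which pushes that twin's spacing out of range.
      if (mode == "expanded") {
        x <- spacing_range[2]
        sp_pam_seq <- "TGA"                        # matches NGN only
      } else {
        x <- sample(seq(spacing_range[1], spacing_range[2]), 1L)
        sp_pam_seq <- "TGG"
      }
      ori <- if (length(orientations) > 1L) sample(orientations, 1L)
             else orientations
      p <- slots[i]                                # sp site start (0-based)
      sp_seq <- c(strsplit(random_dna(sp$protospacer_length, 0.5), "")[[1]],
                  strsplit(sp_pam_seq, "")[[1]])
      q <- p + sp_len + x                          # partner site start
      pa_site <- paste0(random_dna(partner$protospacer_length, 0.5),
                        partner_pam_example(partner))
      if (ori == "D1") {                           # partner on + strand
        pa_seq <- strsplit(pa_site, "")[[1]]
        pa_strand <- "+"
        pa_cut <- q + partner$protospacer_length - partner$cut_offset
      } else {                                     # D2: partner on - strand
        pa_seq <- strsplit(revcomp(pa_site), "")[[1]]
        pa_strand <- "-"
        pa_cut <- q + partner$pam_length + partner$cut_offset
      }
      chars[(p + 1L):(p + sp_len)] <- sp_seq
      chars[(q + 1L):(q + pa_len)] <- pa_seq
      # protect the PAM intervals of both planted sites
      sp_pam_iv <- (p + sp$protospacer_length + 1L):(p + sp_len)
      pa_pam_iv <- if (pa_strand == "+")
        (q + partner$protospacer_length + 1L):(q + pa_len)
      else
        (q + 1L):(q + partner$pam_length)
      protected <- c(protected, sp_pam_iv, pa_pam_iv)
      truth[[i]] <- tibble(
        contig = contig_name,
        sp_start = p, sp_end = p + sp_len, sp_strand = "+",
        sp_cut = p + sp$protospacer_length - sp$cut_offset,
        partner_start = q, partner_end = q + pa_len,
        partner_strand = pa_strand, partner_cut = as.integer(pa_cut),
        orientation = ori, spacing_x = x)
    }
  }
  truth <- if (length(truth)) bind_rows(truth) else
    empty_composite_sites(mode)[0, c("contig", "sp_start", "sp_end",
                                     "sp_strand", "sp_cut", "partner_start",
                                     "partner_end", "partner_strand",
                                     "partner_cut", "orientation",
                                     "spacing_x")]
  protected <- unique(protected)

  genome_str <- function() setNames(paste(chars, collapse = ""), contig_name)

  # Mutate one PAM base that the match actually requires: a G becomes T, a C
  # becomes A (A/T never satisfy a G/C requirement, so progress is monotone).
  # When no unprotected G/C is left (a planted G can seed a background core
  # whose remaining required bases are A/T), flip a random unprotected
  # position between A and T, which breaks R/Y/T/A requirements; repeated
  # rounds then converge on a required base.
  break_pam <- function(ivs) {
    iv <- setdiff(ivs, protected)
    if (!length(iv)) return(FALSE)
    gc_iv <- iv[chars[iv] %in% c("G", "C")]
    if (length(gc_iv)) {
      chars[gc_iv[1]] <<- if (chars[gc_iv[1]] == "G") "T" else "A"
    } else {
      i <- iv[sample.int(length(iv), 1L)]
      chars[i] <<- if (chars[i] == "A") "T" else "A"
    }
    TRUE
  }

  # First pass: destroy every background partner-PAM core.
  pa_sites <- enumerate_guide_sites(genome_str(), partner)
  if (nrow(pa_sites)) {
    planted_keys <- paste(truth$partner_start, truth$partner_strand)
    for (j in seq_len(nrow(pa_sites))) {
      if (paste(pa_sites$start[j], pa_sites$strand[j]) %in% planted_keys) next
      break_pam((pa_sites$pam_start[j] + 1L):(pa_sites$pam_end[j]))
    }
  }

  truth_key <- function(df) paste(df$sp_start, df$sp_strand,
                                  df$partner_start, df$partner_strand)
  for (iter in seq_len(max_scrub_iter)) {
    found <- enumerate_composite_sites(genome_str(), partner, mode,
                                       spacing_range, orientations)
    fk <- truth_key(found); tk <- truth_key(truth)
    if (!all(tk %in% fk))
      abort("internal error: a planted composite was destroyed during scrubbing")
    spurious <- found[!fk %in% tk, , drop = FALSE]
    if (nrow(spurious) == 0L)
      return(list(genome = genome_str(), truth = truth))
    progressed <- FALSE
    for (j in seq_len(nrow(spurious))) {
      # mutate a PAM base of the spurious pair's SpCas9 site, else of its
      # partner site
      sp_pam_iv <- if (spurious$sp_strand[j] == "+")
        (spurious$sp_start[j] + sp$protospacer_length + 1L):(spurious$sp_end[j])
      else
        (spurious$sp_start[j] + 1L):(spurious$sp_start[j] + sp$pam_length)
      pa_pam_iv <- if (spurious$partner_strand[j] == "+")
        (spurious$partner_start[j] + partner$protospacer_length + 1L):(spurious$partner_end[j])
      else
        (spurious$partner_start[j] + 1L):(spurious$partner_start[j] + partner$pam_length)
      # an earlier mutation in this round may already have destroyed this
      # pair; only a full round with no mutation at all is a dead end
      if (break_pam(sp_pam_iv) || break_pam(pa_pam_iv)) progressed <- TRUE
    }
    if (!progressed)
      abort("cannot scrub spurious composites overlapping planted PAMs")
  }
  abort("background scrubbing did not converge; try another seed or a longer genome")
}
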