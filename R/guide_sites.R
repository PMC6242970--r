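# Guide-site enumeration: scan a genome for protospacer+PAM occurrences.
#
# All coordinates are 0-based, half-open. A "full site" interval spans the
# protospacer plus the PAM. On the + strand the PAM immediately follows the
# protospacer; on the - strand it immediately precedes it (in reference
# coordinates). The cut junction is the number of contig bases retained to
# the left of the blunt double-strand break.

#' Predict the blunt cut junction of a guide site
#'
#' The break is placed `cut_offset` nucleotides 5' of the PAM on the
#' protospacer strand and returned as a split point: the count of contig
#' bases to the left of the cut. For a + strand site this is
#' `proto_end - cut_offset`; for a - strand site, `proto_start + cut_offset`.
#'
#' @param proto_start,proto_end 0-based half-open protospacer interval(s).
#' @param strand `"+"` or `"-"` (vectorised).
#' @param cut_offset Offset from the PAM-proximal protospacer end (default 3).
#' @return Integer vector of cut junctions.
#' @export
#' @examples
#' predict_cut_junction(100, 120, "+")  # 117
#' predict_cut_junction(100, 120, "-")  # 103
predict_cut_junction <- function(proto_start, proto_end, strand,
                                 cut_offset = 3L) {
  stopifnot(all(strand %in% c("+", "-")))
  ifelse(strand == "+",
         as.integer(proto_end) - as.integer(cut_offset),
         as.integer(proto_start) + as.integer(cut_offset))
}

# Normalise genome input to an uppercase named DNAStringSet.
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- read_genome_fasta(genome)
  } else if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- if (length(genome) == 1L) "contig" else
        paste0("contig", seq_along(genome))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  } else if (!methods::is(genome, "DNAStringSet")) {
    abort("genome must be a named character vector, DNAStringSet, or FASTA path")
  }
  if (length(genome) == 0L) return(genome)
  if (is.null(names(genome)) || any(names(genome) == ""))
    abort("all genome contigs must be named")
  genome
}

# Effective full-length PAM patterns used in a scan: the enforced core,
# left-padded with N to the canonical PAM length.
effective_pam_set <- function(enzyme, mode = c("canonical", "expanded")) {
  mode <- match.arg(mode)
  pad <- function(core) {
    paste0(strrep("N", enzyme$pam_length - nchar(core)), core)
  }
  if (mode == "expanded" && length(enzyme$pam_expanded))
    return(vapply(enzyme$pam_expanded, pad, character(1), USE.NAMES = FALSE))
  pad(enzyme$pam_search_core)
}

#' Enumerate guide sites in a genome
#'
#' Scans every contig, both strands, for positions where a full site
#' (protospacer + PAM) fits inside the contig and the PAM matches one of the
#' patterns in `pam_set`. Sites whose genomic sequence contains any non-ACGT
#' letter (assembly `N`s and other ambiguity codes) are discarded. A site
#' matching several patterns is reported once.
#'
#' @param genome Named character vector of contigs, a
#'   [Biostrings::DNAStringSet], or a FASTA file path.
#' @param enzyme A [cas9_enzyme()] or preset name.
#' @param pam_set Character vector of PAM patterns (full PAM length, or
#'   shorter cores which are left-padded with `N`). Defaults to the enzyme's
#'   enforced scan core.
#' @return A tibble with one row per site: `contig`, `start`, `end` (full
#'   site, 0-based half-open), `strand`, `enzyme`, `proto_start`,
#'   `proto_end`, `pam_start`, `pam_end`, `pam_seq`, `cut_junction`, sorted
#'   by (contig, start, strand).
#' @export
#' @examples
#' g <- c(chr = paste0(strrep("A", 20), "TGGTTTT"))
#' enumerate_guide_sites(g, "SpCas9")
enumerate_guide_sites <- function(genome, enzyme, pam_set = NULL) {
  enzyme <- as_cas9_enzyme(enzyme)
  genome <- as_genome(genome)
  if (is.null(pam_set)) pam_set <- effective_pam_set(enzyme, "canonical")
  pam_set <- vapply(pam_set, function(p) {
    check_iupac(p)
    if (nchar(p) > enzyme$pam_length)
      abort("PAM pattern longer than the enzyme's PAM")
    paste0(strrep("N", enzyme$pam_length - nchar(p)), p)
  }, character(1), USE.NAMES = FALSE)

  if (length(genome) == 0L) return(empty_guide_sites())

  plen <- enzyme$protospacer_length
  site_len <- plen + enzyme$pam_length
  out <- vector("list", length(genome) * length(pam_set) * 2L)
  k <- 0L
  for (ci in seq_along(genome)) {
    contig <- genome[[ci]]
    cname <- names(genome)[ci]
    if (length(contig) < site_len) next
    for (pam in pam_set) {
      fwd <- Biostrings::DNAString(paste0(strrep("N", plen), pam))
      hits <- Biostrings::matchPattern(fwd, contig, fixed = "subject")
      if (length(hits)) {
        k <- k + 1L
        out[[k]] <- tibble(
          contig = cname,
          start = BiocGenerics::start(hits) - 1L,  # to 0-based
          strand = "+",
          site_seq = as.character(hits))
      }
      rev <- Biostrings::DNAString(revcomp_pattern(paste0(strrep("N", plen), pam)))
      hits <- Biostrings::matchPattern(rev, contig, fixed = "subject")
      if (length(hits)) {
        k <- k + 1L
        out[[k]] <- tibble(
          contig = cname,
          start = BiocGenerics::start(hits) - 1L,
          strand = "-",
          site_seq = as.character(hits))
      }
    }
  }
  if (k == 0L) return(empty_guide_sites())
  sites <- bind_rows(out[seq_len(k)])
  # Non-ACGT letters anywhere in the site disqualify it.
  sites <- sites[grepl("^[ACGT]+$", sites$site_seq), , drop = FALSE]
  if (nrow(sites) == 0L) return(empty_guide_sites())
  sites <- distinct(sites, .data$contig, .data$start, .data$strand,
                    .keep_all = TRUE)

  enz_name <- enzyme$name
  cut_off <- enzyme$cut_offset
  sites <- mutate(
    sites,
    end = .data$start + site_len,
    proto_start = ifelse(.data$strand == "+", .data$start,
                         .data$start + enzyme$pam_length),
    proto_end = .data$proto_start + plen,
    pam_start = ifelse(.data$strand == "+", .data$proto_end,
                       .data$start),
    pam_end = .data$pam_start + enzyme$pam_length,
    pam_seq = ifelse(.data$strand == "+",
                     substr(.data$site_seq, plen + 1L, site_len),
                     revcomp(substr(.data$site_seq, 1L, enzyme$pam_length))),
    enzyme = enz_name,
    cut_junction = predict_cut_junction(.data$proto_start, .data$proto_end,
                                        .data$strand, cut_off))
  sites <- select(sites, "contig", "start", "end", "strand", "enzyme",
                  "proto_start", "proto_end", "pam_start", "pam_end",
                  "pam_seq", "cut_junction")
  sites <- arrange(sites, .data$contig, .data$start, .data$strand)
  class(sites) <- c("guide_sites", class(sites))
  sites
}

empty_guide_sites <- function() {
  out <- tibble(
    contig = character(), start = integer(), end = integer(),
    strand = character(), enzyme = character(),
    proto_start = integer(), proto_end = integer(),
    pam_start = integer(), pam_end = integer(), pam_seq = character(),
    cut_junction = integer())
  class(out) <- c("guide_sites", class(out))
  out
}
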