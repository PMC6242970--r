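# File IO: FASTQ/FASTA via Biostrings, BED-style site tables via readr.

#' Read merged amplicon reads from a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return A tibble with `read_id`, `sequence`, `quality` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata column when
  # converting the quality-scaled set; nothing user-visible is lost.
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tibble(
    read_id = names(x) %||% as.character(seq_along(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x))))
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  check_read_table(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a (multi-contig) genome or amplicon FASTA
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet]. Errors on an empty file.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    abort(paste0("FASTA file contains no sequences: ", path))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

check_read_table <- function(reads) {
  need <- c("read_id", "sequence", "quality")
  if (!all(need %in% names(reads)))
    abort(paste0("read table must have columns: ", paste(need, collapse = ", ")))
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    abort("sequence and quality lengths differ")
  invisible(reads)
}

#' Write guide sites as BED6 (PAM in the name field)
#'
#' Coordinates are already 0-based half-open, matching BED.
#'
#' @param sites A `guide_sites` tibble.
#' @param path Output path.
#' @export
write_guide_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$contig, start = sites$start, end = sites$end,
    name = paste0(sites$enzyme, ":", sites$pam_seq),
    score = 0L, strand = sites$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write composite sites as BED6 plus extra columns
#'
#' BED6 fields describe the SpCas9 site; extra columns carry the partner
#' coordinates and strand, the orientation label, spacing, cut separation,
#' and scan mode.
#'
#' @param sites A `composite_sites` tibble.
#' @param path Output path.
#' @export
write_composite_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$contig, start = sites$sp_start, end = sites$sp_end,
    name = paste0("SpCas9-", sites$partner_enzyme, ":", sites$orientation),
    score = 0L, strand = sites$sp_strand,
    partner_start = sites$partner_start, partner_end = sites$partner_end,
    partner_strand = sites$partner_strand,
    orientation = sites$orientation, spacing_x = sites$spacing_x,
    cut_separation = sites$cut_separation,
    mode = sites$mode)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a composite-site BED written by [write_composite_sites_bed()]
#'
#' @param path BED file path.
#' @return A tibble with the coordinate, orientation and spacing columns.
#' @export
read_composite_sites_bed <- function(path) {
  cols <- c("contig", "sp_start", "sp_end", "name", "score", "sp_strand",
            "partner_start", "partner_end", "partner_strand",
            "orientation", "spacing_x", "cut_separation", "mode")
  readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                  col_types = readr::cols(
                    contig = "c", name = "c", sp_strand = "c",
                    partner_strand = "c", orientation = "c", mode = "c",
                    .default = "i"))
}
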