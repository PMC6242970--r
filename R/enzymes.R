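# Cas9 enzyme models: protospacer geometry, PAM patterns, cut offsets.

IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Construct a Cas9 enzyme model
#'
#' An enzyme model bundles the geometric constants a genome scan and a cut
#' predictor need: protospacer length, PAM length, the canonical PAM, the PAM
#' core actually enforced when scanning (leading `N` positions carry no
#' information), optional expanded PAM patterns, and the blunt-cut offset
#' measured in nucleotides from the PAM-proximal protospacer end.
#'
#' Three presets are available through [cas9_presets()]: SpCas9 (20-nt
#' protospacer, NGG), SaCas9 (21-nt, NNGRRT with enforced core GRRT), and
#' NmCas9 (24-nt, NNNNGATT with enforced core GATT). All three are modelled
#' as blunt cutters 3 bp 5' of the PAM; the offset is configurable to absorb
#' staggered-cut alternatives.
#'
#' @param name Enzyme identifier.
#' @param protospacer_length Protospacer length in nucleotides.
#' @param pam_canonical Canonical PAM as an IUPAC string; its length defines
#'   the PAM length.
#' @param pam_search_core The suffix-aligned sub-pattern of `pam_canonical`
#'   enforced in genome scans (defaults to the canonical PAM itself).
#' @param pam_expanded Character vector of alternative full-length PAM
#'   patterns for expanded-range scans (may be empty).
#' @param cut_offset Blunt-cut offset from the PAM-proximal protospacer end,
#'   in nucleotides; must satisfy `0 < cut_offset < protospacer_length`.
#' @return An object of class `cas9_enzyme` (a named list).
#' @export
#' @examples
#' cas9_enzyme("SpCas9", 20, "NGG")
cas9_enzyme <- function(name, protospacer_length, pam_canonical,
                        pam_search_core = pam_canonical,
                        pam_expanded = character(), cut_offset = 3L) {
  stopifnot(is.character(name), length(name) == 1L)
  protospacer_length <- as.integer(protospacer_length)
  cut_offset <- as.integer(cut_offset)
  check_iupac(pam_canonical)
  check_iupac(pam_search_core)
  for (p in pam_expanded) check_iupac(p)
  if (!(cut_offset > 0L && cut_offset < protospacer_length))
    abort("cut_offset must lie strictly inside the protospacer")
  if (nchar(pam_search_core) > nchar(pam_canonical))
    abort("pam_search_core cannot be longer than pam_canonical")
  structure(
    list(name = name,
         protospacer_length = protospacer_length,
         pam_length = nchar(pam_canonical),
         pam_canonical = pam_canonical,
         pam_search_core = pam_search_core,
         pam_expanded = as.character(pam_expanded),
         cut_offset = cut_offset),
    class = "cas9_enzyme")
}

check_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) > 0L)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_CLASSES))
  if (length(bad))
    abort(paste0("invalid IUPAC symbol(s) in pattern: ",
                 paste(unique(bad), collapse = ", ")))
  invisible(pattern)
}

#' @export
print.cas9_enzyme <- function(x, ...) {
  cat(sprintf("<cas9_enzyme> %s: %d-nt protospacer, PAM %s (scan core %s), cut offset %d\n",
              x$name, x$protospacer_length, x$pam_canonical,
              x$pam_search_core, x$cut_offset))
  if (length(x$pam_expanded))
    cat("  expanded PAMs:", paste(x$pam_expanded, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in enzyme presets
#'
#' @param name One of `"SpCas9"`, `"SaCas9"`, `"NmCas9"`; omit for the full
#'   named list.
#' @return A `cas9_enzyme`, or a named list of all three.
#' @export
#' @examples
#' cas9_presets("SaCas9")
cas9_presets <- function(name = NULL) {
  presets <- list(
    SpCas9 = cas9_enzyme("SpCas9", 20L, "NGG", "NGG", c("NNG", "NGN")),
    SaCas9 = cas9_enzyme("SaCas9", 21L, "NNGRRT", "GRRT"),
    NmCas9 = cas9_enzyme("NmCas9", 24L, "NNNNGATT", "GATT")
  )
  if (is.null(name)) return(presets)
  key <- match(tolower(name), tolower(names(presets)))
  if (is.na(key)) abort(paste0("unknown enzyme preset: ", name))
  presets[[key]]
}

as_cas9_enzyme <- function(x) {
  if (inherits(x, "cas9_enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) return(cas9_presets(x))
  abort("expected a cas9_enzyme or a preset name")
}

#' Match a nucleotide window against an IUPAC pattern
#'
#' A window matches when every base belongs to the IUPAC class of the
#' corresponding pattern symbol. Ambiguity classes are defined over
#' `A`, `C`, `G`, `T` only, so a genome `N` (or any other non-ACGT letter)
#' matches nothing -- including the pattern symbol `N`.
#'
#' @param window Nucleotide string, same length as `pattern`.
#' @param pattern IUPAC pattern string.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' match_pam("AGG", "NGG")   # TRUE
#' match_pam("GAAT", "GRRT") # TRUE: R = A or G
#' match_pam("GCGT", "GRRT") # FALSE: C is not in R
match_pam <- function(window, pattern) {
  stopifnot(is.character(window), length(window) == 1L)
  check_iupac(pattern)
  if (nchar(window) != nchar(pattern))
    abort("match_pam: window and pattern lengths differ")
  wb <- strsplit(toupper(window), "")[[1]]
  pb <- strsplit(toupper(pattern), "")[[1]]
  all(vapply(seq_along(pb),
             function(i) wb[i] %in% IUPAC_CLASSES[[pb[i]]],
             logical(1)))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse complement of an IUPAC pattern (for minus-strand scans).
revcomp_pattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(pattern), "")[[1]]]), collapse = "")
}
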