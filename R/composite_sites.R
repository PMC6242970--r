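# Composite-site enumeration: pair SpCas9 sites with partner-Cas9 sites
# under orientation and spacing constraints.

#' Orientation convention for composite sites
#'
#' A composite site pairs an SpCas9 site with a partner-Cas9 (SaCas9 or
#' NmCas9) site. Orientation is read along the strand of the SpCas9
#' protospacer: the partner is either downstream (3') or upstream (5') of
#' the SpCas9 site, and its protospacer lies on either the same or the
#' opposite strand. The default mapping labels these four geometries
#' D1--D4, with the two "active" configurations (SpCas9 protospacer
#' upstream of the partner site) being D1 (same strand) and D2 (opposite
#' strand); D3/D4 are their partner-first mirror images. Reading the
#' geometry along the SpCas9 strand (rather than along the reference)
#' makes the labels invariant under reverse complementation of the genome.
#'
#' Supply a modified map to `enumerate_composite_sites()` to remap labels.
#'
#' @return A named character vector with keys `downstream_same`,
#'   `downstream_opposite`, `upstream_same`, `upstream_opposite`.
#' @export
orientation_convention <- function() {
  c(downstream_same = "D1", downstream_opposite = "D2",
    upstream_same = "D3", upstream_opposite = "D4")
}

orientation_labels <- function(sp_strand, sp_start, sp_end,
                               partner_strand, partner_start, partner_end,
                               map = orientation_convention()) {
  downstream <- ifelse(sp_strand == "+",
                       partner_start >= sp_end,
                       partner_end <= sp_start)
  same <- sp_strand == partner_strand
  key <- paste0(ifelse(downstream, "downstream", "upstream"),
                ifelse(same, "_same", "_opposite"))
  unname(map[key])
}

default_spacing_range <- function(mode) {
  if (mode == "expanded") c(10L, 100L) else c(10L, 30L)
}

#' Enumerate composite dual-PAM target sites
#'
#' Finds all pairs of an SpCas9 site and a partner-Cas9 site on the same
#' contig whose full-site intervals (protospacer + PAM) do not overlap,
#' whose nearest-edge gap `spacing_x` lies inside `spacing_range`, and whose
#' orientation is in `orientations`. In `canonical` mode the SpCas9 PAM is
#' NGG and spacing defaults to 10--30 bp; in `expanded` mode the SpCas9 PAM
#' set is \{NNG, NGN\} and spacing defaults to 10--100 bp. The partner PAM
#' core (GRRT for SaCas9, GATT for NmCas9) is enforced at its canonical
#' offset in both modes.
#'
#' `within_functional_window` annotates (never filters) whether the distance
#' between the two predicted cut junctions is below `functional_window`,
#' the separation under which the tethered nuclease pair remains active.
#'
#' @param genome Genome input (see [enumerate_guide_sites()]).
#' @param partner Partner enzyme: `"SaCas9"`, `"NmCas9"`, or a
#'   [cas9_enzyme()].
#' @param mode `"canonical"` or `"expanded"`.
#' @param spacing_range Inclusive integer interval for the nearest-edge gap;
#'   `NULL` for the mode default.
#' @param orientations Orientation labels to keep (default `c("D1", "D2")`).
#' @param functional_window Cut-separation annotation threshold in bp
#'   (default 200).
#' @param orientation_map Label mapping, see [orientation_convention()].
#' @return A tibble of class `composite_sites`: one row per pair with SpCas9
#'   and partner coordinates/strands/cut junctions, `orientation`,
#'   `spacing_x`, `cut_separation`, `within_functional_window`, and `mode`.
#' @export
enumerate_composite_sites <- function(genome, partner,
                                      mode = c("canonical", "expanded"),
                                      spacing_range = NULL,
                                      orientations = c("D1", "D2"),
                                      functional_window = 200L,
                                      orientation_map = orientation_convention()) {
  mode <- match.arg(mode)
  partner <- as_cas9_enzyme(partner)
  sp <- cas9_presets("SpCas9")
  if (is.null(spacing_range)) spacing_range <- default_spacing_range(mode)
  spacing_range <- as.integer(spacing_range)
  stopifnot(length(spacing_range) == 2L, spacing_range[1] <= spacing_range[2],
            spacing_range[1] >= 0L)
  if (!all(orientations %in% orientation_map))
    abort("unknown orientation label(s); must appear in orientation_map")

  genome <- as_genome(genome)
  sp_sites <- enumerate_guide_sites(genome, sp, effective_pam_set(sp, mode))
  pa_sites <- enumerate_guide_sites(genome, partner,
                                    effective_pam_set(partner, "canonical"))
  pairs <- pair_sites(sp_sites, pa_sites, spacing_range)
  if (nrow(pairs) == 0L) return(empty_composite_sites(mode))

  pairs$orientation <- orientation_labels(
    pairs$sp_strand, pairs$sp_start, pairs$sp_end,
    pairs$partner_strand, pairs$partner_start, pairs$partner_end,
    orientation_map)
  pairs <- filter(pairs, .data$orientation %in% orientations)
  pairs <- mutate(
    pairs,
    cut_separation = abs(.data$partner_cut - .data$sp_cut),
    within_functional_window = .data$cut_separation < functional_window,
    mode = mode)
  pairs <- arrange(pairs, .data$contig, pmin(.data$sp_start, .data$partner_start),
                   .data$sp_start, .data$sp_strand, .data$partner_start,
                   .data$partner_strand)
  class(pairs) <- c("composite_sites", class(pairs))
  pairs
}

# Window-based pairing: for each partner site, locate SpCas9 sites whose
# nearest-edge gap falls inside the spacing range, on either side.
pair_sites <- function(sp_sites, pa_sites, spacing_range) {
  lo <- spacing_range[1]; hi <- spacing_range[2]
  out <- list()
  for (cname in intersect(unique(sp_sites$contig), unique(pa_sites$contig))) {
    sp <- sp_sites[sp_sites$contig == cname, , drop = FALSE]
    pa <- pa_sites[pa_sites$contig == cname, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    starts <- sp$start
    sp_len <- if (nrow(sp)) sp$end[1] - sp$start[1] else 0L
    in_window <- function(a, b) {
      # indices with starts in [a, b], via binary search on the sorted starts
      i1 <- findInterval(a - 1L, starts) + 1L
      i2 <- findInterval(b, starts)
      if (i1 > i2) integer(0) else seq.int(i1, i2)
    }
    for (i in seq_len(nrow(pa))) {
      p_start <- pa$start[i]; p_end <- pa$end[i]
      # SpCas9 site to the left: gap = p_start - sp_end
      idx_l <- in_window(p_start - hi - sp_len, p_start)
      # SpCas9 site to the right: gap = sp_start - p_end
      idx_r <- in_window(p_end + lo, p_end + hi)
      idx <- union(idx_l, idx_r)
      if (!length(idx)) next
      gap <- ifelse(sp$end[idx] <= p_start, p_start - sp$end[idx],
                    ifelse(sp$start[idx] >= p_end, sp$start[idx] - p_end,
                           -1L))
      keep <- gap >= lo & gap <= hi
      if (!any(keep)) next
      idx <- idx[keep]
      out[[length(out) + 1L]] <- tibble(
        contig = cname,
        sp_start = sp$start[idx], sp_end = sp$end[idx],
        sp_strand = sp$strand[idx], sp_cut = sp$cut_junction[idx],
        sp_pam = sp$pam_seq[idx],
        partner_enzyme = pa$enzyme[i],
        partner_start = p_start, partner_end = p_end,
        partner_strand = pa$strand[i], partner_cut = pa$cut_junction[i],
        partner_pam = pa$pam_seq[i],
        spacing_x = gap[keep])
    }
  }
  if (!length(out)) return(empty_composite_sites("canonical")[0, ])
  bind_rows(out)
}

empty_composite_sites <- function(mode) {
  out <- tibble(
    contig = character(),
    sp_start = integer(), sp_end = integer(), sp_strand = character(),
    sp_cut = integer(), sp_pam = character(),
    partner_enzyme = character(),
    partner_start = integer(), partner_end = integer(),
    partner_strand = character(), partner_cut = integer(),
    partner_pam = character(),
    spacing_x = integer(), orientation = character(),
    cut_separation = integer(), within_functional_window = logical(),
    mode = character())
  class(out) <- c("composite_sites", class(out))
  out
}

#' Compare the targeting range of a Cas9-Cas9 pair with SpCas9 alone
#'
#' Counts composite sites under both the canonical and the expanded
#' parameter set and SpCas9-alone NGG sites, and reports the ratios
#' composite / SpCas9-alone. Ratios are `NA` when the genome contains no
#' SpCas9 NGG site.
#'
#' @inheritParams enumerate_composite_sites
#' @return A one-row tibble with `n_sp_only_ngg`, `n_composite_canonical`,
#'   `n_composite_expanded`, `ratio_canonical`, `ratio_expanded`.
#' @export
compare_targeting_range <- function(genome, partner,
                                    orientations = c("D1", "D2"),
                                    functional_window = 200L) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) abort("genome is empty")
  partner <- as_cas9_enzyme(partner)
  sp_n <- nrow(enumerate_guide_sites(genome, "SpCas9"))
  n_can <- nrow(enumerate_composite_sites(genome, partner, "canonical",
                                          orientations = orientations,
                                          functional_window = functional_window))
  n_exp <- nrow(enumerate_composite_sites(genome, partner, "expanded",
                                          orientations = orientations,
                                          functional_window = functional_window))
  tibble(
    partner = partner$name,
    n_sp_only_ngg = sp_n,
    n_composite_canonical = n_can,
    n_composite_expanded = n_exp,
    ratio_canonical = if (sp_n > 0) n_can / sp_n else NA_real_,
    ratio_expanded = if (sp_n > 0) n_exp / sp_n else NA_real_)
}
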