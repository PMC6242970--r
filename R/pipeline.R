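# End-to-end orchestration: validated run configurations, the
# classification pipeline (reads -> molecules -> calls -> rates), the
# site-finder pipeline, and bit-stable table/report output.

#' Build a validated run configuration for the classification pipeline
#'
#' Unknown keys are rejected; validation happens before any computation.
#'
#' @param reads A read tibble (`read_id`, `sequence`, `quality`) or a FASTQ
#'   path.
#' @param reference An [amplicon_reference()], or a FASTA path combined with
#'   `cut_a`/`cut_b`.
#' @param outdir Output directory (created if missing).
#' @param sample_id Sample identifier.
#' @param cut_a,cut_b Cut junctions when `reference` is a FASTA path.
#' @param umi Use UMI consolidation (default `TRUE`); `FALSE` treats every
#'   read as one molecule (bulk mode).
#' @param umi_length,umi_end,min_support UMI parameters.
#' @param mean_q,min_q Quality-filter thresholds.
#' @param window Indel-attribution half-window.
#' @param large_deletion_mode Disable the identity filter.
#' @param min_identity Identity threshold.
#' @param controls Optional list of control `rate_table`s (or count-table
#'   TSV paths) for background subtraction.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A list of class `run_config`.
#' @export
run_config <- function(reads, reference, outdir, sample_id = "sample",
                       cut_a = NULL, cut_b = NULL,
                       umi = TRUE, umi_length = 10L,
                       umi_end = "5prime", min_support = 4L,
                       mean_q = 30, min_q = 24, window = 5L,
                       large_deletion_mode = FALSE, min_identity = 0.9,
                       controls = NULL, seed = NULL) {
  if (is.character(reference)) {
    if (is.null(cut_a) || is.null(cut_b))
      abort("cut_a and cut_b are required with a FASTA reference")
    fa <- read_genome_fasta(reference)
    reference <- amplicon_reference(as.character(fa[[1]]), cut_a, cut_b,
                                    ref_id = names(fa)[1])
  }
  stopifnot(inherits(reference, "amplicon_reference"))
  structure(list(reads = reads, reference = reference, outdir = outdir,
                 sample_id = sample_id, umi = isTRUE(umi),
                 umi_length = as.integer(umi_length), umi_end = umi_end,
                 min_support = as.integer(min_support),
                 mean_q = mean_q, min_q = min_q, window = as.integer(window),
                 large_deletion_mode = isTRUE(large_deletion_mode),
                 min_identity = min_identity, controls = controls,
                 seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "outdir")])
}

#' Run the classification pipeline
#'
#' Quality filtering, optional UMI extraction/grouping/consolidation,
#' classification against the candidate references, rate computation, and
#' optional background subtraction. Per-molecule calls, class counts, and
#' rates are written as TSV to the configured output directory together
#' with a JSON run report; the report (stage counters, configuration hash,
#' seed, package version) is returned invisibly. Outputs contain no
#' timestamps, so identical configurations produce byte-identical tables.
#'
#' @param config A [run_config()].
#' @return The run report (list of class `run_report`), invisibly.
#' @export
run_classification_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  reads <- config$reads
  if (is.character(reads)) reads <- read_fastq(reads)
  check_read_table(reads)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  counters <- list(reads_in = nrow(reads))
  filtered <- quality_filter(reads, config$mean_q, config$min_q)
  counters$reads_pass_quality <- nrow(filtered)

  if (config$umi) {
    umi_reads <- extract_umis(filtered, config$umi_length, config$umi_end)
    counters$reads_umi_ok <- nrow(umi_reads)
    counters$reads_too_short <- unname(attr(umi_reads, "counters")["reads_too_short"])
    molecules <- consolidate_umis(umi_reads, config$min_support)
    cc <- attr(molecules, "counters")
    counters$umi_groups <- unname(cc["umi_groups"])
    counters$umi_groups_rejected <- unname(cc["groups_rejected"])
    molecules <- tibble(molecule_id = molecules$umi,
                        sequence = molecules$sequence,
                        support = molecules$support)
  } else {
    molecules <- tibble(molecule_id = filtered$read_id,
                        sequence = filtered$sequence)
  }
  counters$molecules <- nrow(molecules)
  if (nrow(molecules) == 0L)
    abort("pipeline error [consolidate]: no molecules left after processing")

  calls <- classify_sample(molecules, config$reference,
                           window = config$window,
                           large_deletion_mode = config$large_deletion_mode,
                           min_identity = config$min_identity)
  counts <- lesion_count_table(calls, config$sample_id)
  counters$molecules_classified <-
    sum(counts$count[counts$class != "UNCLASSIFIED"])
  rates <- compute_rates(counts)

  if (!is.null(config$controls)) {
    controls <- lapply(config$controls, function(ctl) {
      if (is.character(ctl))
        ctl <- compute_rates(readr::read_tsv(ctl, show_col_types = FALSE))
      ctl
    })
    rates <- subtract_background(rates, controls)
  }

  calls_out <- select(as_tibble(calls), -"events")
  readr::write_tsv(calls_out, file.path(config$outdir, "calls.tsv"))
  readr::write_tsv(as_tibble(counts), file.path(config$outdir, "counts.tsv"))
  readr::write_tsv(as_tibble(rates), file.path(config$outdir, "rates.tsv"))

  report <- structure(list(
    pipeline = "classification",
    sample_id = config$sample_id,
    counters = counters,
    class_counts = setNames(as.list(counts$count), counts$class),
    total_lesion_rate_pct = total_lesion_rate(rates),
    precise_deletion_fraction = precise_deletion_fraction(rates),
    config_hash = config_hash(config),
    seed = config$seed,
    version = as.character(utils::packageVersion("dualcut")),
    tables = c("calls.tsv", "counts.tsv", "rates.tsv")),
    class = "run_report")
  jsonlite::write_json(unclass(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Run the composite-site finder
#'
#' Enumerates composite sites in a genome FASTA, writes them as BED6+ plus
#' a targeting-range summary TSV, and returns a run report.
#'
#' @param genome Genome FASTA path (or named character vector).
#' @param partner Partner enzyme name.
#' @param outdir Output directory.
#' @param mode `"canonical"` or `"expanded"`.
#' @param spacing_range Spacing window; `NULL` for the mode default.
#' @param orientations Orientation labels (default `c("D1", "D2")`).
#' @param functional_window Annotation threshold in bp (default 200).
#' @return The run report, invisibly.
#' @export
run_sitefinder <- function(genome, partner, outdir,
                           mode = c("canonical", "expanded"),
                           spacing_range = NULL,
                           orientations = c("D1", "D2"),
                           functional_window = 200L) {
  mode <- match.arg(mode)
  genome <- as_genome(genome)
  if (length(genome) == 0L)
    abort("pipeline error [sitefinder]: genome contains no sequences")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sites <- enumerate_composite_sites(genome, partner, mode, spacing_range,
                                     orientations,
                                     functional_window = functional_window)
  summary <- compare_targeting_range(genome, partner,
                                     orientations = orientations,
                                     functional_window = functional_window)
  write_composite_sites_bed(sites, file.path(outdir, "composite_sites.bed"))
  readr::write_tsv(summary, file.path(outdir, "targeting_range.tsv"))
  report <- structure(list(
    pipeline = "sitefinder",
    n_contigs = length(genome),
    genome_bp = sum(Biostrings::width(genome)),
    n_composite_sites = nrow(sites),
    summary = as.list(summary),
    version = as.character(utils::packageVersion("dualcut")),
    tables = c("composite_sites.bed", "targeting_range.tsv")),
    class = "run_report")
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s pipeline\n", x$pipeline))
  if (!is.null(x$counters))
    cat(paste0("  ", names(x$counters), ": ",
               unlist(x$counters), collapse = "\n"), "\n")
  if (!is.null(x$n_composite_sites))
    cat("  composite sites:", x$n_composite_sites, "\n")
  invisible(x)
}
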