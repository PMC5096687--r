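# Cohort-level reporting: per-genotype summary tables, fold changes and the
# end-to-end pipeline driver.

#' Summarize calls per (genotype, treatment) group
#'
#' Per-sample SNV/insertion/deletion counts are aggregated to group means
#' and sample standard deviations. Samples with zero calls still contribute
#' zeros; every call's sample must appear in the metadata.
#'
#' @param calls call table from [call_unique_mutations()] (or any data.frame
#'   with sample and type columns)
#' @param metadata data.frame with columns sample, genotype and optionally
#'   treatment
#' @return a `cohort_summary`: data.table with one row per group per
#'   mutation type (genotype, treatment, type, n, mean, sd)
#' @export
summarize_cohort <- function(calls, metadata) {
  metadata <- as.data.frame(metadata)
  assert_that(all(c("sample", "genotype") %in% names(metadata)),
              "metadata needs sample and genotype columns")
  if (!"treatment" %in% names(metadata)) metadata$treatment <- "none"
  calls <- as.data.frame(calls)
  unknown <- setdiff(unique(calls$sample), metadata$sample)
  if (length(unknown)) {
    stopf("calls reference unknown sample(s): %s",
          paste(unknown, collapse = ", "))
  }
  types <- c("SNV", "INS", "DEL")
  percell <- expand.grid(sample = metadata$sample, type = types,
                         stringsAsFactors = FALSE)
  cnt <- table(factor(calls$sample, levels = metadata$sample),
               factor(calls$type, levels = types))
  percell$count <- as.vector(cnt[cbind(match(percell$sample, metadata$sample),
                                       match(percell$type, types))])
  percell <- merge(percell, metadata, by = "sample")
  dt <- data.table::as.data.table(percell)
  out <- dt[, list(n = .N, mean = mean(count),
                   sd = if (.N > 1) stats::sd(count) else NA_real_),
            by = c("genotype", "treatment", "type")]
  data.table::setorderv(out, c("genotype", "treatment", "type"))
  structure(out[], class = c("cohort_summary", class(out)))
}

#' Fold change of group means
#'
#' @param summary a `cohort_summary` from [summarize_cohort()]
#' @param genotype,treatment group selector
#' @param baseline_genotype,baseline_treatment baseline group selector
#' @param type mutation type (default `"SNV"`)
#' @return ratio of the group mean to the baseline mean
#' @export
fold_change <- function(summary, genotype, treatment,
                        baseline_genotype, baseline_treatment = treatment,
                        type = "SNV") {
  pick <- function(g, tr) {
    idx <- which(summary$genotype == g & summary$treatment == tr &
                   summary$type == type)
    assert_that(length(idx) == 1L, "group (%s, %s, %s) not found", g, tr, type)
    summary$mean[idx]
  }
  b <- pick(baseline_genotype, baseline_treatment)
  if (b == 0) stopf("baseline mean is zero; fold change undefined")
  pick(genotype, treatment) / b
}

#' Run the full pipeline on a configuration
#'
#' Simulates a cohort (unless counts are supplied), calls unique mutations,
#' builds spectra and signature correlations, classifies deletions, runs the
#' group statistics and writes a JSON report plus TSV tables to `out_dir`.
#' Identical configurations and seeds give byte-identical reports.
#'
#' @param config a list (see [read_run_config()]) with entries `genome`
#'   (chromosome_lengths, gc_content), `cohort` (samples, burdens, ...),
#'   `noise`, `caller`, `baseline_genotype`, `seed`
#' @param out_dir output directory
#' @param quiet suppress stage logging
#' @return the report list (invisibly written as `report.json`)
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  t0 <- Sys.time()
  log <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%5.1fs] %s",
                                as.numeric(Sys.time() - t0, units = "secs"),
                                sprintf(fmt, ...)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  log("simulate: genome + cohort (seed %d)", seed)
  gspec <- genome_spec(config$genome$chromosome_lengths,
                       config$genome$gc_content %||% 0.42, seed)
  reference <- generate_reference(gspec)
  meta <- as.data.frame(config$cohort$samples)
  cspec <- cohort_spec(
    samples = meta,
    snv_burden = config$cohort$snv_burden %||% 0L,
    ins_burden = config$cohort$ins_burden %||% 0L,
    del_burden = config$cohort$del_burden %||% 0L,
    snv_spectrum = config$cohort$snv_spectrum,
    germline_het_density = config$cohort$germline_het_density %||% 1e-4,
    seed = seed)
  truth <- implant_mutations(reference, cspec)
  noise <- noise_model(config$noise$mean_coverage %||% 25,
                       config$noise$coverage_dispersion %||% 0,
                       config$noise$per_base_error %||% 0.002)
  counts <- simulate_pileup_counts(reference, truth, noise, seed = seed)
  write_reference_fasta(reference, file.path(out_dir, "reference.fa"))
  write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
  write_counts_tsv(counts, file.path(out_dir, "counts.tsv"))

  log("call: %d samples", nrow(meta))
  cfg <- do.call(caller_config, config$caller %||% list())
  calls <- call_unique_mutations(counts, cfg, reference)
  write_calls_tsv(calls, file.path(out_dir, "calls.tsv"))
  write_vcf(calls, reference, file.path(out_dir, "vcf"))

  log("spectrum: %d calls", nrow(calls))
  spectrum <- build_spectrum(calls, reference)
  freqs <- genome_triplet_frequencies(reference, "synthetic")
  rates <- normalize_by_genome(spectrum, freqs)
  write_spectrum_tsv(spectrum, file.path(out_dir, "spectrum_counts.tsv"))
  write_spectrum_tsv(rates, file.path(out_dir, "spectrum_rates.tsv"))

  log("signatures")
  catalog <- if (!is.null(config$catalog_path)) {
    read_signature_catalog(config$catalog_path)
  } else synthetic_signature_catalog()
  sig <- list(top_signature = NA_character_, correlations = NULL,
              cg_tg_fold = NA_real_)
  if (sum(spectrum) >= 2 && stats::sd(as.numeric(spectrum)) > 0) {
    adjusted <- cross_genome_adjust(spectrum, freqs, freqs)
    cors <- correlate_with_catalog(adjusted, catalog)
    sig$top_signature <- names(which.max(cors))
    sig$correlations <- as.list(round(cors, 6))
    sig$cg_tg_fold <- cg_tg_overrepresentation(rates)
  }

  log("indels")
  delcls <- classify_deletions_in_calls(calls, reference)
  data.table::fwrite(delcls, file.path(out_dir, "deletion_classes.tsv"),
                     sep = "\t")

  log("summary + stats")
  callmeta <- data.frame(sample = meta$sample_id, genotype = meta$genotype,
                         treatment = if ("treatment" %in% names(meta))
                           meta$treatment else "none")
  summary <- summarize_cohort(calls, callmeta)
  data.table::fwrite(summary, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t")
  report <- list(
    seed = seed,
    n_samples = nrow(meta),
    n_calls = nrow(calls),
    calls_by_type = as.list(table(calls$type)),
    signatures = sig,
    deletion_categories = as.list(table(delcls$category)),
    outputs = c("reference.fa", "truth.tsv", "counts.tsv", "calls.tsv",
                "spectrum_counts.tsv", "spectrum_rates.tsv",
                "deletion_classes.tsv", "cohort_summary.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done: %d calls", nrow(calls))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration (YAML or JSON)
#'
#' @param path configuration file; `.json` is parsed with jsonlite,
#'   `.yaml`/`.yml` with the yaml package when available
#' @return a configuration list for [run_pipeline()]
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("YAML configs need the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    stopf("unsupported config format: %s", ext)
  }
}
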