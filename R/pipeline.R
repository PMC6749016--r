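#' Run the full validation pipeline
#'
#' End-to-end orchestration: generates (or accepts) a synthetic truth
#' cohort, simulates the DNA panel, targeted RNA panel and
#' whole-transcriptome call sets, and derives every validation product —
#' DNA-vs-RNA concordance at each DNA VAF cutoff, the allelic-imbalance
#' table and summary, replicate reproducibility (when a design is
#' supplied), overall and stratified clinical performance against
#' histology, and the companion-variant co-occurrence table. All outputs
#' are plain data frames / S3 summaries bundled in one report object;
#' `out_dir` additionally writes them as TSV plus a JSON manifest.
#' Deterministic given `seed`: the same seed reproduces every table.
#'
#' @param config A [cohort_config()] (its own seed is overridden by
#'   `seed`), or `NULL` for defaults.
#' @param seed Integer seed governing all randomness of the run.
#' @param dna_cutoffs DNA VAF positivity cutoffs (default `c(0.05, 0.20)`).
#' @param conf_level Confidence level for all intervals.
#' @param reporting_rule Passed to [sample_positivity()].
#' @param design Optional [replicate_design()] for reproducibility
#'   metrics.
#' @param lot_effect Passed to [simulate_replicates()].
#' @param models Optional named list of [platform_model()] overrides
#'   (`dna`, `rna_panel`, `wts`).
#' @param out_dir Optional directory; when given, report tables are
#'   written as TSV and a `manifest.json` records config, seed and
#'   file list.
#' @return Object of class `"validation_report"` (a list of stage
#'   results), invisibly when `out_dir` is given.
#' @export
run_validation <- function(config = NULL, seed = 1,
                           dna_cutoffs = c(0.05, 0.20),
                           conf_level = 0.95,
                           reporting_rule = "all_calls",
                           design = NULL, lot_effect = 0,
                           models = list(), out_dir = NULL) {
  if (any(dna_cutoffs <= 0 | dna_cutoffs >= 1))
    stop("dna_cutoffs must lie in (0, 1)", call. = FALSE)
  if (is.null(config)) config <- cohort_config(seed = seed)
  config$seed <- as.integer(seed)
  mdl <- list(
    dna = models$dna %||% platform_model("DNA_PANEL"),
    rna_panel = models$rna_panel %||% platform_model("RNA_PANEL"),
    wts = models$wts %||% platform_model("WTS_RNASEQ"))

  cohort <- generate_cohort(config)
  seeds <- seed + c(dna = 101L, rna = 202L, wts = 303L, fus = 404L,
                    fus_ref = 505L, rep = 606L)
  dna_calls <- simulate_variant_calls(cohort$truth_variants, mdl$dna,
                                      seeds["dna"])
  rna_panel_calls <- simulate_variant_calls(cohort$truth_variants,
                                            mdl$rna_panel, seeds["rna"],
                                            keep_uncalled = TRUE)
  wts_calls <- simulate_variant_calls(cohort$truth_variants, mdl$wts,
                                      seeds["wts"])
  wts_fusions <- simulate_fusion_calls(cohort$truth_fusions, mdl$wts,
                                       seeds["fus"])
  rna_fusion_ref <- simulate_fusion_calls(cohort$truth_fusions,
                                          mdl$rna_panel,
                                          seeds["fus_ref"])
  wts_all <- wts_calls
  wts_all$fusions <- wts_fusions$fusions
  ids <- cohort$metadata$sample_id

  concord <- lapply(dna_cutoffs, function(cutoff) {
    ref <- apply_dna_vaf_threshold(dna_calls, cutoff)
    counts <- cross_tabulate(wts_calls, ref, ids, unit = "variant_event")
    agreement_summary(counts, conf_level,
                      method = sprintf("DNA variants (cutoff %g%%)",
                                       100 * cutoff))
  })
  names(concord) <- paste0("cutoff_", dna_cutoffs)
  fusion_counts <- cross_tabulate(wts_fusions, rna_fusion_ref, ids,
                                  unit = "fusion_event")
  concord_fusion <- agreement_summary(fusion_counts, conf_level,
                                      method = "Fusions")
  concord_table <- do.call(rbind, c(lapply(concord, function(x) x$table),
                                    list(concord_fusion$table)))
  rownames(concord_table) <- NULL

  dna_pos <- apply_dna_vaf_threshold(dna_calls, min(dna_cutoffs))
  imb_records <- pair_dna_rna(dna_pos, rna_panel_calls)
  imb <- list(records = imb_records,
              scatter = imbalance_scatter(imb_records),
              summary = if (nrow(imb_records))
                imbalance_summary(imb_records) else NULL)

  repro <- NULL
  if (!is.null(design)) {
    rep_calls <- simulate_replicates(design, mdl$wts, seeds["rep"],
                                     lot_effect)
    repro <- list(
      intra_plate = replicate_concordance(rep_calls, design,
                                          "intra_plate", conf_level),
      inter_plate = replicate_concordance(rep_calls, design,
                                          "inter_plate", conf_level))
  }

  positivity <- sample_positivity(ids, wts_all, cohort$metadata,
                                  reporting_rule)
  confusion <- suppressMessages(build_confusion(cohort$metadata,
                                                positivity))
  overall <- performance_metrics(confusion, conf_level)
  by_gsc <- stratified_performance(cohort$metadata, positivity,
                                   "gsc_call", conf_level)
  clin_table <- do.call(rbind, c(list(overall = metrics_row(overall)),
                                 lapply(by_gsc, metrics_row)))
  clin_table <- cbind(stratum = rownames(clin_table), clin_table)
  rownames(clin_table) <- NULL

  cooc <- cooccurrence_summary(dna_calls, cohort$metadata)
  prev <- prevalence_by_category(wts_all, cohort$metadata, "bethesda")

  report <- structure(list(
    seed = as.integer(seed), config = config, cohort = cohort,
    callsets = list(dna = dna_calls, rna_panel = rna_panel_calls,
                    wts = wts_all, rna_fusion_ref = rna_fusion_ref),
    concordance = c(concord, list(fusions = concord_fusion)),
    concordance_table = concord_table,
    imbalance = imb, reproducibility = repro,
    clinical = list(positivity = positivity, confusion = confusion,
                    overall = overall, by_gsc = by_gsc,
                    table = clin_table),
    cooccurrence = cooc, prevalence = prev),
    class = "validation_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(concordance = "concordance.tsv",
             imbalance_scatter = "imbalance_scatter.tsv",
             clinical = "clinical_performance.tsv",
             cooccurrence = "cooccurrence.tsv",
             prevalence = "prevalence_by_bethesda.tsv",
             metadata = "metadata.tsv")
  write_tsv(report$concordance_table, file.path(out_dir, files[1]))
  write_tsv(report$imbalance$scatter, file.path(out_dir, files[2]))
  write_tsv(report$clinical$table, file.path(out_dir, files[3]))
  write_tsv(report$cooccurrence$table, file.path(out_dir, files[4]))
  write_tsv(report$prevalence, file.path(out_dir, files[5]))
  write_tsv(report$cohort$metadata, file.path(out_dir, files[6]))
  manifest <- list(
    package = "varconcord",
    version = as.character(utils::packageVersion("varconcord")),
    seed = report$seed,
    n_samples = report$config$n_samples,
    dna_cutoffs = as.numeric(sub("cutoff_", "",
      grep("^cutoff_", names(report$concordance), value = TRUE))),
    reproducibility_included = !is.null(report$reproducibility),
    files = unname(files),
    file_digests = vapply(file.path(out_dir, files), function(f)
      unname(tools::md5sum(f)), ""))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report (seed ", x$seed, ", n = ",
      nrow(x$cohort$metadata), " samples)\n\n", sep = "")
  cat("Platform concordance:\n")
  print(x$concordance_table, row.names = FALSE)
  if (!is.null(x$imbalance$summary)) {
    cat("\n"); print(x$imbalance$summary)
  }
  if (!is.null(x$reproducibility)) {
    cat("\n")
    print(x$reproducibility$intra_plate)
    print(x$reproducibility$inter_plate)
  }
  cat("\nClinical performance vs histology:\n")
  print(x$clinical$table, row.names = FALSE)
  cat("\n"); print(x$cooccurrence)
  invisible(x)
}
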