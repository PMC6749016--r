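#' Per-sample alteration positivity
#'
#' A sample is alteration-positive when at least one variant or fusion
#' attributed to it survives the reporting rule. Under
#' `"suppress_gsc_benign"` — the clinical reporting convention in which
#' alterations are not reported for classifier-benign samples — calls from
#' classifier-benign samples are suppressed; validation analyses use
#' `"all_calls"`. Non-expressed loci (e.g. promoter variants) never count
#' towards positivity of RNA-based platforms.
#'
#' @param sample_ids Character vector of sample ids to evaluate.
#' @param calls A `callset`.
#' @param metadata Sample metadata data frame (see [read_metadata()]);
#'   required (sample must be present in the metadata).
#' @param reporting_rule `"all_calls"` or `"suppress_gsc_benign"`.
#' @return Named logical vector of positivity, one element per sample id.
#' @export
sample_positivity <- function(sample_ids, calls, metadata,
                              reporting_rule = c("all_calls",
                                                 "suppress_gsc_benign")) {
  stopifnot(inherits(calls, "callset"))
  reporting_rule <- match.arg(reporting_rule)
  unknown <- setdiff(sample_ids, metadata$sample_id)
  if (length(unknown))
    stop("sample(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  vr <- calls$variants
  if (calls$platform %in% c("WTS_RNASEQ", "RNA_PANEL"))
    vr <- vr[vr$is_expressed_locus, , drop = FALSE]
  positive_samples <- unique(c(vr$sample_id, calls$fusions$sample_id))
  pos <- sample_ids %in% positive_samples
  if (reporting_rule == "suppress_gsc_benign") {
    gsc <- metadata$gsc_call[match(sample_ids, metadata$sample_id)]
    pos[gsc == "benign"] <- FALSE
  }
  stats::setNames(pos, sample_ids)
}

#' Build a 2x2 confusion table against histology
#'
#' Cross-tabulates alteration positivity against histological truth
#' (malignant = condition positive). Samples with unknown histology are
#' excluded with a message.
#'
#' @param metadata Metadata data frame with `sample_id` and
#'   `histology_class`.
#' @param positivity Named logical vector from [sample_positivity()] (or
#'   any named logical covering the metadata samples).
#' @return Object of class `"confusion2x2"`: `tp`, `fp`, `fn`, `tn`,
#'   `n_excluded`.
#' @export
build_confusion <- function(metadata, positivity) {
  usable <- metadata[metadata$histology_class %in%
                       c("benign", "malignant"), , drop = FALSE]
  n_excluded <- nrow(metadata) - nrow(usable)
  if (nrow(usable) == 0L)
    stop("no samples with known histology", call. = FALSE)
  miss <- setdiff(usable$sample_id, names(positivity))
  if (length(miss))
    stop("positivity missing for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (n_excluded > 0)
    message(n_excluded, " sample(s) with unknown histology excluded")
  pos <- positivity[usable$sample_id]
  mal <- usable$histology_class == "malignant"
  structure(list(tp = sum(pos & mal), fp = sum(pos & !mal),
                 fn = sum(!pos & mal), tn = sum(!pos & !mal),
                 n_excluded = n_excluded),
            class = "confusion2x2")
}

#' @export
print.confusion2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2,
              dimnames = list(c("alteration+", "alteration-"),
                              c("malignant", "benign")))
  print(m)
  invisible(x)
}

#' Diagnostic performance from a 2x2 table
#'
#' Sensitivity, specificity, PPV, NPV and prevalence with exact binomial
#' confidence intervals. A metric whose denominator is zero is flagged
#' undefined (`NA`) rather than raising an error.
#'
#' @param x A `confusion2x2`.
#' @param conf_level Confidence level.
#' @return Object of class `"performance_metrics"`: named list of
#'   [prop_ci()] (or `NULL` when undefined) plus the source counts.
#' @export
performance_metrics <- function(x, conf_level = 0.95) {
  stopifnot(inherits(x, "confusion2x2"))
  total <- x$tp + x$fp + x$fn + x$tn
  safe <- function(num, den, label)
    if (den > 0) prop_ci(num, den, conf_level, label) else NULL
  structure(list(
    sensitivity = safe(x$tp, x$tp + x$fn, "Sensitivity"),
    specificity = safe(x$tn, x$tn + x$fp, "Specificity"),
    ppv = safe(x$tp, x$tp + x$fp, "PPV"),
    npv = safe(x$tn, x$tn + x$fn, "NPV"),
    prevalence = safe(x$tp + x$fn, total, "Prevalence"),
    confusion = x, conf_level = conf_level),
    class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "prevalence")) {
    if (is.null(x[[nm]])) cat(nm, ": undefined\n", sep = "")
    else print(x[[nm]], digits = 0)
  }
  invisible(x)
}

#' Performance metrics as a one-row data frame
#'
#' @param x A `performance_metrics`.
#' @param digits Decimal places on the percent scale.
#' @return One-row data frame of percent metrics (NA when undefined) with
#'   denominators.
#' @export
metrics_row <- function(x, digits = 0) {
  stopifnot(inherits(x, "performance_metrics"))
  g <- function(nm) if (is.null(x[[nm]])) NA_real_ else
    round_half_up(100 * x[[nm]]$point, digits)
  c2 <- x$confusion
  data.frame(sensitivity = g("sensitivity"), specificity = g("specificity"),
             ppv = g("ppv"), npv = g("npv"), prevalence = g("prevalence"),
             tp = c2$tp, fp = c2$fp, fn = c2$fn, tn = c2$tn,
             n = c2$tp + c2$fp + c2$fn + c2$tn)
}

#' Stratified diagnostic performance
#'
#' Computes [performance_metrics()] within each level of a metadata
#' stratification field (classifier call or Bethesda category). Empty
#' strata are omitted with a warning.
#'
#' @param metadata Metadata data frame.
#' @param positivity Named logical vector of per-sample positivity.
#' @param stratum `"gsc_call"` or `"bethesda"`.
#' @param conf_level Confidence level.
#' @return Named list of `performance_metrics`, one per stratum level.
#' @export
stratified_performance <- function(metadata, positivity,
                                   stratum = c("gsc_call", "bethesda"),
                                   conf_level = 0.95) {
  stratum <- match.arg(stratum)
  levels_present <- unique(metadata[[stratum]])
  out <- list()
  for (lev in levels_present) {
    sub <- metadata[metadata[[stratum]] == lev, , drop = FALSE]
    usable <- sub$histology_class %in% c("benign", "malignant")
    if (!any(usable)) {
      warning("stratum '", lev, "' has no usable samples; omitted",
              call. = FALSE)
      next
    }
    out[[lev]] <- performance_metrics(
      suppressMessages(build_confusion(sub, positivity)), conf_level)
  }
  out
}

#' Chi-square test of independence for a 2x2 table
#'
#' Pearson chi-square with optional Yates continuity correction (on by
#' default, the convention of R's `chisq.test`).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param continuity_correction Apply the Yates correction (default TRUE).
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(tab, continuity_correction = TRUE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive", call. = FALSE)
  res <- suppressWarnings(
    stats::chisq.test(tab, correct = continuity_correction))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Co-occurrence of companion DNA-only variants with driver partners
#'
#' Summarizes samples carrying a companion variant observable only on the
#' DNA platform (e.g. a promoter variant) together with any partner
#' variant from configured driver families (e.g. the RAS genes and BRAF).
#'
#' @param dna_calls A `callset` containing the DNA-platform variant calls
#'   (companion and partner variants).
#' @param metadata Metadata data frame.
#' @param companion_keys Character vector of canonical companion variant
#'   ids (default the TERT promoter hotspot `"TERT:C228T"`).
#' @param partner_families Named list of gene-symbol vectors defining the
#'   partner families (default RAS = NRAS/HRAS/KRAS, BRAF = BRAF).
#' @return List of class `"cooccurrence_summary"`: `table` (one row per
#'   companion-positive sample: partner variants, family, Bethesda,
#'   histology, classifier call), `n_companion_positive`,
#'   `family_counts` (named counts incl. `none`).
#' @export
cooccurrence_summary <- function(dna_calls, metadata,
                                 companion_keys = "TERT:C228T",
                                 partner_families = list(
                                   RAS = c("NRAS", "HRAS", "KRAS"),
                                   BRAF = "BRAF")) {
  stopifnot(inherits(dna_calls, "callset"))
  v <- dna_calls$variants
  comp <- v[v$key %in% companion_keys, , drop = FALSE]
  rows <- lapply(seq_len(nrow(comp)), function(i) {
    s <- comp$sample_id[i]
    partners <- v[v$sample_id == s & !(v$key %in% companion_keys), ,
                  drop = FALSE]
    fam <- "none"
    for (f in names(partner_families))
      if (any(partners$gene %in% partner_families[[f]])) { fam <- f; break }
    m <- match(s, metadata$sample_id)
    data.frame(
      sample_id = s, companion = comp$key[i],
      partner_variants = paste(partners$key, collapse = ","),
      partner_family = fam,
      bethesda = if (!is.na(m)) metadata$bethesda[m] else "unknown",
      histology = if (!is.na(m)) metadata$histology[m] else "unknown",
      histology_class = if (!is.na(m)) metadata$histology_class[m]
                        else "unknown",
      gsc_call = if (!is.na(m)) metadata$gsc_call[m] else "not_applicable",
      stringsAsFactors = FALSE)
  })
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), companion = character(),
               partner_variants = character(), partner_family = character(),
               bethesda = character(), histology = character(),
               histology_class = character(), gsc_call = character(),
               stringsAsFactors = FALSE)
  fams <- c(names(partner_families), "none")
  family_counts <- stats::setNames(
    vapply(fams, function(f) sum(table$partner_family == f), 0L), fams)
  structure(list(table = table,
                 n_companion_positive = nrow(table),
                 family_counts = family_counts),
            class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Companion-variant co-occurrence: ", x$n_companion_positive,
      " positive sample(s); partners: ",
      paste(names(x$family_counts), x$family_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Alteration prevalence by metadata group
#'
#' Counts and fractions of variant-positive and fusion-positive samples
#' per level of a grouping field.
#'
#' @param calls A `callset`.
#' @param metadata Metadata data frame.
#' @param group `"bethesda"` or `"gsc_call"`.
#' @return Data frame with one row per group level: `n`,
#'   `n_variant_positive`, `n_fusion_positive`, `n_positive`,
#'   `frac_variant`, `frac_fusion`, `frac_positive`.
#' @export
prevalence_by_category <- function(calls, metadata,
                                   group = c("bethesda", "gsc_call")) {
  stopifnot(inherits(calls, "callset"))
  group <- match.arg(group)
  vr <- calls$variants
  if (calls$platform %in% c("WTS_RNASEQ", "RNA_PANEL"))
    vr <- vr[vr$is_expressed_locus, , drop = FALSE]
  var_pos <- unique(vr$sample_id)
  fus_pos <- unique(calls$fusions$sample_id)
  levs <- unique(metadata[[group]])
  out <- do.call(rbind, lapply(levs, function(lev) {
    ids <- metadata$sample_id[metadata[[group]] == lev]
    nv <- sum(ids %in% var_pos); nf <- sum(ids %in% fus_pos)
    np <- sum(ids %in% union(var_pos, fus_pos))
    data.frame(group = lev, n = length(ids), n_variant_positive = nv,
               n_fusion_positive = nf, n_positive = np,
               frac_variant = nv / length(ids),
               frac_fusion = nf / length(ids),
               frac_positive = np / length(ids),
               stringsAsFactors = FALSE)
  }))
  names(out)[1] <- group
  rownames(out) <- NULL
  out
}
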