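# Synthetic matched-cohort generator. The generator emulates the
# statistical structure the validation pipeline assumes: a cohort of
# FNA-like samples with cytology (Bethesda) categories, benign/malignant
# histology, an expression-based classifier call, ground-truth variants
# with DNA VAFs and per-variant allele-expression fractions, ground-truth
# fusions with expression rates, and platform-specific call sets obtained
# by sampling reads at finite depth and applying each platform's calling
# thresholds.

# Default assayable content: the variant keys and fusion pairs recurrently
# reported in thyroid FNA validation series.
default_variant_panel <- function() {
  data.frame(
    gene = c("BRAF", "BRAF", "NRAS", "NRAS", "HRAS", "HRAS", "KRAS",
             "TSHR", "TSHR", "TSHR", "TSHR", "TSHR", "TSHR", "TSHR",
             "TSHR", "SPOP", "EIF1AX", "EIF1AX", "EIF1AX", "GNAS",
             "PTEN", "EZH1", "RET", "TERT"),
    protein_change = c("p.V600E", "p.K601E", "p.Q61R", "p.Q61K", "p.Q61R",
                       "p.G13R", "p.Q61R", "p.M453T", "p.L629F", "p.I486M",
                       "p.L512R", "p.I568T", "p.D633Y", "p.S425I",
                       "p.S281I", "p.P94R", "p.G8R", "p.G9D",
                       "p.A113_splice", "p.Q870H", "p.G129R", "p.Y642F",
                       "p.M918T", "C228T"),
    is_expressed_locus = c(rep(TRUE, 23), FALSE),
    # sampling weights shaped like observed recurrence (RAS/BRAF common)
    weight = c(8, 1, 12, 5, 8, 1, 2, 3, 2, 1, 1, 2, 1, 1, 1, 5, 1, 1, 2,
               1, 1, 1, 1, 0),
    stringsAsFactors = FALSE)
}

default_fusion_panel <- function() {
  data.frame(
    partner5 = c("PAX8", "ETV6", "CCDC6", "STRN", "NCOA4", "AGK", "SND1",
                 "RBPMS", "EML4", "MKRN1", "PAX8"),
    partner3 = c("PPARG", "NTRK3", "RET", "ALK", "RET", "BRAF", "BRAF",
                 "NTRK3", "ALK", "BRAF", "GLIS3"),
    weight = c(16, 13, 6, 6, 3, 3, 2, 2, 2, 1, 1),
    stringsAsFactors = FALSE)
}

#' Expected RNA VAF under allele-specific expression
#'
#' If a fraction `v` of DNA molecules carry the variant and the
#' variant-bearing allele is expressed at relative rate `e` (1 = balanced
#' with wild type, 0 = silenced), the expected variant fraction among
#' transcripts is `e v / (e v + (1 - v))`. Monotone increasing in both
#' arguments; equals `v` at `e = 1` and 0 at `e = 0`.
#'
#' @param dna_vaf DNA VAF in (0, 1); vectorised.
#' @param e Non-negative relative expression of the variant allele.
#' @return Expected RNA VAF in `[0, 1]`.
#' @examples
#' expected_rna_vaf(0.32, 0.02)  # about 0.0093: strong wild-type bias
#' @export
expected_rna_vaf <- function(dna_vaf, e) {
  if (any(dna_vaf <= 0 | dna_vaf >= 1))
    stop("dna_vaf must be in (0, 1)", call. = FALSE)
  if (any(e < 0)) stop("expression fraction e must be >= 0", call. = FALSE)
  e * dna_vaf / (e * dna_vaf + (1 - dna_vaf))
}

#' Cohort simulation configuration
#'
#' Bundles and validates the parameters of [generate_cohort()]. Defaults
#' describe a 500-sample indeterminate-cytology-enriched FNA cohort with
#' roughly one-third variant positivity, ~5.5% fusion prevalence, a 5%
#' share of true variants drawn from a low-expression (imbalanced)
#' component, and a small rate of DNA-only promoter companion variants
#' co-occurring with RAS/BRAF drivers.
#'
#' @param n_samples Number of samples.
#' @param seed Integer seed; mandatory for reproducibility.
#' @param bethesda_mix Named probabilities over categories II-VI (sums
#'   to 1).
#' @param p_malignant_by_bethesda Named probability of malignant histology
#'   given the Bethesda category.
#' @param p_variant_malignant,p_variant_benign Probability that a sample
#'   of that histology class carries >= 1 true variant.
#' @param p_second_variant Probability an altered sample carries a second
#'   variant.
#' @param p_fusion_malignant,p_fusion_benign Probability of carrying a
#'   true fusion.
#' @param p_suspicious_malignant,p_suspicious_benign Classifier
#'   sensitivity/false-positive rate.
#' @param imbalance_fraction Share of true variants whose expression
#'   fraction comes from the low-expression component `U(0, 0.1)` instead
#'   of the balanced component (lognormal centered at 1).
#' @param vaf_shape1,vaf_shape2 Beta parameters of the true DNA VAF
#'   distribution.
#' @param p_companion_altered,p_companion_unaltered Probability of a
#'   non-expressed promoter companion variant given the sample does/does
#'   not already carry a variant.
#' @param fusion_log_rate_mean,fusion_log_rate_sd Lognormal parameters of
#'   the fusion expression rate (expected supporting reads per 20,000
#'   valid mapped reads).
#' @param variant_panel,fusion_panel Panel data frames (see package
#'   defaults).
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 500, seed,
                          bethesda_mix = c(II = 0.08, III = 0.42,
                                           IV = 0.28, V = 0.10,
                                           VI = 0.12),
                          p_malignant_by_bethesda = c(II = 0.05,
                                                      III = 0.20,
                                                      IV = 0.25, V = 0.70,
                                                      VI = 0.97),
                          p_variant_malignant = 0.50,
                          p_variant_benign = 0.25,
                          p_second_variant = 0.08,
                          p_fusion_malignant = 0.10,
                          p_fusion_benign = 0.04,
                          p_suspicious_malignant = 0.91,
                          p_suspicious_benign = 0.32,
                          imbalance_fraction = 0.05,
                          vaf_shape1 = 1.5, vaf_shape2 = 3.5,
                          p_companion_altered = 0.04,
                          p_companion_unaltered = 0.002,
                          fusion_log_rate_mean = log(15),
                          fusion_log_rate_sd = 1,
                          variant_panel = default_variant_panel(),
                          fusion_panel = default_fusion_panel()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      is.na(seed))
    stop("cohort_config: an integer 'seed' is mandatory", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (abs(sum(bethesda_mix) - 1) > 1e-8)
    stop("cohort_config: 'bethesda_mix' must sum to 1", call. = FALSE)
  if (!all(names(bethesda_mix) %in% c("II", "III", "IV", "V", "VI")))
    stop("cohort_config: 'bethesda_mix' names must be II-VI",
         call. = FALSE)
  if (!all(names(bethesda_mix) %in% names(p_malignant_by_bethesda)))
    stop("cohort_config: 'p_malignant_by_bethesda' must cover the mix",
         call. = FALSE)
  probs <- c(p_variant_malignant, p_variant_benign, p_second_variant,
             p_fusion_malignant, p_fusion_benign, p_suspicious_malignant,
             p_suspicious_benign, imbalance_fraction, p_companion_altered,
             p_companion_unaltered, unlist(p_malignant_by_bethesda))
  if (any(probs < 0 | probs > 1))
    stop("cohort_config: probabilities must lie in [0, 1]", call. = FALSE)
  rm(probs)
  structure(as.list(environment()), class = "cohort_config")
}

# Representative histology subtype frequencies within each class.
BENIGN_SUBTYPE_MIX <- c(BFN = 0.338, FA = 0.372, HCA = 0.117, HN = 0.034,
                        "FT-UMP" = 0.062, "WDT-UMP" = 0.055, CLT = 0.014,
                        HTA = 0.008)
MALIGNANT_SUBTYPE_MIX <- c(PTC = 0.333, FVPTC = 0.244, "HCC-c" = 0.200,
                           FC = 0.156, "PTC-TCV" = 0.022, PDTC = 0.022,
                           MTC = 0.023)

#' Generate a synthetic ground-truth cohort
#'
#' Draws sample metadata (Bethesda category, histology and derived class,
#' classifier call), true variants (key, true DNA VAF, allele-expression
#' fraction) and true fusions (canonical partners, expression rate) from a
#' [cohort_config()]. Fully deterministic given the config's seed.
#'
#' @param config A `cohort_config`.
#' @return List of class `"truth_cohort"`: `metadata`, `truth_variants`,
#'   `truth_fusions` data frames, plus the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  bcat <- sample(names(config$bethesda_mix), n, replace = TRUE,
                 prob = config$bethesda_mix)
  p_mal <- unlist(config$p_malignant_by_bethesda)[bcat]
  malignant <- runif(n) < p_mal
  histology <- character(n)
  histology[malignant] <- sample(names(MALIGNANT_SUBTYPE_MIX),
                                 sum(malignant), replace = TRUE,
                                 prob = MALIGNANT_SUBTYPE_MIX)
  histology[!malignant] <- sample(names(BENIGN_SUBTYPE_MIX),
                                  sum(!malignant), replace = TRUE,
                                  prob = BENIGN_SUBTYPE_MIX)
  gsc <- ifelse(
    runif(n) < ifelse(malignant, config$p_suspicious_malignant,
                      config$p_suspicious_benign),
    "suspicious", "benign")
  metadata <- data.frame(sample_id = ids, bethesda = bcat, gsc_call = gsc,
                         histology = histology,
                         stringsAsFactors = FALSE)
  metadata$histology_class <- histology_class(metadata$histology)

  vp <- config$variant_panel
  expressed <- vp[vp$is_expressed_locus & vp$weight > 0, , drop = FALSE]
  companion <- vp[!vp$is_expressed_locus, , drop = FALSE]
  p_var <- ifelse(malignant, config$p_variant_malignant,
                  config$p_variant_benign)
  has_var <- runif(n) < p_var
  n_var <- ifelse(has_var, 1L + (runif(n) < config$p_second_variant), 0L)
  tv <- list()
  for (i in which(n_var > 0)) {
    idx <- sample(nrow(expressed), n_var[i], prob = expressed$weight)
    tv[[length(tv) + 1L]] <- data.frame(
      sample_id = ids[i], gene = expressed$gene[idx],
      protein_change = expressed$protein_change[idx],
      is_expressed_locus = TRUE, stringsAsFactors = FALSE)
  }
  # non-expressed promoter companion variants, enriched in altered samples
  p_comp <- ifelse(has_var, config$p_companion_altered,
                   config$p_companion_unaltered)
  comp_draw <- runif(n) < p_comp
  if (nrow(companion) && any(comp_draw)) {
    for (i in which(comp_draw)) {
      idx <- sample(nrow(companion), 1L)
      tv[[length(tv) + 1L]] <- data.frame(
        sample_id = ids[i], gene = companion$gene[idx],
        protein_change = companion$protein_change[idx],
        is_expressed_locus = FALSE, stringsAsFactors = FALSE)
    }
  }
  truth_variants <- if (length(tv)) do.call(rbind, tv) else
    data.frame(sample_id = character(), gene = character(),
               protein_change = character(), is_expressed_locus = logical(),
               stringsAsFactors = FALSE)
  if (nrow(truth_variants)) {
    truth_variants$key <- paste0(truth_variants$gene, ":",
                                 truth_variants$protein_change)
    dup <- duplicated(paste(truth_variants$sample_id, truth_variants$key))
    truth_variants <- truth_variants[!dup, , drop = FALSE]
    m <- nrow(truth_variants)
    truth_variants$dna_vaf_true <- rbeta(m, config$vaf_shape1,
                                         config$vaf_shape2)
    imb <- runif(m) < config$imbalance_fraction
    truth_variants$expression_fraction <-
      ifelse(imb, runif(m, 0, 0.1), rlnorm(m, 0, 0.25))
    truth_variants$expression_fraction[!truth_variants$is_expressed_locus] <- 0
    truth_variants$imbalanced_component <- imb &
      truth_variants$is_expressed_locus
    truth_variants <- truth_variants[order(truth_variants$sample_id,
                                           truth_variants$key), ,
                                     drop = FALSE]
    rownames(truth_variants) <- NULL
  } else {
    truth_variants$key <- character()
    truth_variants$dna_vaf_true <- numeric()
    truth_variants$expression_fraction <- numeric()
    truth_variants$imbalanced_component <- logical()
  }

  fp <- config$fusion_panel
  p_fus <- ifelse(malignant, config$p_fusion_malignant,
                  config$p_fusion_benign)
  has_fus <- runif(n) < p_fus
  if (any(has_fus) && nrow(fp)) {
    idx <- sample(nrow(fp), sum(has_fus), replace = TRUE, prob = fp$weight)
    truth_fusions <- data.frame(
      sample_id = ids[has_fus], partner5 = fp$partner5[idx],
      partner3 = fp$partner3[idx],
      expression_rate = rlnorm(sum(has_fus), config$fusion_log_rate_mean,
                               config$fusion_log_rate_sd),
      stringsAsFactors = FALSE)
    truth_fusions$fusion_id <- paste0(truth_fusions$partner5, ":",
                                      truth_fusions$partner3)
    rownames(truth_fusions) <- NULL
  } else {
    truth_fusions <- data.frame(
      sample_id = character(), partner5 = character(),
      partner3 = character(), expression_rate = numeric(),
      fusion_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(metadata = metadata, truth_variants = truth_variants,
                 truth_fusions = truth_fusions, config = config),
            class = "truth_cohort")
}

#' @export
print.truth_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$metadata), " samples (",
      sum(x$metadata$histology_class == "malignant"), " malignant), ",
      nrow(x$truth_variants), " true variants, ",
      nrow(x$truth_fusions), " true fusions\n", sep = "")
  invisible(x)
}

#' Platform detection model
#'
#' Read-depth and calling-threshold model of one platform. Variant calls
#' sample a sequencing depth (negative binomial), then alt reads
#' beta-binomially around the expected allele fraction with overdispersion
#' `rho`, and call the variant when the alt count and observed VAF clear
#' the thresholds and the call survives a per-call miss probability.
#' Fusion-capable platforms sample total valid mapped reads and Poisson
#' supporting reads, with the sample failing QC below
#' `min_valid_mapped_reads` and a call requiring `min_supporting_reads`.
#'
#' @param platform Platform name; sets depth defaults (DNA panel 500x,
#'   targeted RNA panel 300x, whole-transcriptome 60x).
#' @param mean_depth,depth_size Negative-binomial depth mean and size.
#' @param rho Beta-binomial overdispersion of allele sampling
#'   (default 0.01).
#' @param min_alt_reads,min_vaf_call Variant calling thresholds.
#' @param per_call_miss_prob Probability a true signal above threshold is
#'   nevertheless dropped (library/handling failures).
#' @param min_supporting_reads,min_valid_mapped_reads Fusion-calling QC
#'   thresholds (defaults 20 and 20,000).
#' @param mapped_reads_mean,mapped_reads_size Negative-binomial model of
#'   total valid mapped reads per sample.
#' @return Object of class `"platform_model"`.
#' @export
platform_model <- function(platform,
                           mean_depth = switch(platform, DNA_PANEL = 500,
                                               RNA_PANEL = 300,
                                               WTS_RNASEQ = 60, 300),
                           depth_size = 5,
                           rho = 0.01,
                           min_alt_reads = 5,
                           min_vaf_call = switch(platform,
                                                 DNA_PANEL = 0.01, 0.05),
                           per_call_miss_prob = 0.02,
                           min_supporting_reads = 20,
                           min_valid_mapped_reads = 20000,
                           mapped_reads_mean = 2e5,
                           mapped_reads_size = 10) {
  platform <- match.arg(platform, PLATFORMS)
  stopifnot(mean_depth > 0, rho >= 0, rho < 1,
            per_call_miss_prob >= 0, per_call_miss_prob <= 1,
            min_alt_reads >= 0, min_vaf_call >= 0, min_vaf_call <= 1,
            min_supporting_reads > 0, min_valid_mapped_reads > 0)
  structure(as.list(environment()), class = "platform_model")
}

rbetabinom <- function(n, size, prob, rho) {
  p <- prob
  if (rho > 0) {
    ok <- prob > 0 & prob < 1
    a <- prob * (1 - rho) / rho
    b <- (1 - prob) * (1 - rho) / rho
    p[ok] <- rbeta(sum(ok), a[ok], b[ok])
  }
  rbinom(n, size, p)
}

#' Simulate one platform's variant calls from ground truth
#'
#' For each true variant, draws a depth and alt-read count around the
#' expected allele fraction — the true DNA VAF on the DNA platform, or
#' [expected_rna_vaf()] of it on RNA platforms — and applies the
#' platform's calling thresholds. Non-expressed loci are never observed on
#' RNA platforms.
#'
#' @param truth `truth_variants` data frame from [generate_cohort()].
#' @param model A [platform_model()] with a variant-capable platform.
#' @param seed Integer seed.
#' @param keep_uncalled If `TRUE`, return every measured record (the
#'   platform's raw pileup at the truth positions) regardless of calling
#'   thresholds, e.g. to study allelic imbalance; default returns calls
#'   only.
#' @return A `callset`.
#' @export
simulate_variant_calls <- function(truth, model, seed,
                                   keep_uncalled = FALSE) {
  stopifnot(inherits(model, "platform_model"))
  if (!model$platform %in% c("DNA_PANEL", "RNA_PANEL", "WTS_RNASEQ"))
    stop("variant simulation requires a sequencing platform",
         call. = FALSE)
  set.seed(seed)
  is_rna <- model$platform %in% c("RNA_PANEL", "WTS_RNASEQ")
  if (is_rna) truth <- truth[truth$is_expressed_locus, , drop = FALSE]
  m <- nrow(truth)
  if (m == 0L) return(callset(model$platform))
  depth <- pmax(1L, rnbinom(m, mu = model$mean_depth,
                            size = model$depth_size))
  p_exp <- if (is_rna)
    expected_rna_vaf(truth$dna_vaf_true, truth$expression_fraction)
  else truth$dna_vaf_true
  alt <- rbetabinom(m, depth, p_exp, model$rho)
  vaf <- alt / depth
  called <- alt >= model$min_alt_reads & vaf >= model$min_vaf_call &
    runif(m) >= model$per_call_miss_prob
  df <- data.frame(sample_id = truth$sample_id, gene = truth$gene,
                   protein_change = truth$protein_change, vaf = vaf,
                   alt_depth = alt, total_depth = depth,
                   is_expressed_locus = truth$is_expressed_locus,
                   stringsAsFactors = FALSE)
  if (!keep_uncalled) df <- df[called, , drop = FALSE]
  callset(model$platform, variants = df)
}

#' Simulate one platform's fusion calls from ground truth
#'
#' @param truth `truth_fusions` data frame from [generate_cohort()];
#'   `expression_rate` is the expected supporting reads per 20,000 valid
#'   mapped reads.
#' @param model A [platform_model()].
#' @param seed Integer seed.
#' @return A `callset` of fusion calls (samples failing the
#'   mapped-reads QC yield no call).
#' @export
simulate_fusion_calls <- function(truth, model, seed) {
  stopifnot(inherits(model, "platform_model"))
  set.seed(seed)
  m <- nrow(truth)
  if (m == 0L) return(callset(model$platform))
  mapped <- rnbinom(m, mu = model$mapped_reads_mean,
                    size = model$mapped_reads_size)
  support <- rpois(m, truth$expression_rate * mapped / 20000)
  called <- mapped >= model$min_valid_mapped_reads &
    support >= model$min_supporting_reads &
    runif(m) >= model$per_call_miss_prob
  df <- data.frame(sample_id = truth$sample_id,
                   partner5 = truth$partner5, partner3 = truth$partner3,
                   supporting_reads = support,
                   total_valid_mapped_reads = mapped,
                   stringsAsFactors = FALSE)[called, , drop = FALSE]
  callset(model$platform, fusions = df)
}

#' Simulate replicate-design calls
#'
#' Independently simulates, for every replicate well and every expected
#' positive event of its sample, whether the event is detected. The
#' per-call miss probability comes from the platform model; a planted
#' reagent-lot effect adds extra miss probability on the affected lot(s),
#' which lowers inter-plate relative to intra-plate concordance when lots
#' differ across plates.
#'
#' @param design A [replicate_design()].
#' @param model A [platform_model()] (its `per_call_miss_prob` is the base
#'   miss rate).
#' @param seed Integer seed.
#' @param lot_effect Either a single number — extra miss probability
#'   applied to the last (sorted) reagent lot — or a named vector of extra
#'   miss probability per reagent lot.
#' @return Data frame of detected calls: `sample_id`, `replicate_index`,
#'   `plate_id`, `key`.
#' @export
simulate_replicates <- function(design, model, seed, lot_effect = 0) {
  stopifnot(inherits(design, "replicate_design"),
            inherits(model, "platform_model"))
  set.seed(seed)
  lay <- design$layout
  lots <- sort(unique(lay$reagent_lot))
  extra <- stats::setNames(rep(0, length(lots)), lots)
  if (length(lot_effect) == 1L && is.null(names(lot_effect))) {
    if (lot_effect > 0 && length(lots)) extra[length(lots)] <- lot_effect
  } else {
    extra[names(lot_effect)] <- lot_effect
  }
  rows <- list()
  for (i in seq_len(nrow(lay))) {
    exp_i <- design$expected_positive[
      design$expected_positive$sample_id == lay$sample_id[i], ,
      drop = FALSE]
    if (nrow(exp_i) == 0L) next
    miss <- min(1, model$per_call_miss_prob +
                  extra[as.character(lay$reagent_lot[i])])
    hit <- runif(nrow(exp_i)) >= miss
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = lay$sample_id[i],
        replicate_index = lay$replicate_index[i],
        plate_id = lay$plate_id[i], key = exp_i$key[hit],
        stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), replicate_index = integer(),
               plate_id = character(), key = character(),
               stringsAsFactors = FALSE)
}

#' Triplicate-across-plates layout
#'
#' Convenience constructor of the standard analytical-validation layout:
#' each sample plated in `n_replicates` wells on each of `n_plates`
#' plates, one reagent lot and operator per plate.
#'
#' @param sample_ids Character vector of sample ids.
#' @param expected_positive Data frame `sample_id`, `key`.
#' @param n_replicates Replicates per plate (default 3).
#' @param n_plates Number of plates (default 3).
#' @return A [replicate_design()].
#' @export
triplicate_design <- function(sample_ids, expected_positive,
                              n_replicates = 3, n_plates = 3) {
  layout <- expand.grid(sample_id = sample_ids,
                        replicate_index = seq_len(n_replicates),
                        plate_id = paste0("P", seq_len(n_plates)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  layout$reagent_lot <- paste0("LOT", sub("^P", "", layout$plate_id))
  layout$lab_id <- "LAB1"
  layout$operator_id <- paste0("OP", sub("^P", "", layout$plate_id))
  replicate_design(layout, expected_positive)
}
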