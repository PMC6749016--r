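test_that("positivity counts a multi-variant nodule once and honours the
           reporting rule", {
  meta <- data.frame(
    sample_id = c("N1", "N2", "N3"), bethesda = "unknown",
    gsc_call = c("suspicious", "benign", "benign"),
    histology = c("FVPTC", "BFN", "FA"), stringsAsFactors = FALSE)
  meta$histology_class <- histology_class(meta$histology)
  cs <- callset("WTS_RNASEQ", variants = data.frame(
    sample_id = c("N1", "N1", "N3"),
    gene = c("KRAS", "EIF1AX", "TSHR"),
    protein_change = c("p.Q61R", "p.A113_splice", "p.M453T"),
    vaf = 0.3, alt_depth = 30L, total_depth = 100L,
    stringsAsFactors = FALSE))
  pos <- sample_positivity(meta$sample_id, cs, meta)
  expect_equal(unname(pos), c(TRUE, FALSE, TRUE))
  # classifier-benign nodule suppressed under the clinical reporting rule
  pos2 <- sample_positivity(meta$sample_id, cs, meta,
                            "suppress_gsc_benign")
  expect_equal(unname(pos2), c(TRUE, FALSE, FALSE))
  expect_error(sample_positivity("N9", cs, meta), "absent")
})

test_that("non-expressed loci never drive RNA-platform positivity", {
  meta <- data.frame(sample_id = "N1", bethesda = "IV",
                     gsc_call = "suspicious", histology = "FA",
                     histology_class = "benign",
                     stringsAsFactors = FALSE)
  tert_only <- data.frame(sample_id = "N1", gene = "TERT",
                          protein_change = "C228T", vaf = 0.3,
                          alt_depth = 30L, total_depth = 100L,
                          is_expressed_locus = FALSE,
                          stringsAsFactors = FALSE)
  rna <- callset("WTS_RNASEQ", variants = tert_only)
  dna <- callset("DNA_PANEL", variants = tert_only)
  expect_false(sample_positivity("N1", rna, meta)[[1]])
  expect_true(sample_positivity("N1", dna, meta)[[1]])
})

test_that("confusion tables equal the brute-force tally on random cohorts", {
  set.seed(17)
  for (rep in 1:100) {
    meta <- random_metadata(sample(5:30, 1))
    pos <- setNames(runif(nrow(meta)) < 0.4, meta$sample_id)
    want <- oracle_confusion(meta, pos)
    if (want$tp + want$fp + want$fn + want$tn == 0) next
    got <- suppressMessages(build_confusion(meta, pos))
    expect_equal(got[c("tp", "fp", "fn", "tn")], want)
  }
})

test_that("unknown-histology samples are excluded with a message", {
  meta <- random_metadata(10)
  meta$histology <- c(rep("unknown", 3), rep(c("FA", "PTC"), length.out = 7))
  meta$histology_class <- histology_class(meta$histology)
  pos <- setNames(rep(TRUE, 10), meta$sample_id)
  expect_message(cf <- build_confusion(meta, pos), "excluded")
  expect_equal(cf$n_excluded, 3L)
  expect_equal(cf$tp + cf$fp + cf$fn + cf$tn, 7L)
})

test_that("performance metrics match independently coded formulas", {
  set.seed(23)
  for (rep in 1:50) {
    counts <- as.list(sample(0:40, 4, replace = TRUE))
    names(counts) <- c("tp", "fp", "fn", "tn")
    cf <- structure(c(counts, n_excluded = 0L), class = "confusion2x2")
    pm <- performance_metrics(cf)
    with(counts, {
      if (tp + fn > 0) expect_equal(pm$sensitivity$point, tp / (tp + fn))
      else expect_null(pm$sensitivity)
      if (tn + fp > 0) expect_equal(pm$specificity$point, tn / (tn + fp))
      if (tp + fp > 0) expect_equal(pm$ppv$point, tp / (tp + fp))
      if (tn + fn > 0) expect_equal(pm$npv$point, tn / (tn + fn))
      if (tp + fp + fn + tn > 0)
        expect_equal(pm$prevalence$point,
                     (tp + fn) / (tp + fp + fn + tn))
    })
  }
  perfect <- structure(list(tp = 10L, fp = 0L, fn = 0L, tn = 20L,
                            n_excluded = 0L), class = "confusion2x2")
  pm <- performance_metrics(perfect)
  expect_equal(pm$sensitivity$point, 1)
  expect_equal(pm$specificity$point, 1)
  expect_equal(pm$ppv$point, 1)
  expect_equal(pm$npv$point, 1)
})

test_that("adding a positive call never hurts sensitivity nor helps
           specificity", {
  set.seed(29)
  meta <- random_metadata(20)
  pos <- setNames(runif(20) < 0.3, meta$sample_id)
  base <- performance_metrics(suppressMessages(
    build_confusion(meta, pos)))
  for (s in names(pos)[!pos]) {
    pos2 <- pos; pos2[s] <- TRUE
    pm2 <- performance_metrics(suppressMessages(
      build_confusion(meta, pos2)))
    if (!is.null(base$sensitivity))
      expect_gte(pm2$sensitivity$point, base$sensitivity$point)
    if (!is.null(base$specificity))
      expect_lte(pm2$specificity$point, base$specificity$point)
  }
})

test_that("stratified performance equals filter-then-compute and sums to
           the overall table", {
  set.seed(37)
  meta <- random_metadata(60)
  pos <- setNames(runif(60) < 0.4, meta$sample_id)
  strat <- suppressWarnings(
    stratified_performance(meta, pos, "gsc_call"))
  total <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  for (lev in names(strat)) {
    sub <- meta[meta$gsc_call == lev, , drop = FALSE]
    want <- performance_metrics(suppressMessages(
      build_confusion(sub, pos)))
    expect_equal(strat[[lev]]$confusion, want$confusion)
    cf <- strat[[lev]]$confusion
    total <- total + c(tp = cf$tp, fp = cf$fp, fn = cf$fn, tn = cf$tn)
  }
  overall <- suppressMessages(build_confusion(meta, pos))
  expect_equal(total,
               c(tp = overall$tp, fp = overall$fp, fn = overall$fn,
                 tn = overall$tn))
  # single-stratum input equals the unstratified result
  meta1 <- meta; meta1$gsc_call <- "suspicious"
  strat1 <- stratified_performance(meta1, pos, "gsc_call")
  expect_equal(strat1$suspicious$confusion, overall)
})

test_that("chi-square of independence matches stats::chisq.test", {
  tab <- matrix(c(22, 23, 35, 110), 2, byrow = TRUE)
  got <- chi_square_2x2(tab)
  want <- chisq.test(tab, correct = TRUE)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p_value, want$p.value)
  expect_equal(round(got$p_value, 3), 0.003)
  # identical row proportions -> statistic 0, p = 1 (uncorrected)
  flat <- chi_square_2x2(matrix(c(10, 20, 30, 60), 2, byrow = TRUE),
                         continuity_correction = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # Yates correction never increases the statistic
  set.seed(41)
  for (rep in 1:20) {
    t2 <- matrix(sample(1:50, 4, replace = TRUE), 2)
    expect_lte(chi_square_2x2(t2, TRUE)$statistic,
               chi_square_2x2(t2, FALSE)$statistic)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("co-occurrence fixture yields 15 companion-positive samples,
           14 with a RAS/BRAF partner", {
  co <- cooccurrence_summary(table4_callset(), table4_tert())
  expect_equal(co$n_companion_positive, 15L)
  expect_equal(sum(co$family_counts[c("RAS", "BRAF")]), 14L)
  expect_equal(unname(co$family_counts["none"]), 1L)
  expect_true(all(co$table$gsc_call == "suspicious"))
  # no companion-positive samples -> empty table
  none <- cooccurrence_summary(
    callset("DNA_PANEL", variants = data.frame(
      sample_id = "S1", gene = "NRAS", protein_change = "p.Q61R",
      vaf = 0.3, alt_depth = 30L, total_depth = 100L)),
    table4_tert())
  expect_equal(none$n_companion_positive, 0L)
  expect_equal(nrow(none$table), 0L)
})

test_that("prevalence by category equals a group-by counting oracle", {
  set.seed(43)
  meta <- random_metadata(40)
  cs <- random_variant_calls(30, n_samples = 40)
  cs$variants$sample_id <- sample(meta$sample_id,
                                  nrow(cs$variants), replace = TRUE)
  prev <- prevalence_by_category(cs, meta, "bethesda")
  for (i in seq_len(nrow(prev))) {
    ids <- meta$sample_id[meta$bethesda == prev$bethesda[i]]
    want <- sum(ids %in% cs$variants$sample_id)
    expect_equal(prev$n_variant_positive[i], want)
    expect_equal(prev$frac_variant[i], want / length(ids))
  }
  expect_equal(sum(prev$n), nrow(meta))
})

test_that("a 943-sample cohort with 52 fusion positives reports 5.5%", {
  meta <- data.frame(sample_id = sprintf("S%03d", 1:943),
                     bethesda = "III", gsc_call = "suspicious",
                     histology = "unknown",
                     histology_class = "unknown",
                     stringsAsFactors = FALSE)
  fus <- callset("WTS_RNASEQ", fusions = data.frame(
    sample_id = meta$sample_id[1:52], partner5 = "CCDC6",
    partner3 = "RET", supporting_reads = 40L,
    total_valid_mapped_reads = 60000L, stringsAsFactors = FALSE))
  prev <- prevalence_by_category(fus, meta, "bethesda")
  expect_equal(round_half_up(100 * prev$frac_fusion, 1), 5.5)
})
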