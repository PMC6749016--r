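test_that("published concordance counts give the published agreement", {
  counts <- concordance_counts(n_both = 134, n_ref_only = 47,
                               n_test_only = 2)
  p <- ppa(counts)
  expect_equal(round_half_up(100 * p$point), 74)
  expect_equal(round_half_up(100 * p$ci_low), 67)
  expect_equal(round_half_up(100 * p$ci_high), 80)
  cf <- confirmation(counts)
  expect_equal(round_half_up(100 * cf$point, 1), 98.5)
  fus <- concordance_counts(50, 11, 0, unit = "fusion_event")
  expect_equal(round_half_up(100 * ppa(fus)$point), 82)
  expect_equal(confirmation(fus)$point, 1)
})

test_that("agreement degenerate cases behave as defined", {
  expect_equal(ppa(concordance_counts(5, 0, 3))$point, 1)
  expect_equal(confirmation(concordance_counts(0, 2, 3))$point, 0)
  expect_error(ppa(concordance_counts(0, 0, 3)), "undefined")
  expect_error(confirmation(concordance_counts(0, 3, 0)), "undefined")
  expect_error(npa(concordance_counts(1, 1, 1)), "panel")
  expect_equal(npa(concordance_counts(1, 1, 1, n_neither = 99))$point,
               0.99)
  expect_equal(npa(concordance_counts(0, 0, 0, n_neither = 1000))$point,
               1)
})

test_that("cross_tabulate equals the brute-force oracle on random sets", {
  set.seed(42)
  for (rep in 1:100) {
    test_cs <- random_variant_calls(sample(3:25, 1))
    ref_cs <- random_variant_calls(sample(3:25, 1),
                                   platform = "DNA_PANEL")
    ids <- sprintf("S%02d", 1:5)
    got <- cross_tabulate(test_cs, ref_cs, ids)
    want <- oracle_cross_tabulate(test_cs, ref_cs, ids)
    expect_equal(got$n_both, want$n_both)
    expect_equal(got$n_ref_only, want$n_ref_only)
    expect_equal(got$n_test_only, want$n_test_only)
  }
})

test_that("a call set against itself is fully concordant", {
  set.seed(3)
  cs <- random_variant_calls(15)
  counts <- cross_tabulate(cs, cs, unique(cs$variants$sample_id))
  expect_equal(counts$n_ref_only, 0L)
  expect_equal(counts$n_test_only, 0L)
  expect_equal(ppa(counts)$point, 1)
  expect_equal(confirmation(counts)$point, 1)
})

test_that("confirmation equals PPA with platform roles swapped", {
  set.seed(5)
  for (rep in 1:10) {
    a <- random_variant_calls(20)
    b <- random_variant_calls(20, platform = "DNA_PANEL")
    ids <- sprintf("S%02d", 1:5)
    fwd <- cross_tabulate(a, b, ids)
    rev <- cross_tabulate(b, a, ids)
    if (fwd$n_both + fwd$n_test_only > 0)
      expect_equal(confirmation(fwd)$point, ppa(rev)$point)
  }
})

test_that("NPA with a panel matches a per-(sample,target) negative tally", {
  set.seed(8)
  panel <- c("BRAF:p.V600E", "NRAS:p.Q61R", "HRAS:p.Q61R",
             "TSHR:p.M453T")
  test_cs <- random_variant_calls(10)
  ref_cs <- random_variant_calls(10, platform = "DNA_PANEL")
  ids <- sprintf("S%02d", 1:5)
  counts <- cross_tabulate(test_cs, ref_cs, ids, panel = panel)
  # brute force: enumerate every (sample, target) pair
  tally <- 0L
  te <- paste(test_cs$variants$sample_id, test_cs$variants$key)
  re <- paste(ref_cs$variants$sample_id, ref_cs$variants$key)
  for (s in ids) for (k in panel) {
    pair <- paste(s, k)
    if (!(pair %in% te) && !(pair %in% re)) tally <- tally + 1L
  }
  expect_equal(counts$n_neither, tally)
  expect_equal(npa(counts)$point,
               tally / (tally + counts$n_test_only))
})

test_that("exact binomial CI matches closed forms and binom.test", {
  # boundary closed forms
  n <- 17
  expect_equal(exact_binomial_ci(0, n),
               c(low = 0, high = 1 - 0.025^(1 / n)))
  expect_equal(exact_binomial_ci(n, n),
               c(low = 0.025^(1 / n), high = 1))
  # independent oracle across a grid
  for (n in c(5, 20, 181)) for (x in unique(c(0, 1, n %/% 2, n))) {
    got <- exact_binomial_ci(x, n)
    want <- binom.test(x, n)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-10)
  }
  expect_error(exact_binomial_ci(1, 0), "n > 0")
  expect_error(exact_binomial_ci(5, 3), "<=")
})

test_that("Clopper-Pearson coverage is at least nominal for n <= 30", {
  # exact coverage: sum dbinom over x where p falls inside the interval
  for (n in c(5, 12, 21, 30)) {
    for (p in seq(0.05, 0.95, by = 0.15)) {
      inside <- vapply(0:n, function(x) {
        ci <- exact_binomial_ci(x, n)
        p >= ci[1] && p <= ci[2]
      }, TRUE)
      coverage <- sum(dbinom(0:n, n, p)[inside])
      expect_gte(coverage, 0.95)
    }
  }
})

test_that("CI endpoints bracket the point and tighten with n", {
  pci <- prop_ci(134, 181)
  expect_lte(pci$ci_low, pci$point)
  expect_gte(pci$ci_high, pci$point)
  widths <- vapply(c(20, 80, 320, 1280), function(n) {
    ci <- exact_binomial_ci(round(0.74 * n), n)
    ci[2] - ci[1]
  }, 1)
  expect_true(all(diff(widths) < 0))
})

test_that("discordant events are adjudicated against the arbiter", {
  mk_fus <- function(platform, samples, p5, p3) callset(
    platform, fusions = data.frame(
      sample_id = samples, partner5 = p5, partner3 = p3,
      supporting_reads = 30L, total_valid_mapped_reads = 50000L,
      stringsAsFactors = FALSE))
  test_cs <- mk_fus("WTS_RNASEQ", c("S1", "S2"),
                    c("CCDC6", "PAX8"), c("RET", "PPARG"))
  ref_cs <- mk_fus("RNA_PANEL", c("S1", "S3"),
                   c("CCDC6", "ETV6"), c("RET", "NTRK3"))
  truth <- mk_fus("QPCR", c("S2", "S3"),
                  c("PAX8", "ETV6"), c("PPARG", "NTRK3"))
  counts <- cross_tabulate(test_cs, ref_cs, c("S1", "S2", "S3"),
                           unit = "fusion_event")
  adj <- adjudicate_discordants(counts, truth)
  expect_setequal(adj$verdict[adj$sample_id == "S2"], "test_correct")
  expect_setequal(adj$verdict[adj$sample_id == "S3"],
                  "reference_correct")
  # event in a sample the arbiter never assayed -> unresolved + warning
  ref2 <- mk_fus("RNA_PANEL", c("S1", "S4"),
                 c("CCDC6", "STRN"), c("RET", "ALK"))
  counts2 <- cross_tabulate(test_cs, ref2, c("S1", "S2", "S4"),
                            unit = "fusion_event")
  expect_warning(adj2 <- adjudicate_discordants(counts2, truth),
                 "unresolved")
  expect_equal(adj2$verdict[adj2$sample_id == "S4"], "unresolved")
  # empty discordant set -> empty table
  same <- cross_tabulate(test_cs, test_cs, c("S1", "S2"),
                         unit = "fusion_event")
  expect_equal(nrow(adjudicate_discordants(same, truth)), 0L)
})

test_that("report formatting matches the published table style", {
  s <- agreement_summary(concordance_counts(134, 47, 2),
                         method = "DNA variants")
  expect_equal(s$table$ppa, "74%[67-80]")
  expect_equal(s$table$confirmation, "98.5%[95-100]")
  s2 <- agreement_summary(concordance_counts(50, 11, 0,
                                             unit = "fusion_event"))
  expect_equal(s2$table$ppa, "82%[70-91]")
  expect_equal(s2$table$confirmation, "100%[93-100]")
})
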