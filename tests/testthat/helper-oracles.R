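# Shared generators and brute-force oracles. Oracles deliberately use
# naive set/tally logic, independent of the package's vectorised paths.

random_variant_calls <- function(n, n_samples = 5, n_keys = 4,
                                 platform = "WTS_RNASEQ") {
  genes <- c("BRAF", "NRAS", "HRAS", "TSHR")[seq_len(n_keys)]
  pcs <- c("p.V600E", "p.Q61R", "p.Q61R", "p.M453T")[seq_len(n_keys)]
  idx <- sample(n_keys, n, replace = TRUE)
  depth <- sample(50:500, n, replace = TRUE)
  alt <- vapply(depth, function(d) sample.int(d, 1), 1L)
  df <- data.frame(
    sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n,
                       replace = TRUE),
    gene = genes[idx], protein_change = pcs[idx],
    vaf = alt / depth, alt_depth = alt, total_depth = depth,
    stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("sample_id", "gene", "protein_change")]), ,
           drop = FALSE]
  callset(platform, variants = df)
}

# brute-force event classification by exhaustive pairwise comparison
oracle_cross_tabulate <- function(test, reference, sample_ids) {
  ev <- function(x) {
    df <- x$variants[x$variants$sample_id %in% sample_ids, , drop = FALSE]
    unique(paste(df$sample_id, df$key))
  }
  te <- ev(test); re <- ev(reference)
  n_both <- 0L; n_ref_only <- 0L
  for (e in re) {
    found <- FALSE
    for (t in te) if (identical(t, e)) found <- TRUE
    if (found) n_both <- n_both + 1L else n_ref_only <- n_ref_only + 1L
  }
  n_test_only <- 0L
  for (t in te) if (!any(vapply(re, identical, TRUE, t)))
    n_test_only <- n_test_only + 1L
  list(n_both = n_both, n_ref_only = n_ref_only,
       n_test_only = n_test_only)
}

# naive per-sample confusion tally
oracle_confusion <- function(metadata, positivity) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(metadata))) {
    cls <- metadata$histology_class[i]
    if (!cls %in% c("benign", "malignant")) next
    p <- positivity[[metadata$sample_id[i]]]
    if (cls == "malignant" && p) tp <- tp + 1L
    if (cls == "malignant" && !p) fn <- fn + 1L
    if (cls == "benign" && p) fp <- fp + 1L
    if (cls == "benign" && !p) tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

random_metadata <- function(n) {
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    bethesda = sample(c("II", "III", "IV", "V", "VI"), n, replace = TRUE),
    gsc_call = sample(c("benign", "suspicious"), n, replace = TRUE),
    histology = sample(c("BFN", "FA", "PTC", "FC", "unknown"), n,
                       replace = TRUE),
    stringsAsFactors = FALSE) |>
    (\(df) { df$histology_class <- histology_class(df$histology); df })()
}
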