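#' DNA:RNA variant-allele-frequency ratio
#'
#' Ratio of the DNA VAF to the RNA VAF of the same variant, quantifying how
#' strongly the wild-type allele out-expresses the variant allele. The RNA
#' VAF is floored at a small positive value so the ratio stays finite when
#' the variant is essentially absent from the transcript pool.
#'
#' @param dna_vaf DNA VAF, must be positive (the ratio is defined only for
#'   DNA-positive variants).
#' @param rna_vaf RNA VAF in `[0, 1]`.
#' @param floor Positive lower bound substituted for small RNA VAFs
#'   (default 0.005).
#' @return `dna_vaf / max(rna_vaf, floor)`, vectorised.
#' @examples
#' vaf_ratio(0.32, 0.009)  # about 35.6
#' @export
vaf_ratio <- function(dna_vaf, rna_vaf, floor = 0.005) {
  if (!is.numeric(floor) || floor <= 0)
    stop("floor must be positive", call. = FALSE)
  if (any(is.na(dna_vaf)) || any(dna_vaf <= 0))
    stop("vaf_ratio is defined only for DNA-positive variants ",
         "(dna_vaf > 0)", call. = FALSE)
  if (any(rna_vaf < 0 | rna_vaf > 1, na.rm = TRUE))
    stop("rna_vaf outside [0, 1]", call. = FALSE)
  dna_vaf / pmax(rna_vaf, floor)
}

#' Classify strong wild-type-allele expression bias
#'
#' A variant shows allelic-expression imbalance when its DNA VAF exceeds
#' 10% while its RNA VAF is under 5% (both strict): the variant is clearly
#' present in the genome but depleted in the transcript pool.
#'
#' @param dna_vaf,rna_vaf VAFs in `[0, 1]`; vectorised.
#' @param dna_cutoff,rna_cutoff Strict thresholds (defaults 0.10, 0.05).
#' @return Logical vector.
#' @export
classify_imbalanced <- function(dna_vaf, rna_vaf, dna_cutoff = 0.10,
                                rna_cutoff = 0.05) {
  if (any(dna_vaf < 0 | dna_vaf > 1 | rna_vaf < 0 | rna_vaf > 1,
          na.rm = TRUE))
    stop("VAFs must be in [0, 1]", call. = FALSE)
  dna_vaf > dna_cutoff & rna_vaf < rna_cutoff
}

#' Pair DNA and RNA calls and analyze allelic expression imbalance
#'
#' Joins a DNA call set with an RNA call set on (sample, variant key) for
#' DNA-positive variants, excludes records with low RNA coverage of the
#' variant position, computes DNA:RNA VAF ratios and flags imbalanced
#' records. A variant absent from the RNA call set but present in the RNA
#' table's depth record is treated as RNA VAF 0 only if an `rna_vaf` is
#' supplied; otherwise RNA VAF comes from the matched RNA call (0 when the
#' variant key was assayed but not called, encoded by a row with vaf 0).
#'
#' @param dna A `DNA_PANEL` `callset`.
#' @param rna An RNA-platform `callset` whose rows carry the measured RNA
#'   VAF and depth at the DNA variant positions (uncalled variants may be
#'   present with `vaf = 0`).
#' @param min_rna_depth Records with RNA `total_depth` below this are
#'   excluded as low-coverage (default 50 reads).
#' @param floor RNA VAF floor for ratios, see [vaf_ratio()].
#' @return Data frame of class `"imbalance_records"`: one row per
#'   DNA-positive variant matched in the RNA table, with `dna_vaf`,
#'   `rna_vaf`, `rna_depth`, `excluded_low_coverage`, `ratio` (`NA` when
#'   excluded) and `imbalanced`.
#' @export
pair_dna_rna <- function(dna, rna, min_rna_depth = 50, floor = 0.005) {
  stopifnot(inherits(dna, "callset"), inherits(rna, "callset"))
  if (dna$platform != "DNA_PANEL")
    stop("'dna' must be a DNA_PANEL call set", call. = FALSE)
  dv <- dna$variants[dna$variants$vaf > 0 & dna$variants$is_expressed_locus,
                     , drop = FALSE]
  rv <- rna$variants
  m <- match(paste(dv$sample_id, dv$key), paste(rv$sample_id, rv$key))
  rec <- data.frame(
    sample_id = dv$sample_id, key = dv$key, dna_vaf = dv$vaf,
    rna_vaf = rv$vaf[m], rna_depth = rv$total_depth[m],
    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$rna_vaf), , drop = FALSE]
  rec$excluded_low_coverage <- rec$rna_depth < min_rna_depth
  rec$ratio <- NA_real_
  keep <- !rec$excluded_low_coverage
  rec$ratio[keep] <- vaf_ratio(rec$dna_vaf[keep], rec$rna_vaf[keep], floor)
  rec$imbalanced <- keep & classify_imbalanced(rec$dna_vaf, rec$rna_vaf)
  rownames(rec) <- NULL
  class(rec) <- c("imbalance_records", "data.frame")
  rec
}

#' Summarize allelic-imbalance records
#'
#' Applies low-coverage exclusions, then reports how many variants show
#' strong wild-type-allele expression bias and the range of DNA:RNA VAF
#' ratios among them.
#'
#' @param records An `imbalance_records` data frame (from [pair_dna_rna()],
#'   or any data frame with `dna_vaf`, `rna_vaf`, `ratio` and optional
#'   `excluded_low_coverage` columns).
#' @param floor RNA VAF floor used if `ratio` is missing.
#' @return List of class `"imbalance_summary"`: `n_considered`,
#'   `n_excluded`, `n_imbalanced`, `ratio_min`, `ratio_max`,
#'   `n_ratio_gt10` (ratios above 10 among imbalanced records).
#' @export
imbalance_summary <- function(records, floor = 0.005) {
  if (nrow(records) == 0L)
    stop("no imbalance records supplied", call. = FALSE)
  if (!"excluded_low_coverage" %in% names(records))
    records$excluded_low_coverage <- FALSE
  kept <- records[!records$excluded_low_coverage, , drop = FALSE]
  n_excluded <- sum(records$excluded_low_coverage)
  if (nrow(kept) == 0L) {
    warning("all records excluded for low RNA coverage", call. = FALSE)
    return(structure(list(n_considered = 0L, n_excluded = n_excluded,
                          n_imbalanced = 0L, ratio_min = NA_real_,
                          ratio_max = NA_real_, n_ratio_gt10 = 0L),
                     class = "imbalance_summary"))
  }
  if (!"ratio" %in% names(kept) || anyNA(kept$ratio))
    kept$ratio <- vaf_ratio(kept$dna_vaf, kept$rna_vaf, floor)
  if (!"imbalanced" %in% names(kept))
    kept$imbalanced <- classify_imbalanced(kept$dna_vaf, kept$rna_vaf)
  imb <- kept[kept$imbalanced, , drop = FALSE]
  structure(list(
    n_considered = nrow(kept),
    n_excluded = n_excluded,
    n_imbalanced = nrow(imb),
    ratio_min = if (nrow(imb)) min(imb$ratio) else NA_real_,
    ratio_max = if (nrow(imb)) max(imb$ratio) else NA_real_,
    n_ratio_gt10 = sum(imb$ratio > 10)),
    class = "imbalance_summary")
}

#' @export
print.imbalance_summary <- function(x, ...) {
  cat("Allelic expression imbalance: ", x$n_imbalanced, " of ",
      x$n_considered, " DNA-positive variants (", x$n_excluded,
      " excluded for low RNA coverage)\n", sep = "")
  if (x$n_imbalanced > 0)
    cat("  DNA:RNA VAF ratio ", sprintf("%.1f", x$ratio_min), " to ",
        sprintf("%.1f", x$ratio_max), " (", x$n_ratio_gt10,
        " with ratio > 10)\n", sep = "")
  invisible(x)
}

#' Scatter-style export of paired DNA/RNA VAFs
#'
#' One row per non-excluded paired variant with a detection category,
#' suitable for plotting DNA VAF against RNA VAF.
#'
#' @param records An `imbalance_records` data frame.
#' @return Data frame with `sample_id`, `key`, `dna_vaf`, `rna_vaf`,
#'   `category` (`"imbalanced"` or `"balanced"`).
#' @export
imbalance_scatter <- function(records) {
  kept <- records[!records$excluded_low_coverage, , drop = FALSE]
  out <- data.frame(sample_id = kept$sample_id, key = kept$key,
                    dna_vaf = kept$dna_vaf, rna_vaf = kept$rna_vaf,
                    category = ifelse(kept$imbalanced, "imbalanced",
                                      "balanced"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
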