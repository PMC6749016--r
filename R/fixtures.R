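# Packaged validation fixtures. These reconstruct, in code, the three
# published summary tables of the thyroid-FNA cross-platform validation
# series that the pipeline is designed to reproduce: the platform
# concordance counts, the 190-nodule clinical-performance table, and the
# promoter-variant co-occurrence rows. They are data, not test logic:
# tests and the acceptance script run the pipeline on them.

#' Platform concordance count fixture
#'
#' Event counts of the three platform comparisons in the validation
#' series: whole-transcriptome RNA-seq (test) vs the targeted DNA variant
#' panel at a 5% DNA VAF cutoff, vs the targeted RNA variant panel, and vs
#' the targeted RNA fusion panel.
#'
#' @return Data frame with one row per comparison: `method`, `unit`,
#'   `n_samples`, `test_only`, `ref_only`, `both`.
#' @export
table2_counts <- function() {
  data.frame(
    method = c("DNA variants", "RNA variants", "Fusions"),
    unit = c("variant_event", "variant_event", "fusion_event"),
    n_samples = c(501L, 102L, 695L),
    test_only = c(2L, 4L, 0L),
    ref_only = c(47L, 9L, 11L),
    both = c(134L, 72L, 50L),
    stringsAsFactors = FALSE)
}

# (subtype, classifier call, alteration label, nodule count) blocks of the
# 190-nodule series; alteration "" = no variant or fusion. Comma-joined
# labels are two co-occurring variants of one nodule.
table3_blocks <- function() {
  b <- function(subtype, gsc, alteration, n)
    data.frame(histology = subtype, gsc_call = gsc,
               alterations = alteration, n = n, stringsAsFactors = FALSE)
  rbind(
    # --- histologically benign ---
    b("BFN", "benign", "EIF1AX:p.G8R", 1),
    b("BFN", "benign", "TSHR:p.I486M", 1),
    b("BFN", "benign", "TSHR:p.L512R", 1),
    b("BFN", "benign", "TSHR:p.M453T", 1),
    b("BFN", "benign", "", 34),
    b("BFN", "suspicious", "HRAS:p.Q61R", 2),
    b("BFN", "suspicious", "NRAS:p.Q61K", 1),
    b("BFN", "suspicious", "NRAS:p.Q61R", 1),
    b("BFN", "suspicious", "", 7),
    b("HN", "benign", "TSHR:p.I568T", 1),
    b("HN", "benign", "", 4),
    b("FA", "benign", "GNAS:p.Q870H", 1),
    b("FA", "benign", "SPOP:p.P94R", 3),
    b("FA", "benign", "TSHR:p.D633Y", 1),
    b("FA", "benign", "TSHR:p.L629F", 1),
    b("FA", "benign", "", 31),
    b("FA", "suspicious", "HRAS:p.Q61R", 1),
    b("FA", "suspicious", "NRAS:p.Q61R", 3),
    b("FA", "suspicious", "PAX8/PPARG", 1),
    b("FA", "suspicious", "", 12),
    b("FT-UMP", "benign", "", 4),
    b("FT-UMP", "suspicious", "HRAS:p.Q61R", 1),
    b("FT-UMP", "suspicious", "NRAS:p.Q61R", 1),
    b("FT-UMP", "suspicious", "SPOP:p.P94R", 1),
    b("FT-UMP", "suspicious", "", 2),
    b("WDT-UMP", "benign", "", 4),
    b("WDT-UMP", "suspicious", "HRAS:p.Q61R", 2),
    b("WDT-UMP", "suspicious", "NRAS:p.Q61R", 1),
    b("WDT-UMP", "suspicious", "PAX8/PPARG", 1),
    b("HCA", "benign", "EIF1AX:p.G9D", 1),
    b("HCA", "benign", "PTEN:p.G129R", 1),
    b("HCA", "benign", "TSHR:p.L629F, EZH1:p.Y642F", 1),
    b("HCA", "benign", "TSHR:p.S425I", 1),
    b("HCA", "benign", "", 6),
    b("HCA", "suspicious", "NRAS:p.Q61K", 2),
    b("HCA", "suspicious", "TSHR:p.M453T", 1),
    b("HCA", "suspicious", "TSHR:p.S281I", 1),
    b("HCA", "suspicious", "", 3),
    b("CLT", "benign", "", 1),
    b("CLT", "suspicious", "", 1),
    b("HTA", "suspicious", "PAX8/GLIS3", 1),
    # --- histologically malignant ---
    b("PTC", "benign", "", 2),
    b("PTC", "suspicious", "BRAF:p.V600E", 3),
    b("PTC", "suspicious", "NRAS:p.Q61R", 1),
    b("PTC", "suspicious", "SPOP:p.P94R", 1),
    b("PTC", "suspicious", "MKRN1/BRAF", 1),
    b("PTC", "suspicious", "ETV6/NTRK3", 1),
    b("PTC", "suspicious", "", 6),
    b("PTC-TCV", "suspicious", "", 1),
    b("FVPTC", "benign", "", 1),
    b("FVPTC", "suspicious", "HRAS:p.Q61R", 1),
    b("FVPTC", "suspicious", "KRAS:p.Q61R, EIF1AX:p.A113_splice", 1),
    b("FVPTC", "suspicious", "NRAS:p.Q61K", 1),
    b("FVPTC", "suspicious", "NRAS:p.Q61R", 4),
    b("FVPTC", "suspicious", "", 3),
    b("HCC-c", "benign", "TSHR:p.I568T", 1),
    b("HCC-c", "suspicious", "EIF1AX:p.A113_splice", 1),
    b("HCC-c", "suspicious", "NRAS:p.Q61R", 1),
    b("HCC-c", "suspicious", "", 6),
    b("FC", "suspicious", "BRAF:p.K601E", 1),
    b("FC", "suspicious", "HRAS:p.G13R", 1),
    b("FC", "suspicious", "NRAS:p.Q61R", 1),
    b("FC", "suspicious", "", 4),
    b("PDTC", "suspicious", "NRAS:p.Q61K", 1),
    b("MTC", "suspicious", "HRAS:p.Q61R", 1))
}

#' 190-nodule clinical performance fixture
#'
#' Per-nodule reconstruction of the indeterminate-cytology (Bethesda
#' III/IV) clinical validation series: 145 histologically benign and 45
#' malignant nodules with their classifier call and the RNA-seq variants
#' and fusions attributed to each (comma-joined labels are two variants in
#' one nodule). Per-nodule Bethesda subcategory is not published, so
#' `bethesda` is `"unknown"`.
#'
#' @return Data frame with columns `sample_id`, `bethesda`, `gsc_call`,
#'   `histology`, `histology_class`, `alterations` (empty string when no
#'   variant or fusion was observed).
#' @export
table3_nodules <- function() {
  blocks <- table3_blocks()
  df <- blocks[rep(seq_len(nrow(blocks)), blocks$n),
               c("histology", "gsc_call", "alterations"), drop = FALSE]
  df <- data.frame(sample_id = sprintf("N%03d", seq_len(nrow(df))),
                   bethesda = "unknown", gsc_call = df$gsc_call,
                   histology = df$histology, alterations = df$alterations,
                   stringsAsFactors = FALSE)
  df$histology_class <- histology_class(df$histology)
  df[c("sample_id", "bethesda", "gsc_call", "histology",
       "histology_class", "alterations")]
}

#' Convert the nodule fixture into a call set
#'
#' Expands the `alterations` labels of [table3_nodules()] (or any table in
#' the same shape) into an RNA-seq `callset`: `"GENE:p.X"` entries become
#' variant calls, `"A/B"` entries fusion calls. Read-level fields are
#' nominal placeholders (the fixture records presence, not depths).
#'
#' @param nodules Data frame with `sample_id` and `alterations`.
#' @return A `WTS_RNASEQ` `callset`.
#' @export
table3_callset <- function(nodules = table3_nodules()) {
  vrows <- list(); frows <- list()
  for (i in seq_len(nrow(nodules))) {
    lab <- nodules$alterations[i]
    if (is.na(lab) || !nzchar(lab)) next
    for (entry in trimws(strsplit(lab, ",", fixed = TRUE)[[1]])) {
      if (grepl("/", entry, fixed = TRUE)) {
        p <- strsplit(entry, "/", fixed = TRUE)[[1]]
        frows[[length(frows) + 1L]] <- data.frame(
          sample_id = nodules$sample_id[i], partner5 = p[1],
          partner3 = p[2], supporting_reads = 100L,
          total_valid_mapped_reads = 100000L, stringsAsFactors = FALSE)
      } else {
        p <- strsplit(entry, ":", fixed = TRUE)[[1]]
        vrows[[length(vrows) + 1L]] <- data.frame(
          sample_id = nodules$sample_id[i], gene = p[1],
          protein_change = p[2], vaf = 0.3, alt_depth = 30L,
          total_depth = 100L, stringsAsFactors = FALSE)
      }
    }
  }
  callset("WTS_RNASEQ",
          variants = if (length(vrows)) do.call(rbind, vrows),
          fusions = if (length(frows)) do.call(rbind, frows))
}

#' Promoter-variant co-occurrence fixture
#'
#' The 15 samples of the series carrying the TERT promoter hotspot C228T
#' on the targeted DNA panel, with their cytology category, histology and
#' co-occurring driver variant (one sample carries the promoter variant in
#' isolation). One nodule has unknown histopathology.
#'
#' @return Data frame: `sample_id`, `bethesda`, `gsc_call`, `histology`,
#'   `histology_class`, `partner_variant` (`""` when none),
#'   `tert_variant`.
#' @export
table4_tert <- function() {
  df <- data.frame(
    bethesda = c("II", rep("IV", 7), rep("V", 2), rep("VI", 5)),
    histology = c("FVPTC", "HCA", "HCA", "HN", "FA", "WDT-UMP", "PTC",
                  "FC-v", "PTC", "PTC", "PTC", "PTC-TCV", "PTC-TCV",
                  "unknown", "FC-v"),
    partner_variant = c("NRAS:p.Q61K", "HRAS:p.Q61R", "NRAS:p.Q61K",
                        "NRAS:p.Q61R", "NRAS:p.Q61R", "NRAS:p.Q61R",
                        "KRAS:p.Q61R", "NRAS:p.Q61R", "BRAF:p.V600E",
                        "BRAF:p.V600E", "BRAF:p.V600E", "BRAF:p.V600E",
                        "BRAF:p.V600E", "BRAF:p.V600E", ""),
    stringsAsFactors = FALSE)
  df <- data.frame(sample_id = sprintf("T%02d", seq_len(nrow(df))),
                   bethesda = df$bethesda, gsc_call = "suspicious",
                   histology = df$histology,
                   histology_class = histology_class(df$histology),
                   partner_variant = df$partner_variant,
                   tert_variant = "C228T", stringsAsFactors = FALSE)
  df
}

#' DNA-panel call set of the co-occurrence fixture
#'
#' @param tert Data frame from [table4_tert()].
#' @return A `DNA_PANEL` `callset` carrying each sample's promoter
#'   variant (flagged non-expressed) and driver partner variant.
#' @export
table4_callset <- function(tert = table4_tert()) {
  rows <- list()
  for (i in seq_len(nrow(tert))) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = tert$sample_id[i], gene = "TERT",
      protein_change = tert$tert_variant[i], vaf = 0.3, alt_depth = 150L,
      total_depth = 500L, is_expressed_locus = FALSE,
      stringsAsFactors = FALSE)
    pv <- tert$partner_variant[i]
    if (nzchar(pv)) {
      p <- strsplit(pv, ":", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = tert$sample_id[i], gene = p[1], protein_change = p[2],
        vaf = 0.3, alt_depth = 150L, total_depth = 500L,
        is_expressed_locus = TRUE, stringsAsFactors = FALSE)
    }
  }
  callset("DNA_PANEL", variants = do.call(rbind, rows))
}

#' Write the packaged fixtures as TSV files
#'
#' Writes the concordance-count, nodule and co-occurrence fixtures in the
#' package's tab-delimited dialect.
#'
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("table2_concordance.tsv",
                                "table3_nodules.tsv", "table4_tert.tsv"))
  write_tsv(table2_counts(), paths[1])
  write_tsv(table3_nodules(), paths[2])
  write_tsv(table4_tert(), paths[3])
  invisible(paths)
}
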