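# Tab-delimited dialects. Column orders are fixed so that written files can
# be consumed by other tools without a schema:
#   variants: sample_id gene protein_change vaf alt_depth total_depth platform
#   fusions : sample_id partner5 partner3 supporting_reads
#             total_valid_mapped_reads platform
#   metadata: sample_id bethesda gsc_call histology

VARIANT_TSV_COLS <- c("sample_id", "gene", "protein_change", "vaf",
                      "alt_depth", "total_depth", "platform")
FUSION_TSV_COLS <- c("sample_id", "partner5", "partner3",
                     "supporting_reads", "total_valid_mapped_reads",
                     "platform")
META_TSV_COLS <- c("sample_id", "bethesda", "gsc_call", "histology")

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), quote = "",
                    fileEncoding = "UTF-8")
}

#' Read a variant or fusion call set
#'
#' Reads one platform's calls from a tab-delimited table or a VCF v4.2
#' file into a [callset()]. TSV variant tables use the columns
#' `sample_id, gene, protein_change, vaf, alt_depth, total_depth, platform`;
#' fusion tables use `sample_id, partner5, partner3, supporting_reads,
#' total_valid_mapped_reads, platform`. For VCF input the VAF is taken from
#' the FORMAT `AF` field (falling back to `AD`), depth from `DP`, and the
#' sample id from the single sample column; gene and protein change come
#' from the INFO fields `GENE` and `PCHANGE`.
#'
#' @param path File to read.
#' @param platform Platform label for the resulting call set.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param type For TSV, `"variants"` or `"fusions"`; ignored for VCF
#'   (variants only).
#' @return A `callset`.
#' @export
read_callset <- function(path, platform, format = c("tsv", "vcf"),
                         type = c("variants", "fusions")) {
  format <- match.arg(format)
  type <- match.arg(type)
  platform <- match.arg(platform, PLATFORMS)
  if (format == "vcf") return(read_callset_vcf(path, platform))
  df <- tryCatch(read_tsv_strict(path), error = function(e)
    stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE))
  want <- if (type == "variants") VARIANT_TSV_COLS else FUSION_TSV_COLS
  missing_cols <- setdiff(setdiff(want, "platform"), names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  check_numeric_rows(df, path, type)
  if (type == "variants") callset(platform, variants = df)
  else callset(platform, fusions = df)
}

check_numeric_rows <- function(df, path, type) {
  cols <- if (type == "variants") c("vaf", "alt_depth", "total_depth")
          else c("supporting_reads", "total_valid_mapped_reads")
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    if (length(bad))
      # +1 for the header row so the message points at the file line
      stop(path, " line ", bad[1] + 1L, ": non-numeric value '",
           df[[col]][bad[1]], "' in column ", col, call. = FALSE)
  }
  if (type == "variants") {
    v <- as.numeric(df$vaf)
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad))
      stop(path, " line ", bad[1] + 1L, ": VAF ", v[bad[1]],
           " outside [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

read_callset_vcf <- function(path, platform) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0L || ncol(v@gt) < 2L)
    stop(path, ": VCF must contain exactly one sample column",
         call. = FALSE)
  if (ncol(v@gt) > 2L)
    stop(path, ": multi-sample VCF not supported; one sample per file",
         call. = FALSE)
  sample_id <- colnames(v@gt)[2]
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(v@fix)) else val
  }
  gene <- info_field("GENE")
  pchange <- info_field("PCHANGE")
  if (anyNA(gene) || anyNA(pchange))
    stop(path, ": every record needs INFO fields GENE and PCHANGE for ",
         "protein-level harmonization", call. = FALSE)
  af <- suppressWarnings(as.numeric(
    vcfR::extract.gt(v, element = "AF")[, 1]))
  dp <- suppressWarnings(as.integer(
    vcfR::extract.gt(v, element = "DP")[, 1]))
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  alt <- rep(NA_integer_, length(af))
  if (!all(is.na(ad))) {
    parts <- strsplit(ad, ",", fixed = TRUE)
    alt <- vapply(parts, function(p)
      if (length(p) >= 2) suppressWarnings(as.integer(p[2]))
      else NA_integer_, integer(1))
    ref <- vapply(parts, function(p)
      suppressWarnings(as.integer(p[1])), integer(1))
    if (all(is.na(dp))) dp <- ref + alt
  }
  need_af <- is.na(af)
  af[need_af] <- alt[need_af] / dp[need_af]  # AD-derived fallback
  if (anyNA(af))
    stop(path, ": cannot determine VAF (no AF and no usable AD)",
         call. = FALSE)
  alt[is.na(alt)] <- as.integer(round(af[is.na(alt)] * dp[is.na(alt)]))
  callset(platform, variants = data.frame(
    sample_id = sample_id, gene = gene, protein_change = pchange,
    vaf = af, alt_depth = alt, total_depth = dp,
    stringsAsFactors = FALSE))
}

#' Write a call set to tab-delimited files
#'
#' Writes the variant and/or fusion tables of a call set in the package's
#' TSV dialect, such that [read_callset()] reproduces all fields exactly.
#'
#' @param x A `callset`.
#' @param variants_path,fusions_path Output paths; either may be `NULL` to
#'   skip that table.
#' @return Invisibly, the paths written.
#' @export
write_callset <- function(x, variants_path = NULL, fusions_path = NULL) {
  stopifnot(inherits(x, "callset"))
  written <- character()
  if (!is.null(variants_path)) {
    df <- x$variants[, intersect(c(VARIANT_TSV_COLS, "is_expressed_locus"),
                                 names(x$variants)), drop = FALSE]
    write_tsv(df, variants_path)
    written <- c(written, variants_path)
  }
  if (!is.null(fusions_path)) {
    write_tsv(x$fusions[, FUSION_TSV_COLS, drop = FALSE], fusions_path)
    written <- c(written, fusions_path)
  }
  invisible(written)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

HISTOLOGY_MALIGNANT <- c("FC", "FC-c", "FC-v", "FVPTC", "mFVPTC", "HCC",
                         "HCC-c", "HCC-v", "PTC", "mPTC", "PTC-TCV",
                         "mPTC-TCV", "MTC", "PDC", "PDTC", "WDC-NOS")
HISTOLOGY_BENIGN <- c("BFN", "CLT", "FA", "HCA", "HN", "HTA",
                      "FT-UMP", "WDT-UMP")

#' Classify a histopathology subtype as benign or malignant
#'
#' Maps histology subtype codes to the benign/malignant grouping used for
#' clinical performance. Tumors of unknown malignant potential (FT-UMP,
#' WDT-UMP) count as benign by default.
#'
#' @param histology Character vector of subtype codes (e.g. `"PTC"`,
#'   `"BFN"`); unrecognized codes map to `"unknown"`.
#' @param ump_malignant Logical; reassign FT-UMP/WDT-UMP to malignant.
#' @return Character vector in `{"benign", "malignant", "unknown"}`.
#' @export
histology_class <- function(histology, ump_malignant = FALSE) {
  out <- ifelse(histology %in% HISTOLOGY_MALIGNANT, "malignant",
                ifelse(histology %in% HISTOLOGY_BENIGN, "benign",
                       "unknown"))
  if (ump_malignant)
    out[histology %in% c("FT-UMP", "WDT-UMP")] <- "malignant"
  out
}

#' Read sample metadata
#'
#' Reads the sample metadata table (`sample_id, bethesda, gsc_call,
#' histology`) and derives `histology_class`. Bethesda categories are II-VI
#' (or `"unknown"`); classifier calls are `benign`, `suspicious`,
#' `no_result` or `not_applicable`.
#'
#' @param path TSV file.
#' @param ump_malignant Passed to [histology_class()].
#' @return Data frame with the four input columns plus `histology_class`.
#' @export
read_metadata <- function(path, ump_malignant = FALSE) {
  df <- read_tsv_strict(path)
  missing_cols <- setdiff(META_TSV_COLS, names(df))
  if (length(missing_cols))
    stop(path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validate_metadata(df, ump_malignant)
}

validate_metadata <- function(df, ump_malignant = FALSE) {
  df$bethesda[is.na(df$bethesda)] <- "unknown"
  df$gsc_call[is.na(df$gsc_call)] <- "not_applicable"
  df$histology[is.na(df$histology)] <- "unknown"
  bad <- setdiff(unique(df$bethesda),
                 c("II", "III", "IV", "V", "VI", "unknown"))
  if (length(bad))
    stop("invalid Bethesda category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$gsc_call),
                 c("benign", "suspicious", "no_result", "not_applicable"))
  if (length(bad))
    stop("invalid classifier call: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  df$histology_class <- histology_class(df$histology, ump_malignant)
  df
}
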