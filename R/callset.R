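#' @importFrom stats qbeta rbinom rbeta rpois rnbinom runif rlnorm setNames
#'   binom.test chisq.test pbinom dbinom
#' @importFrom utils read.delim write.table
NULL

PLATFORMS <- c("WTS_RNASEQ", "DNA_PANEL", "RNA_PANEL", "QPCR")

#' Canonical variant identity
#'
#' Builds the canonical identity used to match a variant across platforms:
#' an uppercase HGNC-style gene symbol plus an HGVS protein change in short
#' form (`p.` prefix enforced for coding changes). Non-coding loci such as
#' promoter variants keep their conventional token (e.g. `"C228T"`) and are
#' flagged as not expressed, since they cannot be observed in transcript
#' sequence and must never count towards RNA-platform positivity.
#'
#' @param gene Gene symbol; canonicalised to uppercase.
#' @param protein_change HGVS protein change (`"p.V600E"` or `"V600E"`), or
#'   a non-coding token such as `"C228T"` when `expressed = FALSE`.
#' @param expressed Logical; `FALSE` for loci undetectable in RNA
#'   (promoter variants). Default `TRUE`.
#' @return A list of class `"variant_key"` with elements `gene`,
#'   `protein_change`, `is_expressed_locus` and `id` (the canonical
#'   `"GENE:p.X"` string used for matching).
#' @examples
#' variant_key("braf", "V600E")
#' variant_key("TERT", "C228T", expressed = FALSE)
#' @export
variant_key <- function(gene, protein_change, expressed = TRUE) {
  gene <- trimws(as.character(gene))
  protein_change <- trimws(as.character(protein_change))
  if (length(gene) != 1L || is.na(gene) || !nzchar(gene))
    stop("variant key: 'gene' must be a non-empty string", call. = FALSE)
  if (length(protein_change) != 1L || is.na(protein_change) ||
      !nzchar(protein_change))
    stop("variant key: 'protein_change' must be a non-empty string",
         call. = FALSE)
  if (grepl("[^A-Za-z0-9_.-]", gene))
    stop("variant key: malformed gene symbol '", gene, "'", call. = FALSE)
  gene <- toupper(gene)
  pc <- normalize_protein_change(protein_change, expressed)
  structure(
    list(gene = gene, protein_change = pc,
         is_expressed_locus = isTRUE(expressed),
         id = paste0(gene, ":", pc)),
    class = "variant_key")
}

# Coding changes get a canonical "p." prefix and case-insensitive matching
# of the amino-acid body ("p.v600e" -> "p.V600E"); suffixes like "_splice"
# stay lowercase. Non-coding tokens (promoter variants) pass through as-is
# apart from uppercasing the nucleotide token.
normalize_protein_change <- function(pc, expressed) {
  if (!expressed && !grepl("^p\\.", pc, ignore.case = TRUE)) {
    # non-coding locus token, e.g. promoter "C228T"
    if (!grepl("^[A-Za-z][0-9]+[A-Za-z]$|^[A-Za-z0-9_>+-]+$", pc))
      stop("variant key: malformed locus token '", pc, "'", call. = FALSE)
    return(toupper(pc))
  }
  body <- sub("^p\\.", "", pc, ignore.case = TRUE)
  if (!nzchar(body))
    stop("variant key: malformed protein change '", pc, "'", call. = FALSE)
  # canonical case: letters in the substitution body uppercase, except
  # descriptive suffixes (e.g. "_splice", "fs", "del") which keep case
  if (grepl("^[A-Za-z][0-9]+[A-Za-z*]+$", body)) {
    body <- toupper(body)
  } else if (grepl("^[A-Za-z][0-9]+(_[A-Za-z0-9]+)+$", body)) {
    parts <- strsplit(body, "_", fixed = TRUE)[[1]]
    parts[1] <- toupper(parts[1])
    body <- paste(c(parts[1], tolower(parts[-1])), collapse = "_")
  } else if (!grepl("^[A-Za-z0-9_*=?]+$", body)) {
    stop("variant key: malformed protein change '", pc, "'", call. = FALSE)
  }
  paste0("p.", body)
}

#' @export
print.variant_key <- function(x, ...) {
  cat(x$id, if (!x$is_expressed_locus) "[non-expressed locus]", "\n")
  invisible(x)
}

#' @export
format.variant_key <- function(x, ...) x$id

#' Parse comma-joined alteration labels
#'
#' Report tables list co-occurring variants of one nodule as a comma-joined
#' string such as `"TSHR:p.L629F, EZH1:p.Y642F"`. This splits such a label
#' into one canonical [variant_key()] per entry.
#'
#' @param label String of one or more `"GENE:p.X"` entries, comma-separated.
#' @return List of `variant_key` objects (empty for `""`/`NA`).
#' @export
parse_variant_labels <- function(label) {
  if (length(label) != 1L) stop("one label at a time", call. = FALSE)
  if (is.na(label) || !nzchar(trimws(label))) return(list())
  entries <- trimws(strsplit(label, ",", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]
  lapply(entries, function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("cannot parse alteration label '", e, "'", call. = FALSE)
    variant_key(parts[1], parts[2])
  })
}

# Two fusions, and only two, carry colloquial display names in reports.
FUSION_COLLOQUIAL <- c("CCDC6:RET" = "RET/PTC1", "NCOA4:RET" = "RET/PTC3")

#' Canonical fusion identity and display names
#'
#' Fusion partners are matched in their 5'/3' order: the canonical id is the
#' ordered pair, so a reverse-orientation call is a different event. Two
#' display names are exposed: the 5'/3'-ordered name (`"STRN/ALK"`) and the
#' report-style name, which joins partners alphabetically except for the two
#' colloquial overrides `RET/PTC1` (= CCDC6/RET) and `RET/PTC3` (= NCOA4/RET).
#'
#' @param partner5,partner3 Gene symbols of the 5' and 3' partners.
#' @return List of class `"fusion_id"` with `partner5`, `partner3`, `id`
#'   (canonical ordered id), `name` (5'/3'-ordered display) and
#'   `report_name` (alphabetical/colloquial report style).
#' @examples
#' canonical_fusion_id("CCDC6", "RET")$report_name  # "RET/PTC1"
#' canonical_fusion_id("STRN", "ALK")$name          # "STRN/ALK"
#' @export
canonical_fusion_id <- function(partner5, partner3) {
  p5 <- toupper(trimws(as.character(partner5)))
  p3 <- toupper(trimws(as.character(partner3)))
  if (!nzchar(p5) || !nzchar(p3))
    stop("fusion id: both partners must be non-empty", call. = FALSE)
  if (identical(p5, p3))
    stop("fusion id: 5' and 3' partners must differ (got '", p5, "')",
         call. = FALSE)
  id <- paste0(p5, ":", p3)
  colloquial <- FUSION_COLLOQUIAL[id]
  report <- if (!is.na(colloquial)) unname(colloquial) else
    paste(sort(c(p5, p3)), collapse = "/")
  structure(
    list(partner5 = p5, partner3 = p3, id = id,
         name = paste0(p5, "/", p3), report_name = report),
    class = "fusion_id")
}

#' @export
print.fusion_id <- function(x, ...) {
  cat(x$name, if (x$report_name != x$name) paste0("(", x$report_name, ")"),
      "\n")
  invisible(x)
}

#' Construct a call set
#'
#' A call set is one platform's collection of variant and fusion calls,
#' with at most one variant call per (sample, variant key) and one fusion
#' call per (sample, canonical fusion id). Duplicate records are collapsed
#' to the maximum-depth record with a warning.
#'
#' @param platform One of `"WTS_RNASEQ"`, `"DNA_PANEL"`, `"RNA_PANEL"`,
#'   `"QPCR"`.
#' @param variants Data frame with columns `sample_id`, `gene`,
#'   `protein_change`, `vaf`, `alt_depth`, `total_depth` (and optionally
#'   `is_expressed_locus`); may be `NULL`/empty.
#' @param fusions Data frame with columns `sample_id`, `partner5`,
#'   `partner3`, `supporting_reads`, `total_valid_mapped_reads`; may be
#'   `NULL`/empty.
#' @return Object of class `"callset"`: list with `platform`, `variants`
#'   and `fusions` data frames. Variant rows gain canonical `gene`,
#'   `protein_change` and `key` columns; fusion rows gain `fusion_id` and
#'   `display_name`.
#' @export
callset <- function(platform, variants = NULL, fusions = NULL) {
  platform <- match.arg(platform, PLATFORMS)
  variants <- validate_variant_df(variants, platform)
  fusions <- validate_fusion_df(fusions, platform)
  structure(list(platform = platform, variants = variants,
                 fusions = fusions),
            class = "callset")
}

empty_variant_df <- function() {
  data.frame(sample_id = character(), gene = character(),
             protein_change = character(), vaf = numeric(),
             alt_depth = integer(), total_depth = integer(),
             platform = character(), is_expressed_locus = logical(),
             key = character(), stringsAsFactors = FALSE)
}

empty_fusion_df <- function() {
  data.frame(sample_id = character(), partner5 = character(),
             partner3 = character(), supporting_reads = integer(),
             total_valid_mapped_reads = integer(), platform = character(),
             fusion_id = character(), display_name = character(),
             stringsAsFactors = FALSE)
}

validate_variant_df <- function(df, platform) {
  if (is.null(df) || nrow(df) == 0L) return(empty_variant_df())
  req <- c("sample_id", "gene", "protein_change", "vaf", "alt_depth",
           "total_depth")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("variant table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"is_expressed_locus" %in% names(df))
    df$is_expressed_locus <- TRUE
  df$is_expressed_locus <- as.logical(df$is_expressed_locus)
  df$vaf <- as.numeric(df$vaf)
  df$alt_depth <- as.integer(df$alt_depth)
  df$total_depth <- as.integer(df$total_depth)
  bad <- which(is.na(df$vaf) | df$vaf < 0 | df$vaf > 1)
  if (length(bad))
    stop("variant row ", bad[1], ": VAF ", df$vaf[bad[1]],
         " outside [0, 1]", call. = FALSE)
  bad <- which(!is.na(df$total_depth) & df$total_depth <= 0L)
  if (length(bad))
    stop("variant row ", bad[1], ": total_depth must be positive",
         call. = FALSE)
  bad <- which(!is.na(df$alt_depth) & !is.na(df$total_depth) &
                 df$alt_depth > df$total_depth)
  if (length(bad))
    stop("variant row ", bad[1], ": alt_depth exceeds total_depth",
         call. = FALSE)
  # VAF must be consistent with its read counts up to table-export rounding
  both <- !is.na(df$alt_depth) & !is.na(df$total_depth)
  incons <- which(both &
    abs(df$vaf - df$alt_depth / df$total_depth) > 0.005 + 1e-12)
  if (length(incons))
    stop("variant row ", incons[1], ": vaf inconsistent with ",
         "alt_depth/total_depth beyond tolerance 0.005", call. = FALSE)
  keys <- mapply(function(g, p, e) variant_key(g, p, e)$id,
                 df$gene, df$protein_change, df$is_expressed_locus)
  df$gene <- toupper(trimws(df$gene))
  df$protein_change <- sub("^[^:]+:", "", keys)
  df$key <- unname(keys)
  df$platform <- platform
  df <- collapse_duplicates(df, c("sample_id", "key"), "total_depth",
                            what = "variant")
  df <- df[names(empty_variant_df())]
  rownames(df) <- NULL
  df
}

validate_fusion_df <- function(df, platform) {
  if (is.null(df) || nrow(df) == 0L) return(empty_fusion_df())
  req <- c("sample_id", "partner5", "partner3", "supporting_reads",
           "total_valid_mapped_reads")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("fusion table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$supporting_reads <- as.integer(df$supporting_reads)
  df$total_valid_mapped_reads <- as.integer(df$total_valid_mapped_reads)
  if (any(df$supporting_reads < 0, na.rm = TRUE))
    stop("fusion supporting_reads must be non-negative", call. = FALSE)
  ids <- mapply(function(a, b) canonical_fusion_id(a, b),
                df$partner5, df$partner3, SIMPLIFY = FALSE)
  df$partner5 <- vapply(ids, `[[`, "", "partner5")
  df$partner3 <- vapply(ids, `[[`, "", "partner3")
  df$fusion_id <- vapply(ids, `[[`, "", "id")
  df$display_name <- vapply(ids, `[[`, "", "name")
  df$platform <- platform
  df <- collapse_duplicates(df, c("sample_id", "fusion_id"),
                            "supporting_reads", what = "fusion")
  df <- df[names(empty_fusion_df())]
  rownames(df) <- NULL
  df
}

# Keep the best-measured record among duplicates (max depth/support);
# deterministic tie-break on original order.
collapse_duplicates <- function(df, key_cols, depth_col, what) {
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  if (!anyDuplicated(key)) return(df)
  warning("collapsed ", sum(duplicated(key)), " duplicate ", what,
          " record(s) to the maximum-", depth_col, " record",
          call. = FALSE)
  ord <- order(key, -df[[depth_col]], seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df[!duplicated(key[ord]), , drop = FALSE]
}

#' @export
print.callset <- function(x, ...) {
  cat("Call set [", x$platform, "]: ", nrow(x$variants), " variant call(s), ",
      nrow(x$fusions), " fusion call(s), ",
      length(unique(c(x$variants$sample_id, x$fusions$sample_id))),
      " sample(s)\n", sep = "")
  invisible(x)
}

#' Number of calls in a call set
#' @param x A `callset`.
#' @export
n_calls <- function(x) {
  stopifnot(inherits(x, "callset"))
  nrow(x$variants) + nrow(x$fusions)
}

#' Restrict a call set to a set of samples
#' @param x A `callset`.
#' @param sample_ids Character vector of sample ids to keep.
#' @return A `callset` containing only calls from those samples.
#' @export
restrict_samples <- function(x, sample_ids) {
  stopifnot(inherits(x, "callset"))
  x$variants <- x$variants[x$variants$sample_id %in% sample_ids, ,
                           drop = FALSE]
  x$fusions <- x$fusions[x$fusions$sample_id %in% sample_ids, ,
                         drop = FALSE]
  rownames(x$variants) <- rownames(x$fusions) <- NULL
  x
}

#' Filter DNA calls at a variant-allele-frequency cutoff
#'
#' DNA positivity in cross-platform comparisons is defined at a VAF cutoff
#' (typically 5% or 20%): a DNA variant call is positive when its VAF is at
#' least the cutoff. Fusion calls are untouched. Raising the cutoff always
#' yields a subset of the calls retained at a lower cutoff.
#'
#' @param x A `callset` with `platform == "DNA_PANEL"` (the threshold
#'   encodes DNA-positivity semantics).
#' @param cutoff VAF cutoff in (0, 1); calls with `vaf >= cutoff` are kept.
#' @return The filtered `callset`.
#' @export
apply_dna_vaf_threshold <- function(x, cutoff) {
  stopifnot(inherits(x, "callset"))
  if (x$platform != "DNA_PANEL")
    stop("VAF positivity threshold applies to DNA_PANEL call sets only ",
         "(got ", x$platform, ")", call. = FALSE)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= 1)
    stop("cutoff must be a single value in (0, 1)", call. = FALSE)
  x$variants <- x$variants[x$variants$vaf >= cutoff, , drop = FALSE]
  rownames(x$variants) <- NULL
  x
}
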