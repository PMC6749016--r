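test_that("variant keys canonicalise case and protein-change prefix", {
  k <- variant_key("braf", "V600E")
  expect_equal(k$gene, "BRAF")
  expect_equal(k$protein_change, "p.V600E")
  expect_equal(k$id, "BRAF:p.V600E")
  expect_true(k$is_expressed_locus)
  # case-insensitive input, canonical-case output
  expect_equal(variant_key("Braf", "p.v600e")$id, "BRAF:p.V600E")
  # splice-style suffixes keep their descriptive lowercase part
  expect_equal(variant_key("EIF1AX", "p.A113_splice")$protein_change,
               "p.A113_splice")
  # promoter locus: token retained, flagged non-expressed
  tert <- variant_key("TERT", "C228T", expressed = FALSE)
  expect_equal(tert$id, "TERT:C228T")
  expect_false(tert$is_expressed_locus)
  expect_error(variant_key("", "V600E"), "gene")
  expect_error(variant_key("BRAF", "  "), "protein_change")
})

test_that("comma-joined alteration labels split into two keys", {
  keys <- parse_variant_labels("TSHR:p.L629F, EZH1:p.Y642F")
  expect_length(keys, 2)
  expect_equal(vapply(keys, `[[`, "", "id"),
               c("TSHR:p.L629F", "EZH1:p.Y642F"))
  expect_length(parse_variant_labels(""), 0)
})

test_that("fusion ids keep 5'/3' order with exactly two colloquial names", {
  f <- canonical_fusion_id("CCDC6", "RET")
  expect_equal(f$report_name, "RET/PTC1")
  expect_equal(f$id, "CCDC6:RET")
  expect_equal(canonical_fusion_id("NCOA4", "RET")$report_name, "RET/PTC3")
  expect_equal(canonical_fusion_id("PAX8", "PPARG")$report_name,
               "PAX8/PPARG")
  # 5'/3'-ordered display preserved even when alphabetical order differs
  s <- canonical_fusion_id("STRN", "ALK")
  expect_equal(s$name, "STRN/ALK")
  expect_equal(s$report_name, "ALK/STRN")
  # deterministic and idempotent on its own output partners
  again <- canonical_fusion_id(s$partner5, s$partner3)
  expect_identical(again, s)
  # reverse orientation is a different canonical id
  expect_false(canonical_fusion_id("RET", "CCDC6")$id == f$id)
  expect_error(canonical_fusion_id("RET", "ret"), "differ")
})

test_that("callset validates depth/VAF consistency and collapses duplicates", {
  base <- data.frame(sample_id = "S1", gene = "BRAF",
                     protein_change = "p.V600E", vaf = 0.3,
                     alt_depth = 30L, total_depth = 100L,
                     stringsAsFactors = FALSE)
  expect_s3_class(callset("DNA_PANEL", variants = base), "callset")
  bad_vaf <- transform(base, vaf = 1.2)
  expect_error(callset("DNA_PANEL", variants = bad_vaf), "outside")
  bad_depth <- transform(base, alt_depth = 150L)
  expect_error(callset("DNA_PANEL", variants = bad_depth), "exceeds")
  # vaf must match alt/total within 0.005
  incons <- transform(base, vaf = 0.32)
  expect_error(callset("DNA_PANEL", variants = incons), "tolerance")
  dup <- rbind(base, transform(base, vaf = 0.31, alt_depth = 62L,
                               total_depth = 200L))
  expect_warning(cs <- callset("DNA_PANEL", variants = dup), "duplicate")
  expect_equal(nrow(cs$variants), 1L)
  expect_equal(cs$variants$total_depth, 200L)  # max-depth record kept
})

test_that("TSV round trip reproduces all fields", {
  set.seed(7)
  cs <- random_variant_calls(12)
  fus <- callset("WTS_RNASEQ", fusions = data.frame(
    sample_id = c("S1", "S2"), partner5 = c("CCDC6", "STRN"),
    partner3 = c("RET", "ALK"), supporting_reads = c(40L, 21L),
    total_valid_mapped_reads = c(50000L, 23000L),
    stringsAsFactors = FALSE))
  vpath <- withr::local_tempfile(fileext = ".tsv")
  fpath <- withr::local_tempfile(fileext = ".tsv")
  write_callset(cs, variants_path = vpath)
  write_callset(fus, fusions_path = fpath)
  back_v <- read_callset(vpath, "WTS_RNASEQ", type = "variants")
  back_f <- read_callset(fpath, "WTS_RNASEQ", type = "fusions")
  expect_equal(back_v$variants, cs$variants)
  expect_equal(back_f$fusions, fus$fusions)
})

test_that("TSV parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("sample_id", "gene", "protein_change", "vaf",
                       "alt_depth", "total_depth", "platform"),
                     collapse = "\t"),
               "S1\tBRAF\tp.V600E\t1.2\t30\t100\tWTS_RNASEQ"), path)
  expect_error(read_callset(path, "WTS_RNASEQ"), "line 2")
})

test_that("VCF input maps AF/DP/sample column to a call set", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele freq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "S001"), collapse = "\t"),
    paste(c("7", "140453136", ".", "A", "T", "99", "PASS",
            "GENE=BRAF;PCHANGE=p.V600E", "GT:AF:DP",
            "0/1:0.32:500"), collapse = "\t")), path)
  cs <- read_callset(path, "DNA_PANEL", format = "vcf")
  expect_equal(nrow(cs$variants), 1L)
  expect_equal(cs$variants$sample_id, "S001")
  expect_equal(cs$variants$vaf, 0.32)
  expect_equal(cs$variants$total_depth, 500L)
  expect_equal(cs$variants$key, "BRAF:p.V600E")
})

test_that("DNA VAF threshold keeps exactly the calls at/above the cutoff", {
  df <- data.frame(sample_id = c("S1", "S2"), gene = "BRAF",
                   protein_change = "p.V600E", vaf = c(0.32, 0.04),
                   alt_depth = c(32L, 4L), total_depth = c(100L, 100L),
                   stringsAsFactors = FALSE)
  cs <- callset("DNA_PANEL", variants = df)
  kept <- apply_dna_vaf_threshold(cs, 0.05)
  expect_equal(kept$variants$sample_id, "S1")
  # threshold semantics are DNA positivity only
  rna <- callset("WTS_RNASEQ", variants = df)
  expect_error(apply_dna_vaf_threshold(rna, 0.05), "DNA_PANEL")
  expect_error(apply_dna_vaf_threshold(cs, 1.5), "cutoff")
})

test_that("filtering at a higher cutoff yields a subset (property)", {
  set.seed(11)
  for (rep in 1:20) {
    cs <- random_variant_calls(30, n_samples = 8, platform = "DNA_PANEL")
    cuts <- sort(runif(2, 0.02, 0.6))
    lo <- apply_dna_vaf_threshold(cs, cuts[1])$variants
    hi <- apply_dna_vaf_threshold(cs, cuts[2])$variants
    expect_true(all(paste(hi$sample_id, hi$key) %in%
                      paste(lo$sample_id, lo$key)))
  }
})
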