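# varconcord

Cross-platform validation of expressed variants and gene fusions from
RNA-sequencing of small clinical specimens (the motivating setting is
thyroid fine-needle aspirates). The package is for assay developers and
analysts who must show that variant and fusion calls from whole-
transcriptome RNA-seq agree with orthogonal platforms (targeted DNA and
RNA panels, qPCR), characterize why they sometimes do not, and anchor the
calls to clinical truth.

## What it computes

**Agreement between platforms.** Each alteration event (sample ×
canonical key) in a shared sample scope is classified as detected by both
platforms, the reference only, or the test only. With counts
*b* = both, *r* = reference-only, *t* = test-only and (given an assayable
target panel) *z* = double negatives:

- positive percent agreement `PPA = b / (b + r)`
- confirmation rate `= b / (b + t)`
- negative percent agreement `NPA = z / (z + t)`

all with two-sided exact binomial (Clopper–Pearson) confidence
intervals, `[qbeta(α/2, x, n−x+1), qbeta(1−α/2, x+1, n−x)]`. Variant
identity is harmonized as `GENE:p.Change` (protein-level, case-canonical);
fusion identity is the ordered 5′/3′ partner pair with the two colloquial
report names (`RET/PTC1`, `RET/PTC3`) handled. Discordant events can be
adjudicated against a third arbiter platform.

**Allelic expression imbalance.** For DNA-positive variants with paired
RNA measurements, the DNA:RNA VAF ratio `dna_vaf / max(rna_vaf, 0.005)`
and the strong-imbalance classification (DNA VAF > 10% and RNA VAF < 5%,
both strict) quantify preferential wild-type-allele expression, after
excluding variants with low RNA coverage.

**Reproducibility.** Between-lab accuracy (expected positives detected in
both labs) and intra-/inter-plate pair-agreement concordance over
replicate designs, with closed-form expectations ((1−m)² and m²+(1−m)²
under per-call miss probability m) verified by simulation.

**Clinical performance.** Sensitivity / specificity / PPV / NPV /
prevalence of "≥ 1 reported variant or fusion" against benign/malignant
histopathology, overall and stratified by classifier call or Bethesda
category, plus chi-square tests of independence and co-occurrence
summaries for DNA-only companion loci (TERT promoter C228T with RAS/BRAF
partners).

**Synthetic cohorts.** A fully seeded generator
(`cohort_config()` → `generate_cohort()` → `simulate_variant_calls()` /
`simulate_fusion_calls()` / `simulate_replicates()`) produces ground-truth
cohorts and platform call sets with realistic read-depth (beta-binomial)
and allele-expression structure, so the entire pipeline is testable
without proprietary specimen data. Published summary tables ship as
code-built fixtures (`table2_counts()`, `table3_nodules()`,
`table4_tert()`, also under `inst/extdata/`).

## Worked example

```r
library(varconcord)

# Platform agreement from published-style event counts:
# 134 events on both platforms, 47 reference-only, 2 test-only
counts <- concordance_counts(n_both = 134, n_ref_only = 47, n_test_only = 2)
ppa(counts)
#> PPA: 74% [67-80.3] (134/181, 95% CI)
confirmation(counts)
#> Confirmation: 98.5% [94.8-99.8] (134/136, 95% CI)
```

74% of reference-positive events were also called by the test platform;
conversely 98.5% of the test platform's calls were corroborated.

```r
# Clinical performance on the packaged 190-nodule fixture
nodules <- table3_nodules()
meta <- nodules[c("sample_id", "bethesda", "gsc_call", "histology",
                  "histology_class")]
pos <- sample_positivity(meta$sample_id, table3_callset(nodules), meta)
performance_metrics(build_confusion(meta, pos))
#> Sensitivity: 49% [34-64] (22/45, 95% CI)
#> Specificity: 75% [67-82] (109/145, 95% CI)
#> PPV: 38% [26-52] (22/58, 95% CI)
#> NPV: 83% [75-89] (109/132, 95% CI)
#> Prevalence: 24% [18-30] (45/190, 95% CI)
```

So in this 190-nodule cohort (24% cancer prevalence), about half of the
malignant nodules carry a detectable alteration — informative when
positive, but not a standalone rule-out test (NPV 83%).

```r
# Allelic imbalance summary for six strongly imbalanced variants
imbalance_summary(records)   # records: paired DNA/RNA VAFs, see ?pair_dna_rna
#> Allelic expression imbalance: 6 of 6 DNA-positive variants (0 excluded
#> for low RNA coverage)
#>   DNA:RNA VAF ratio 5.7 to 38.1 (3 with ratio > 10)
```

`run_validation()` chains everything (simulation → concordance →
imbalance → reproducibility → clinical performance → co-occurrence) into
one seed-stable report bundle; `inst/scripts/varconcord.R` exposes the
stages as shell subcommands. See the vignette
(`vignettes/validation-methods.Rmd`) for the model, parameter rationale
and limitations.

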