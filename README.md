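# mirlifespan

Lifespan analysis of blood microRNA qPCR-array profiles: from raw
threshold-cycle (Ct) tables to a five-class age taxonomy, post-adulthood
aging diminution, and chromosomal hot spots.

## What it does

TaqMan Low Density Arrays report each miRNA as a Ct value, with
"Undetermined" wells censored at the detection limit (40 cycles). Given a
samples x miRNAs Ct table and sample metadata (preterm infants, children,
adults), the package:

1. **Normalizes** against an endogenous control (RNU48):
   ΔCt = Ct(miRNA) − Ct(control), relative expression 2^−ΔCt, with
   censoring propagated (`delta_ct()`, `expression_value()`).
2. **Filters by detectability**: a miRNA is analyzed when it amplified in
   ≥ 30% of the samples of at least one comparison group
   (`detection_profile()`).
3. **Classifies** every panel miRNA into five classes — nonexpressed,
   age-constant, preterm-only, adult-only, down-regulated in adults,
   up-regulated in adults — via a two-sided Wilcoxon rank-sum test at a
   Bonferroni per-test threshold of α / (number of detectable miRNAs),
   with censored values imputed at the per-sample detection limit
   (`assign_expression_classes()`).
4. **Scans for aging diminution** among adult-detectable miRNAs: young
   (≤ 35 y) vs middle-aged (> 35 y) rank-sum tests under
   Benjamini–Hochberg FDR control at the 20% level, followed by Pearson
   and gender-adjusted partial correlations with age
   (`aging_analysis()`, `age_correlation()`).
5. **Detects cytoband hot spots**: bands carrying more than five distinct
   miRNAs of one class, with hypergeometric enrichment
   (`load_annotation()`, `chromosome_class_table()`, `find_hotspots()`).
6. **Calls lifespan transition patterns** over the four strata
   preterm → child → young adult → middle-aged adult
   (`call_transition_pattern()`).
7. Provides **contingency/score utilities** — Fisher exact, 2x2
   chi-squared, and the network score −log10(p) (`fisher_exact()`,
   `chi_square_2x2()`, `network_score()`).

A synthetic TLDA-style generator (`generate_dataset()`,
`generate_annotation()`, `generate_clinical_flags()`) emits study-like
data with planted ground truth, so the whole pipeline is testable end to
end without external data.

## Worked example

```r
library(mirlifespan)

report <- run_pipeline(list(simulate = TRUE, seed = 7), out_dir = "out")
print(report)
```

```
mirlifespan run report
  panel: 365 miRNAs, 228 detectable, per-test alpha 0.000219
         class   n pct_panel pct_differential
    adult_only  22     6.027           17.742
  age_constant 104    28.493               NA
 down_in_adult  20     5.479           16.129
  nonexpressed 137    37.534               NA
  preterm_only   1     0.274            0.806
   up_in_adult  81    22.192           65.323
  aging: 0 BH discoveries (crude-p cutoff 0, universe 227)
  hot spots: 2
```

Reading the output: of the 365-assay panel, 228 miRNAs passed the 30%
detectability rule in at least one group, so the Bonferroni per-test
threshold is 0.05/228 ≈ 0.000219. The classifier recovered the planted
structure exactly — 137 nonexpressed, 104 age-constant, and 124
differential miRNAs of which 81 (65.3% of the differential set) are
up-regulated in adults. The two planted cytoband clusters (a 16-member
age-constant cluster on 14q32.31 and a 6-member up-regulated cluster on
9q22.32) are the only flagged hot spots:

```r
report$hotspots[, c("cytoband", "class", "n_members", "band_total",
                    "prop_band", "prop_genome", "p_enrich")]
```

```
  cytoband        class n_members band_total prop_band prop_genome     p_enrich
1 14q32.31 age_constant        16         16         1   0.4561404 1.784326e-06
2  9q22.32  up_in_adult         6          6         1   0.3552632 1.777446e-03
```

File-based runs take the same configuration with paths instead of
`simulate`:

```r
run_pipeline(list(ct_table = "ct.tsv", sample_meta = "meta.tsv",
                  annotation = "mirna.gff3", cytoband_map = "cytoBand.txt"),
             out_dir = "out")
```

writing `classes.tsv`, `aging.tsv`, `hotspots.tsv`, `patterns.tsv`, and a
`summary.json` that echoes every threshold actually applied. A thin CLI
wrapper lives at `inst/scripts/mirlifespan.R`:

```sh
Rscript inst/scripts/mirlifespan.R --simulate --seed 7 --out out/
Rscript inst/scripts/mirlifespan.R --config run.yaml --out out/
```

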