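---
title: "Methods: lifespan classification of blood miRNA qPCR profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan classification of blood miRNA qPCR profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlifespan)
```

## The problem

TaqMan Low Density Arrays (TLDA) measure a few hundred miRNAs per sample as
threshold-cycle (Ct) values. In a lifespan design -- preterm infants,
children, young adults, middle-aged adults -- three questions arise:

1. Which miRNAs are expressed at all, and in which age groups?
2. Which are differentially expressed between infancy and adulthood, and in
   which direction?
3. Which adult-expressed miRNAs decline after young adulthood
   ("aging-diminished" expression)?

`mirlifespan` implements this analysis as a reusable pipeline with a
synthetic data generator carrying planted ground truth, so every stage is
testable without access to the original cohort.

## Quantification model

Expression is quantified relative to an endogenous control (RNU48 on the
TLDA human panel):

$$\Delta C_t = C_t(\text{miRNA}) - C_t(\text{control}), \qquad
  \text{relative expression} = 2^{-\Delta C_t}.$$

A well that never crosses threshold within `ct_max` cycles (default 40) is
*censored*, not zero and not missing: the abundance is below the detection
limit. Censoring propagates through normalization. The control must amplify
in every sample; otherwise normalization is impossible and the pipeline
stops naming the offending samples.

The control's $\Delta C_t$ with itself (identically 0) is excluded from the
output rather than reported, so class counts downstream refer only to
target assays.

### Censoring policy

The instrument reports only "Undetermined" for a censored well; how such
wells enter a rank test is a genuine design choice. The default policy
imputes a censored $\Delta C_t$ at the per-sample detection limit,
$ct_{max} - C_t(\text{control})$: the value known to bound the true one
from below (in expression terms). This is the standard censored-qPCR
convention; it preserves sample size and ranks censored wells below every
detected well of the same sample, with midranks breaking ties. A `"drop"`
policy (discard censored values) is available; it loses power and can make
one-group-heavy miRNAs untestable, in which case those miRNAs are kept
under an explicit `untestable` label rather than silently removed.

Whether "detectable" should mean the instrument call or a cycle cutoff is
not observable from a Ct table alone; the reader supports both (token
mapping plus coercion of any finite value above `ct_max`), asserting
neither as canonical.

## Five-class taxonomy

`detection_profile()` computes, per miRNA and comparison group, the
fraction of samples in which the assay amplified. A miRNA is *detectable*
in a group when that fraction reaches `min_frac` (default 0.30, boundary
inclusive: 3 detections in 10 samples qualify). The *panel-detectable set*
is everything detectable in at least one of the two groups.

`assign_expression_classes()` then applies a decision tree:

| condition | class |
|---|---|
| detectable in neither group | `nonexpressed` |
| detectable in group A only | `<A>_only` |
| detectable in group B only | `<B>_only` |
| both; rank-sum not significant | `age_constant` |
| both; significant, higher in B | `up_in_<B>` |
| both; significant, lower in B | `down_in_<B>` |

The two-group test is a two-sided Wilcoxon rank-sum test with a Bonferroni
per-test threshold of `alpha_family / n_detectable`; the denominator is the
size of the panel-detectable set, computed from the data rather than
hard-coded, so a 228-miRNA detectable set at family level 0.05 yields the
per-test threshold 0.05/228 = 0.00022. The threshold actually applied is
echoed in every output so it can be audited.

"Expressed in one group only" is operationalized as detectable in exactly
one group; the other group may still show sporadic sub-threshold
detections. This matches how an exclusively-infant miRNA can amplify in a
handful of adults without counting as adult-expressed.

### Rank-sum test

The test statistic is the rank sum over pooled midranks. Because censored
values imputed at a shared limit produce heavy ties, and the classical
exact tables assume no ties, the package computes the exact permutation
distribution itself (dynamic programming over doubled midranks) whenever
the combined sample size is at most 12, and otherwise uses the normal
approximation with tie correction and continuity correction. The exact
two-sided p-value is defined symmetrically,
$P(|W - E[W]| \ge |w_{obs} - E[W]|)$, which is well defined under
arbitrary ties; the unit tests verify it against exhaustive enumeration of
all label assignments, and against `wilcox.test` on tie-free data.

### Fold change

The signed fold change between two group means is
$r = 2^{-\overline{\Delta C_t}(A)} / 2^{-\overline{\Delta C_t}(B)}$,
reported as $r$ when $r \ge 1$ and $-1/r$ otherwise, so its magnitude is
at least 1 and its sign names the higher group. Group summaries are
arithmetic means of $\Delta C_t$, i.e. geometric means of expression. Two
call conventions follow from this:

* classification reports `signed_fold_change(mean_B, mean_A)` -- positive
  means up-regulated in adults;
* the aging table reports `signed_fold_change(mean_middle, mean_young)` --
  negative means expression declining with age.

The aging sign convention deserves a note: written literally, the ratio
"young over middle-aged" would be *positive* for declining miRNAs, but the
field's reporting convention attaches a negative sign to age-declining
fold changes (e.g. $-1.6$ for a 1.6-fold decline). The package follows the
sign convention, implemented by passing the later life stage first.

## Post-adulthood aging analysis

Adults are split at 35 years (young $\le 35$ < middle-aged), the age at
which human physical performance conventionally peaks. Among the miRNAs
detectable in adults, young vs middle-aged differences are rank-sum tested
and controlled by Benjamini-Hochberg step-up at `q = 0.20`.

The BH *universe* defaults to the adult-detectable set rather than the
whole panel: miRNAs that never amplify in adults cannot contribute
hypotheses about adult aging, and with ~205-230 adult-detectable miRNAs
the realized crude-p cutoff for six discoveries at the 20% level lands
near $0.2 \times 6 / 205 \approx 0.006$, the regime such screens report.
The realized cutoff `q * k / universe_size` is attached to every result so
any universe choice is auditable, and `universe = "panel"` is available.

Discovered miRNAs are followed up with Pearson correlation between
expression and age, plus a gender-adjusted partial correlation
(residualize both variables on gender; the partial test uses $n - 3$
degrees of freedom), at per-test level $0.05 / k$ for $k$ discoveries
($k = 6$ gives 0.0083). Correlations use $-\Delta C_t$, the log2
expression scale, where Pearson correlation is appropriate; correlating
$2^{-\Delta C_t}$ directly would let a single high expresser dominate.
Spearman is offered as an option since the underlying scale choice is a
convention, not a fact of the data.

For validation-style three-group comparisons (preterm / child / adult),
`three_group_compare()` runs a one-way ANOVA with pairwise comparisons
Bonferroni-adjusted across the three contrasts.

### Transition patterns

With children available, each miRNA's trajectory over the four strata
(preterm, child, young adult, middle-aged adult) is matched against four
templates: adult-onset expression (nondetectable before adulthood,
detectable in both adult strata), and three detectable-throughout shapes
given by the signs of three successive rank-sum contrasts, each at
$\alpha/3$: (flat, down, down), (flat, up, down), (down, up, down). The
contrasts use rank tests rather than ANOVA post-hocs because strata are
small and censoring-imputed values are heavily tied. Anything else --
including trajectories where a contrast cannot be evaluated -- is
`unclassified`; the caller never forces a template.

## Genomic hot spots

Chromosomal placements come from miRBase-style GFF3
(`miRNA_primary_transcript` records preferred, 1-based inclusive
coordinates) or a flat table; cytobands from an explicit column or by
maximal-overlap interval lookup in a UCSC `cytoBand.txt` map (0-based
half-open, converted internally). A miRNA may map to several loci and
contributes its class once to *every* band it maps to, so total placements
can exceed the panel size.

A *hot spot* is a cytoband carrying strictly more than `cluster_threshold`
(default 5) distinct miRNAs of the same class -- i.e. clusters of six or
more. The cytogenetic band is the clustering unit because that is the
resolution at which such clusters are reported and interpreted (imprinted
domains, polycistronic clusters); a sliding genomic-window alternative is
out of scope. Each hot spot reports the within-band class proportion
against the panel-wide proportion, plus a right-tail hypergeometric
enrichment p-value -- a formal complement to the descriptive proportion
comparison, verified in tests against direct tail enumeration.

Per-band counting uses distinct miRNAs (a miRNA placed twice inside one
band counts once there); panel-wide proportions use the detectable panel,
not placements, so multi-locus miRNAs do not inflate the reference
denominator.

## Contingency utilities and the network score

`fisher_exact()` and `chi_square_2x2()` wrap the standard exact
hypergeometric and Pearson chi-squared tests with explicit degenerate-table
handling. `detection_association()` cross-tabulates a miRNA's detection
state against a binary clinical outcome and reports *both* tests side by
side: at small counts they can disagree noticeably (for a 20-vs-10 split
with 10% vs 50% outcome rates, the uncorrected chi-squared gives p = 0.015
while the exact test gives ~0.026), and published association p-values do
not always name their test. The default is the uncorrected chi-squared.

`network_score()` is $-\log_{10}(p)$ of an enrichment p-value (so
$10^{-24} \mapsto 24$); base 10 is forced by that worked example. Only the
score transform is implemented -- network construction against a
proprietary knowledge base is not reproduced.

## The synthetic data generator

`generate_dataset()` emulates the study-like structure: a 365-assay panel
plus RNU48 control; 30 preterm / 66 children / 32 young / 28 middle-aged
adults; class fractions 137 : 104 : 1 : 22 : 20 : 81 (nonexpressed,
age-constant, preterm-only, adult-only, down-, up-regulated in adults).
Per sample, control Ct is drawn $N(24, 0.5^2)$; per target,
$C_t = C_t(\text{control}) + \mu_{\text{stratum}} + N(0, \sigma^2)$ with
$\sigma = 1$ cycle, censored at $C_t \ge 40$.

Key planting choices:

* Expressed baselines are uniform on 2-10 $\Delta C_t$ cycles, keeping
  expressed assays comfortably inside the detection range.
* The planted between-group effect is 1.5 cycles, chosen so that typical
  observed fold-change magnitudes fall in the 1.4-2.4x range such screens
  print.
* Nondetectable states sit at $\Delta C_t = 19$ (mean Ct ~3 cycles past
  the limit), giving sporadic per-cell detection of a few percent --
  detection failure is expression-dependent, not an independent coin flip.
  An optional extra logistic-style dropout is available.
* The preterm-only miRNA sits at the detection margin, so about two thirds
  of preterm samples detect it (floored half a cycle inside the limit so
  the noiseless limit stays detectable) -- one-group-only expression with
  partial detection, the hardest case for the detectability rule.
* A fraction (default 0.03) of adult-detectable miRNAs get an
  aging-diminution slope of +0.03 $\Delta C_t$ cycles/year centered at the
  35-year cutoff, i.e. roughly a 1.5-fold expression decline across the
  young-to-middle-aged span. Note this couples the aging plant to the
  infant-adult classes, as in real data, and can occasionally pull a
  planted up-regulated miRNA just below the Bonferroni bar.
* Children default to their infancy means (or nondetectable states), and
  per-stratum means are planted independently enough that all four
  transition templates are expressible.

`generate_annotation()` places requested same-class clusters on named
cytobands and scatters all remaining miRNAs round-robin per class across a
fixed pool of 44 plausible band names, which guarantees no accidental
same-class cluster above five members; extra placements emulate
multi-locus miRNAs (401 placements for 365 panel miRNAs under defaults).
Synthetic coordinates live on 2-Mb band windows and round-trip through the
GFF3 and cytoband writers. `generate_clinical_flags()` plants a
detection-state-dependent binary outcome.

Everything is deterministic under the config seed.

### What the simulator does not emulate

Amplification chemistry, plate and batch effects, inter-miRNA correlation,
heavy-tailed noise, and disease-subgroup structure are all absent; noise
is independent Gaussian on the cycle scale. Passing recovery tests on this
generator therefore demonstrates that the *pipeline logic* is correct
under the declared model -- not that the thresholds are optimal for any
particular real cohort.

## Numerical and testing choices

* Exact rank-sum switchover at combined $n \le 12$ by default
  (`exact = TRUE` forces the DP exact path, used in tests up to ~13,000
  arrangements); ties always via midranks; p-values from the symmetric
  deviation definition above.
* BH via the standard step-up (`p.adjust`) with an explicit universe size;
  flags verified against a literal step-up implementation for all short
  p-vectors.
* Detectability boundaries are inclusive (0.30 exactly qualifies); the
  hot-spot rule is strictly exclusive (exactly 5 never flags).
* Ct tables are written with 17 significant digits so write/read
  round-trips are bit-exact, censored cells included.
* Degenerate inputs: zero-variance correlation, all-censored groups under
  `"drop"`, zero-margin 2x2 tables, and empty annotations all produce
  explicit errors, flags, or empty results -- never silent coercion.
* Test problem sizes: recovery suites run the default 365-miRNA panel
  with 96 infant/adult samples (about 230 rank tests per run); oracle
  suites enumerate up to `choose(16, 8)` arrangements, p-vectors up to
  length 10, and 2x2 margins up to 30. The full suite completes in about
  a minute on one CPU.

## Known limitations

* The rank-sum normal approximation is used for all production-size
  groups; at the extreme Bonferroni thresholds involved, its tail accuracy
  (with continuity and tie correction) is adequate for classification but
  p-values in the far tail should not be over-interpreted.
* Limit-imputation makes the rank test conservative when censoring is
  heavy in both groups (mass ties at the limit).
* The aging correlation follow-up conditions on BH discovery, so its
  per-test level is interpretable only jointly with the selection step.
* Hot-spot detection inherits the annotation's band assignments; bands of
  very different gene densities are compared on counts, and the
  hypergeometric test treats the band as a simple random draw from the
  panel, ignoring genomic clustering of miRNA families.
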