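---
title: "Methods: expression-bias screening of miRNA target sets and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-bias screening of miRNA target sets and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirbias)
```

# The problem

In diseases with a tissue lesion and a plausible post-transcriptional
component — here, ovarian endometrioma (OMA), the ovarian cyst form of
endometriosis — one wants to know which microRNAs could be driving the
lesion's transcriptome away from that of the matched eutopic endometrium.
Direct miRNA profiling studies of endometriosis disagree with each other, so
`mirbias` implements the reverse, annotation-driven route: start from a
target atlas (every known miRNA with the set of genes it regulates), start
from a lesion-vs-eutopic expression table, and ask for each miRNA whether
its *target set* is biased toward deregulation. miRNAs whose targets are
collectively shifted — typically toward downregulation, since miRNAs repress
their targets — are candidate regulators and, if they circulate, candidate
plasma biomarkers. The package carries the full downstream path as well:
relative qPCR quantification, ROC evaluation of plasma marker panels,
factorial ANOVA of cycle-phase effects, clinical correlation and
cohort-table statistics, and the factorial analysis of miRNA-mimic
transfection experiments.

# The screen

## Model

Each gene with induction ratio $r$ (lesion / eutopic expression) is placed in
one of three categories:

* downregulated: $r < 0.5$
* unchanged: $0.5 \le r \le 2.0$
* upregulated: $r > 2.0$

The boundary values belong to the *unchanged* category: the outer categories
are defined by strict inequalities, and the unchanged band is read as the
closed interval between them. For a miRNA $m$ with target set $T_m$, the
screen forms the $2 \times 3$ table of category counts over
$T_m \cap G$ (where $G$ is the categorized transcriptome) versus the
background $G \setminus T_m$, and tests independence with the Pearson
statistic

$$X^2 = \sum_{ij} \frac{(O_{ij} - E_{ij})^2}{E_{ij}}, \qquad
E_{ij} = \frac{n_{i\cdot} n_{\cdot j}}{n},$$

on $(r-1)(c-1)$ degrees of freedom, without continuity correction. The raw
p-values are Bonferroni-corrected with $m$ equal to the number of miRNAs
actually testable in the given atlas-expression cross (not the atlas size:
the atlas is always wider than any one transcriptome, and only the tested
family is a defensible multiplicity). Results are ranked by raw p, ties
broken by larger tested-target count and then lexicographic id, so rankings
are reproducible.

## Design choices

* **Background.** The source analysis describes the comparator both as a
  random gene set and as the whole genome. The default here is the
  deterministic whole-genome complement — reproducible and strictly more
  data — with `background = "random", background_n = N` available for the
  random-subset reading.
* **Continuity correction.** None; the uncorrected Pearson p is the one
  consistent with the worked cohort example (the reconstructed
  hormonal-treatment 2x2 gives p = 0.0021 uncorrected, 0.0048 with Yates,
  and 0.002 is the printed value).
* **Small expected counts.** Tables with any expected count below 5 are
  flagged (`low_expected`); `chi2_contingency()` then offers a seeded
  Monte-Carlo p conditional on the margins, and — for two-row tables — an
  exact conditional p by full enumeration of the fixed-margin tables with
  multivariate-hypergeometric weights. The exact p is the deterministic
  limit of the label-shuffling permutation test. A practical note: even when
  all expected counts exceed 5, the *asymptotic* p differs from the
  conditional/permutation p by up to a few hundredths at n of a few hundred;
  this is the ordinary chi-square asymptotics gap, shared by every textbook
  implementation. Agreement with a permutation oracle at Monte-Carlo
  precision is therefore a property of the conditional modes, and that is
  what the test suite checks at that precision.
* **Degenerate categories.** A category with zero genes in both rows carries
  no information; such columns are dropped before testing and the degrees of
  freedom shrink accordingly. A miRNA with no targets in the expression
  table is untestable and skipped with a logged count.
* **Aggregation.** `aggregate_genes()` surfaces genes targeted by at least
  `k` distinct hit miRNAs (convergent targeting), and `mirnas_targeting()`
  answers the reverse question in rank order — the step that, in the
  motivating study, singled out an estrogen-regulated gene with induction
  ratio 0.0084 targeted by three of the screen's hits.
* **Literature flags.** The "previously reported" annotation is a
  user-supplied table joined by miRNA id; it is curation, never computation.

# Relative quantification (2^-ddCt)

`delta_ct()` computes $\Delta Ct = Ct_{target} - \overline{Ct}_{references}$
per sample; multiple reference assays are combined by the arithmetic mean of
their Cts, i.e. the geometric mean on the expression scale — the standard
convention when the combination rule is unstated. `fold_change()` then
reports $\Delta\Delta Ct = \overline{\Delta Ct}_{case} -
\overline{\Delta Ct}_{control}$ and the fold $2^{-\Delta\Delta Ct}$, with a
two-sample t-test on the $\Delta Ct$ (log2) scale, where residuals are much
closer to Gaussian than on the linear scale. `paired_tissue_contrast()`
handles the lesion-vs-eutopic design where both tissues come from the same
patient: a paired t-test on within-patient differences.

Missingness conventions: undetectable wells are `NA`, not errors; a sample
missing any reference Ct is dropped with a logged count; analyses are
complete-case per assay. Zero-variance edge cases are reported rather than
hidden: identical groups give fold 1 with p = 1, while a constant nonzero
shift with zero noise gives the fold and a `degenerate` flag with p
undefined, since no test statistic exists.

# ROC panel evaluation

A panel score is the sign-oriented sum of $\Delta Ct$ over the panel assays.
Because Ct falls as expression rises and the markers of interest are
overexpressed in cases, the default orientation negates the sum so that
larger scores are more case-like (`direction` overrides). `roc_eval()`
builds the empirical curve over all observed thresholds; ties are traversed
diagonally, so the trapezoid AUC equals the normalized Mann-Whitney
statistic with ties counted one half — an identity the suite verifies
exactly on tie-rich fixtures. The 95% CI uses the DeLong placement-value
variance (the default of the easyROC family of tools); the cutoff maximizes
Youden's $J = sens + spec - 1$; predictive values are computed at the
observed case-control prevalence, and LR+ / LR- accompany them. All curve
coordinates are returned so any other cutoff convention can be audited.
Degenerate inputs (all scores identical) yield AUC 0.5 with a flagged,
unavailable CI.

# Clinical and transfection statistics

* **Disease x cycle-phase ANOVA.** Balanced complete designs use the
  classical decomposition (the suite checks a hand-computed 2x2 table and SS
  additivity to 1e-9 relative); unbalanced designs use Type II sums of
  squares, the conventional default when no effect hierarchy is
  pre-specified. The response scale is $\Delta Ct$ (log2 expression) —
  variance-stabilizing, and recorded in the result's attributes because the
  interaction test is scale-dependent.
* **SNK.** The Student-Newman-Keuls procedure is implemented on ordered
  means with studentized-range tests at each stretch size; the reported
  adjusted p of a pair is the maximum range-test p over all stretches
  containing the pair, which encodes the stepwise accept/reject logic in a
  single monotone column and reduces exactly to the pooled t-test for two
  groups. Because SNK's stepwise nature weakens familywise control for some
  configurations, Tukey HSD is available as a conservative cross-check.
* **Spearman.** The correlation of midranks (identical to rank-Pearson,
  which is the tested invariant), with a t-approximate p and an exact
  permutation p over all $n!$ orderings for $n \le 9$.
* **Cohort tables.** Quantitative features: Welch t. Qualitative features:
  the package's own Pearson chi-square (no correction), switching to
  Fisher's exact test when any expected count is below 5; missing values are
  excluded per feature and counted.
* **Kruskal-Wallis / Dunn.** Tie-corrected KW; Dunn's z-tests on mean ranks
  with Bonferroni adjustment run only when the multigroup test is
  significant at 0.05 — the gate is explicit in the source protocol.
* **Dunnett.** Many-to-one comparisons against a shared control with the
  adjusted p $P(\max_j |T_j| \ge |t_i|)$ estimated by seeded Monte Carlo of
  the correlated t-statistics (shared control mean, shared variance
  estimate; default $10^5$ draws). This converges to the multivariate-t
  Dunnett probability, agrees with `multcomp` to ~0.01, and reduces to the
  two-sample t-test for a single arm.
* **Transfection analysis.** Expression is normalized to the scrambled arm
  within each patient x cell-type x dose block and analyzed on the log2
  scale, where multiplicative effects are additive and the control sits at
  0. Stage 1 is the additive factorial model
  `log2(rel_expr) ~ patient + cell_type + dose + arm`; the source analysis
  names three factors but reports a mimic-arm p from the same model, so the
  arm term is included and every term plus the overall model F is reported.
  Stage 2 runs a per-dose one-way ANOVA across arms and, only where it is
  significant at 0.05, Dunnett comparisons of each mimic arm against
  scrambled. Note that dividing by the scrambled well makes the mimic arms
  share its noise; an oracle simulation of this procedure under the complete
  null (2,000 replicates) puts the per-dose rejection rate near 0.016 at
  nominal 0.05, i.e. the stage is conservative, and the null-calibration
  test asserts exactly that one-sided behavior.

# The synthetic-data generator

The generator exists so that every stage is testable with known truth and no
external downloads; its defaults are the study conditions.

* `simulate_screen_inputs()` draws gene categories from background
  proportions (default 0.2 / 0.7 / 0.1 down / unchanged / up), induction
  ratios log-uniformly within the category intervals (down (0.01, 0.5),
  unchanged [0.5, 2], up (2, 100) — the upper bound is arbitrary and
  overridable), and target sets by weighted sampling without replacement,
  down-category genes weighted by the planted odds ratio. Unplanted sets are
  uniform draws, i.e. exactly null.
* `simulate_ct_study()` writes Ct values as baseline + group + phase +
  interaction effects plus Gaussian technical noise on the Ct scale
  (log-multiplicative on expression — the standard qPCR error model);
  reference assays receive noise but no effects; phases are balanced 50/50
  within each group, as in the motivating cohort. The default target panel
  plants overexpression of roughly 30-fold and 4-fold in cases — the folds
  reported for the two circulating markers — as Ct shifts of -log2(30) and
  -2 cycles; these are illustrative planted values, not calibrated effect
  sizes, since the source reports folds without dispersions.
* `simulate_transfection()` emulates the fully crossed mimic experiment
  (default 10 patients x 2 cell types x 4 arms x 3 estradiol doses) with
  multiplicative patient, arm and dose effects and lognormal noise
  (default CV 0.2), and emits both raw and scrambled-normalized values. The
  default planted effect in the pipeline configuration is a 40% reduction
  for the double-mimic arm at the high dose, mirroring the reported
  knockdown.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: overlap and correlation between the target sets
of related miRNAs, annotation biases of a real interaction atlas, heavy
tails and batch structure of plasma Ct values, informative missingness of
undetectable wells, and any real prevalence (predictive values are
case-control quantities here).

# Numerical conventions

Every stochastic function takes an explicit `seed` and is bitwise
reproducible under it; seeding is scoped (`withr`), so the caller's RNG
stream is untouched. The pipeline runner `run_all()` requires a seed in its
config, stamps every output table with a config hash + seed header, and
reproduces byte-identical tables on re-run. Ranking ties, boundary ratios,
degenerate-variance cases and dropped columns/samples all follow the fixed
conventions described above, and the readers reject malformed input with
line-numbered messages rather than guessing.

Problem sizes in the test suite are the package's analysis plan: 200 random
tables for the oracle-equivalence check, 200 all-null screens and 100
planted-recovery screens at 2,000 genes x 50 miRNAs, 100 replicates for the
fold-recovery check, 500 fixtures for the AUC identity, 500 replicates at
n = 93/95 for DeLong coverage, and 500 null replicates for Dunnett
familywise error. These sizes put Monte-Carlo error comfortably below the
asserted bounds while keeping the default run in the minutes range.

# Limitations

The screen inherits every bias of its inputs: a target atlas mixes predicted
and validated interactions without distinction (the input format carries no
interaction-class column because the source analysis did not use one), and
induction ratios come from a single transcriptomic comparison. The
Bonferroni family is the testable subset, which is the defensible choice but
not the only one. SNK is reported because it is the procedure used in the
motivating analyses, with Tukey available where familywise control matters.
The package performs no target prediction, no network/pathway analysis, no
amplification-efficiency correction and no alias resolution of gene symbols.
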