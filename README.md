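# mirbias

Expression-bias screening of miRNA target sets, with the downstream
quantification and biomarker statistics such a screen feeds.

## The problem

Ovarian endometrioma (OMA) — the cyst form of endometriosis — rewires the
transcriptome of ectopic endometrial tissue relative to the same patient's
eutopic endometrium. Direct miRNA profiling of the disease has produced
conflicting marker lists, so an alternative is to work backwards from
annotation: take a miRNA→target atlas and a lesion-vs-eutopic expression
table, and ask, per miRNA, whether its *target set* is collectively biased
toward deregulation. miRNAs under whose targets the transcriptome shifts are
candidate regulators; if they circulate, they are candidate plasma
biomarkers. `mirbias` is for analysts who want that screen, and everything
after it, as tested, seeded, reproducible R functions.

## The core computation

Genes are categorized by their induction ratio `r` (lesion/eutopic):
**down** if `r < 0.5`, **up** if `r > 2.0`, **unchanged** otherwise
(boundaries inclusive to unchanged). For each miRNA the 2×3 table of
category counts — targets vs the whole-genome complement — is tested with
the Pearson chi-square statistic

    X² = Σ (O − E)² / E,   E = (row total × column total) / n,

df = (r−1)(c−1), no continuity correction, followed by Bonferroni correction
with m = number of testable miRNAs, and ranking by raw p (ties: larger
target set, then id). Downstream modules implement 2^−ΔΔCt relative
quantification, empirical ROC evaluation (midrank AUC = Mann–Whitney
U/(n₁n₂), DeLong 95% CI, Youden cutoff, PPV/NPV at observed prevalence,
likelihood ratios), disease × cycle-phase factorial ANOVA with SNK post-hoc,
Spearman symptom correlations, cohort-table tests, Kruskal–Wallis + Dunn,
and Monte-Carlo Dunnett comparisons for miRNA-mimic transfection designs.
A synthetic-data module generates atlases, transcriptomes, Ct matrices and
transfection designs with planted effects, so every stage is testable with
known truth.

## Worked example

```r
library(mirbias)

# A 2,000-gene transcriptome, 50 miRNAs, three of them planted with a
# down-category enrichment odds ratio of 5 (target sets of 100 genes).
sim <- simulate_screen_inputs(
  n_genes = 2000, n_mirnas = 50, target_size_range = c(100, 100),
  planted = c(mir001 = 5, mir002 = 5, mir003 = 5), seed = 42)

screen <- run_screen(sim$atlas, sim$expression, alpha = 0.05, top_n = 5)
screen
#> miRNA expression-bias screen: 50 miRNAs tested, 3 significant at Bonferroni alpha = 0.05
#> # A tibble: 5 × 13
#>    rank mirna_id n_down n_unchanged  n_up n_targets statistic    df  p_value
#>   <int> <chr>     <int>       <int> <int>     <int>     <dbl> <int>    <dbl>
#> 1     1 mir003       54          43     3       100     81.3      2 2.20e-18
#> 2     2 mir001       54          42     4       100     80.7      2 2.96e-18
#> 3     3 mir002       45          46     9       100     44.2      2 2.56e-10
#> 4     4 mir047       32          61     7       100     11.1      2 3.95e- 3
#> 5     5 mir036       23          59    18       100      7.59     2 2.25e- 2
```

The three planted miRNAs are recovered as the only Bonferroni hits: ~54 of
100 targets downregulated against a 20% background. Genes under convergent
targeting, and the hit miRNAs targeting a given gene:

```r
agg <- aggregate_genes(sim$atlas, screen_hits(screen), sim$expression, k = 2)
head(agg, 3)
#> # A tibble: 3 × 3
#>   gene_id n_targeting_hits induction_ratio
#> 1 g01207                 3          0.0530
#> 2 g00099                 2          0.130
#> 3 g00272                 2          0.0468
mirnas_targeting(sim$atlas, screen_hits(screen), "g01207")
#> [1] "mir003" "mir001" "mir002"
```

A plasma qPCR study (93 cases / 95 controls, between-subject variability of
4 cycles, planted overexpression of ~30-fold and 4-fold in cases), from raw
Ct values to fold changes and a two-marker ROC panel:

```r
study <- simulate_ct_study(n_cases = 93, n_controls = 95, noise_sd = 4, seed = 42)
dct   <- delta_ct(study$ct, study$meta)
fold_change(dct)
#> # A tibble: 2 × 7
#>   assay_id   delta_delta_ct  fold  p_value n_case n_control degenerate
#> 1 let-7b-5p           -5.29 39.2  2.57e-10     93        95 FALSE
#> 2 miR-92a-3p          -2.88  7.35 6.09e- 4     93        95 FALSE

roc_eval(panel_score(dct, c("let-7b-5p", "miR-92a-3p")))
#> ROC report: AUC 0.733 (95% CI 0.662-0.805), n = 93 cases / 95 controls
#> Youden cutoff -17.6: sens 0.731, spec 0.674, PPV 0.687, NPV 0.719, LR+ 2.24, LR- 0.40
```

The fold changes recover the planted effects (39.2 vs 30, 7.35 vs 4 — at
4-cycle noise single-study folds are noisy; across replicates they center on
the truth), and the summed-ΔCt panel score reaches AUC 0.733. `roc_eval()`
results have `tidy()` (curve points), `glance()` (one-row metrics) and
`autoplot()` methods; `run_all(run_config(...))` drives the whole pipeline
from one seeded config and writes provenance-stamped TSVs plus a checksum
manifest.

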