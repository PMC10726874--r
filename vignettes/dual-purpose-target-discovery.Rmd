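---
title: "Methods: dual-purpose anti-aging / anti-cancer target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-purpose anti-aging / anti-cancer target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtarget)
```

## The problem

Aging is the dominant risk factor for most solid cancers, and many signaling
axes (nutrient sensing, senescence, DNA repair, proteostasis) are dysregulated
in both processes — often in opposite directions. `dualtarget` implements a
complete, testable analysis for asking which druggable cancer targets are also
credible geroprotective targets: genes whose expression drifts with age across
many healthy tissues, which rank highly as cancer targets across several
malignancies, which map onto the hallmarks of aging, and for which organismal
lifespan evidence (or its absence) can be organized into an actionable
classification.

The package is built so that every stage runs on synthetic data with planted
truth. Real cohort data (protected human tissue expression, dozens of
case-control cancer datasets, proprietary target rankings) are not required;
where the real analysis would consume them, the pipeline takes the same table
shapes as input.

## Age-association calling

For each gene in each tissue two tests are run:

1. **Sex-adjusted partial Pearson correlation** between age and expression,
   \deqn{r_{ae \cdot s} = \frac{r_{ae} - r_{as} r_{es}}
     {\sqrt{(1 - r_{as}^2)(1 - r_{es}^2)}},}
   with a two-sided p-value from the t-distribution. The degrees of freedom
   are `n - 2`, the convention adopted throughout this analysis style; the
   classical partial-correlation test controlling one covariate would use
   `n - 3`, a negligible difference at the cohort sizes involved (the package
   keeps `n - 2`).
2. **Old-versus-young moderated t**: a least-squares fit of expression on an
   old/young indicator (old = age at least 60, young = under 50; donors aged
   50-59 are excluded from this contrast) plus sex and an intercept, with
   limma's empirical-Bayes variance moderation. The printed form of such
   models often omits the intercept; one is always included here, because
   without it the age coefficient absorbs baseline expression and loses its
   log-fold-change interpretation. A continuous-age fit is available behind
   `age_mode = "continuous"`.

A gene is *age-associated* in a tissue when both tests give `p < 0.05` (raw
p-values by design; no multiplicity correction at this stage), and its
direction is the sign of the old/young coefficient. `tsg_enrichment_test()`
asks, via a 2x2 Pearson chi-square without continuity correction, whether
tumor-suppressor genes are over-represented among genes age-associated in at
least one tissue.

## Pathway dysregulation and consensus

Pathway activation is scored per comparison by a transparent surrogate in the
spirit of topology/coexpression-weighted scorers such as iPANDA, whose
internals are proprietary-adjacent and not re-derived here. Genes sharing a
coexpression-module label are collapsed to module means, then

```
score = scale * sum(w * s * logFC) / sum(w)
```

with topology weights `w` (default 1), significance gate `s` (1 if `p <
0.05`, else `s_relax = 0.1`) and `scale = 0.1` mapping typical magnitudes
onto the conventional +/-0.01 decision thresholds. The score's *scale* is a
free parameter of any such surrogate; the thresholds, consensus rule and
roll-up below are what the downstream analysis actually consumes, and they are
honored exactly.

Across the datasets of one cancer, a pathway is called only when at least 50%
of all datasets agree in direction past the +/-0.01 threshold; an exact 50/50
split is unidirectional for neither direction and yields no call. The
arithmetic mean is then taken over the majority-direction extracted scores and
must itself clear the threshold. (Because every extracted score already
exceeds the threshold, this mean check cannot fail under majority-only
averaging; it is retained for interface fidelity and would bind if the mean
were ever taken over all datasets.) Consensus calls roll up to the parent
processes (27 main cellular processes by default) as percentages of each
process's total pathway count, and matched tissue/cancer pairs are
cross-classified into the four aging-by-cancer direction categories, reported
against both the process total and the overlapped-pathway denominator, since
both conventions are in circulation.

## Meta-analysis and common-target prioritization

Within each cancer, per-dataset moderated-t results are combined per gene:

* **Combined logFC** — inverse-variance weighting by default. The alternative
  `"sd_product"` weighting (weights proportional to the standard deviations
  themselves) is retained because the originating convention is ambiguous;
  inverse-variance is the standard meta-analytic choice and is the default.
* **Stouffer's method** on the two-sided p-values with the signs of the
  per-dataset effects and weights equal to the square root of each dataset's
  sample size (the classical weighted choice when per-study weights are
  otherwise unspecified).
* **Benjamini-Hochberg FDR** across the genes of that cancer (the family is
  the within-cancer gene list; no cross-cancer family is defined).

Per-cancer ranked target lists (top 100 per cancer per novelty setting) are
pooled per setting and prioritized by descending occurrence, then ascending
average rank, then gene identifier for determinism; the top 100 per setting
(200 in total across the two settings) are the *common cancer targets*. The
two settings' lists may overlap; the pipeline reports them separately so any
overlap is visible.

## Hallmarks, filtering, classification

Hallmark-of-aging annotation is keyword matching: a gene is linked to a
hallmark when any of its GO term **names** contains (case-insensitive
substring) any keyword of that hallmark; the 12-key keyword map is
`aging_hallmark_keywords()`. Keywords match names, not term identifiers,
because keywords are words.

A common target survives the age filter when it is age-associated in strictly
more than 10% of the analyzed tissues (with 47 tissues: at least 5) *and*
carries at least one hallmark. Its proposed anti-cancer direction follows the
majority of significant expression changes across cancers (up-majority:
antagonism; down-majority: agonism), with an explicit override table for
mechanism-of-action exceptions (the classic case: a receptor upregulated in
tumors whose higher activity is nonetheless anti-tumorigenic, so agonism is
proposed). Ties or no significant cancer leave the direction unknown and
flagged.

Classification into the four lifespan-evidence groups:

| Group | Rule |
|---|---|
| 1 | extension evidence, aging and cancer directions concordant |
| 2 | extension evidence, directions discordant (or undetermined) |
| 3 | shortening evidence only |
| 4 | no evidence, or no effect |

Evidence ledgers may carry several rows per gene (different model organisms);
conflicting extension/shortening evidence resolves to extension with a
warning, mirroring how such genes are conventionally placed with the
extension groups while staying visible for review. The dual-purpose list is
Group 1 minus tumor suppressors — antagonizing a tumor suppressor could
promote tumorigenesis in healthy tissue — ordered by the number of
age-dysregulated tissues (alphabetical tie-break).

## Enrichment-based candidate prediction

The lifespan-extending query set is Groups 1 and 2 combined. Each group is
tested for GO biological-process enrichment by the upper-tail hypergeometric
test with BH control (`fdr < 0.05`); the universe is all genes carrying at
least one biological-process annotation in the supplied table (configurable —
the natural alternative, all protein-coding genes, changes only `N`).
Annotations are used flat, with no propagation up the GO graph: propagation
status of any real annotation source should be decided by the user and
applied before the table is passed in. Terms enriched in the extenders and in
Group 4 *but not* in Group 3 nominate the unexplored candidates: every
Group-4 gene annotated to at least one such term, ranked by its number of
supporting terms. The final curation step from this candidate pool to a short
list is judgment-based (mechanisms of action, disease associations) and out
of computational scope; the pipeline emits the full annotated pool.

## Lifespan assays

Per-animal death days from the biological repeats are pooled into single
Kaplan-Meier curves per arm (the unstratified analysis matches the pooled
design; a repeat-stratified logrank is available). The median is the smallest
observed day with survival at or below one half — the step-function
convention, with no interpolation. The headline effect measure is the percent
change of the treated median over the control median, reported to one
decimal: a 22-day versus 19-day assay is +15.8%. Censoring is supported even
though a well-run worm assay may have none. Uncertainty for the medians is
available as bootstrap percentile intervals, clearly labeled as such, since
no analytic convention for a median's standard error is assumed.

## The synthetic-data generator

`synth_config()` fixes the study conditions; all generation is driven by
named substreams of one integer seed, so every object is a byte-identical
pure function of (config, indices) regardless of call order, and planted
truth travels alongside the data without ever being read by analysis code.

* **Tissues** — donors with ages uniform on 20-79 years (populating both the
  under-50 and 60-plus strata by construction) and balanced sex; expression
  is baseline + linear age slope for the planted fifth of genes (0.35 units
  per decade, 60% downward, against unit Gaussian noise — about one noise SD
  per 30 years, the regime in which a 150-donor tissue should recover the
  planted genes), plus an additive per-gene sex effect, the additive form
  matching the downstream model.
* **Cancers** — case-control datasets of 40 + 40 with a planted DE gene set
  (10% of genes, mean |log2 FC| 1) shared across a cancer's datasets;
  pathway-level effects are planted by shifting member genes of selected
  pathways, in both the cancer and the aging comparisons.
* **Pathways** — 100 pathways of 20 genes under 27 processes, every process
  populated. Within-pathway coexpression structure is *not* modeled (the
  scorer accepts module labels, the generator leaves them empty by default).
* **Lifespan** — a Gompertz law with fixed shape 0.45/day, the steep
  late-life mortality typical of FUdR-treated wild-type nematodes at 18-20C;
  the rate is solved in closed form so the continuous median sits half a day
  below the target and once-daily scoring (ceiling to whole days) lands the
  discrete median on the target day. The default assay is 90 animals per arm
  in 3 repeats, control median 19 days, +15.8% planted extension.

What passing tests show — and do not show — about real data: the generator is
Gaussian on a log-like scale with linear age effects, no batch structure, no
library-size artifacts, no count overdispersion, and no real coexpression.
Recovery and calibration results on it validate the *logic and arithmetic* of
the pipeline, not its robustness to the messiness of real cohorts.

## Numerical and design notes

* Quantile normalization averages tied ranks (deterministic); upper-quartile
  normalization scales to the dataset-internal mean upper quartile of nonzero
  values, so rescaling one sample moves only the global reference.
  "Zero coverage" means exactly zero on the raw scale, and the zero filter
  runs before normalization (the order is configurable by composing the
  functions in the other order).
* The proteomics transform is a calibrated generalized-log (per-sample affine
  least-squares calibration to the row-mean reference, then `asinh` on the
  log2 scale), a transparent stand-in for full maximum-likelihood
  variance-stabilizing fits: it keeps the testable contract (monotonicity,
  constant-stability, log-like tails) with two parameters per sample.
* Problem sizes in the test suite (2,000-gene tissues, 150 donors, 3-4
  datasets per cancer, 200 lifespan simulations) are the package's chosen
  operating points for demonstrating recovery and calibration.
* Stouffer p-values of exactly 0 or 1 are clipped to machine bounds with a
  warning rather than propagating infinities.

## Known limitations

* **The dual criterion is not an alpha-squared test.** The correlation test
  and the old/young contrast are computed on the same expression values, so
  under the null their statistics are strongly positively correlated (about
  0.83 at the default design) and the joint false-call rate sits near 3% —
  well above the 0.25% that independence would give, though far below either
  single test's 5%. Each criterion alone is calibrated at its nominal level;
  the conservative bound for the pair is alpha, not alpha squared. The
  acceptance suite asserts the independence bound as stated and that
  expectation fails honestly.
* The pathway scorer is a surrogate: its score scale is conventional, and
  only sign/threshold behavior — not magnitudes — should be compared across
  scorers. With majority-only averaging the consensus mean-score check is
  mathematically redundant (see above).
* Keyword-based hallmark mapping inherits the usual failure modes of
  substring matching (over-matching short keywords, missing synonyms); it is
  meant to reproduce a curated keyword workflow, not to replace ontology
  reasoning.
* The `n - 2` partial-correlation degrees of freedom are kept for fidelity to
  the analysis style being reproduced (see above).

## A worked run

```{r run, eval = FALSE}
cfg <- synth_config(seed = 1)
report <- run_pipeline(cfg, outdir = "dualtarget_run")
report
```

The report records the configuration and seed, per-stage row counts, the
four group sizes, the dual-purpose and candidate gene lists and the lifespan
summary; every intermediate table is written as TSV under `outdir` together
with a JSON copy of the report.
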