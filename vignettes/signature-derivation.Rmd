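---
title: "Deriving drug-sensitivity gene signatures: methods and design notes"
author: "drugsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving drug-sensitivity gene signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugsig)
```

## The modelling problem

A cell-line panel provides, for each line, a log2 gene-expression profile
and a measured IC50 (Molar) of a compound. The goal is a *compact* gene
signature — a dozen genes rather than thousands — whose expression predicts
sensitivity on lines never used in training. Compactness matters: small
signatures are assayable on clinical samples, interpretable, and less prone
to overfitting a cohort of a few dozen lines.

All regression happens on the sensitivity scale
$y = -\log_{10}(\mathrm{IC50\ [M]})$, where higher values mean more
sensitive. One canonical internal scale avoids repeated conversions; only
the fold-accuracy metrics translate back to linear Molar ratios. Working in
log space also reflects how dose–response potencies are actually compared:
a prediction "within four fold" is $|\Delta y| \le \log_{10} 4$.

Blood-derived lines are excluded before training (default
`exclude_lineage = "blood"`): hematological lines tend to respond as a
systematically shifted subgroup, and a solid-tumor signature should not
spend capacity explaining a lineage offset. The exclusion removes samples
only; the gene dimension is untouched.

## The derivation funnel

`derive_signature()` chains five stages, each narrowing (or, for the
network stage, modestly expanding) the candidate set. Counts in and out of
every stage are logged, because the funnel narrative — thousands of genes
to a handful — is itself a result worth auditing.

**1. Correlation screen.** Pearson product-moment correlation of every gene
with $y$; the two-sided p-value uses the exact t transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. The threshold
$p \le 0.05$ is deliberately permissive and *inclusive* at the boundary;
this stage exists to discard the clearly uninformative bulk, not to control
error rates. Constant-expression genes have undefined $r$ and are dropped
with a log entry. p-values that underflow double precision are reported as
the smallest positive double rather than zero, so downstream ranking never
divides by or takes logs of zero.

**2. Biological filters (optional).** When a gene-set collection (GMT) is
supplied along with the drug's known target genes, candidates are kept if
they share at least one set with at least one target gene. When an
interaction network (SIF) is supplied, candidates are expanded by their
distance-1 neighbors, restricted to measured genes. The two filters are
applied *separately* and combined; whether upstream knowledge should be
combined permissively or strictly is genuinely open, so the default is the
union (a gene passing either filter survives) with
`combine_filters = "intersection"` available. The filters are skippable so
the pipeline runs when no curated annotation is available.

**3. RReliefF ranking.** Relief-family algorithms score features by how
well value differences track target differences among near neighbors.
Classical Relief is defined for classification only; with a continuous
IC50 target the regression variant (RReliefF) is required. Implementation
choices, fixed for reproducibility: every sample serves as a reference
instance (no subsampling, hence no randomness), $k = 10$ neighbors with
uniform weight $1/k$, Manhattan distance on min-max-scaled features, and
min-max normalized feature/target differences. The weight is
$$W[f] = \frac{N_{dC \wedge dA}[f]}{N_{dC}} -
        \frac{N_{dA}[f] - N_{dC \wedge dA}[f]}{m - N_{dC}},$$
the standard decomposition into "feature changes when the target changes"
versus "feature changes when it does not". The top 100 genes are handed to
the selection stage; 100 is large enough to retain weak correlates yet
small enough that shadow-feature selection stays well-posed at $n \approx 50$.

**4. Boruta confirmation.** Each iteration appends an independently
permuted copy of every remaining candidate, fits a random forest
(impurity importance, 300 trees), and scores a *hit* for every real
feature whose importance beats the best shadow. A two-sided binomial test
on hit counts (null $p = 0.5$), Bonferroni-corrected across candidates,
confirms or rejects features; rejected features leave the race. Features
still undecided after `max_iter = 50` iterations are *tentative* and —
conservatively — excluded from the signature. Bonferroni (rather than a
lighter correction) mirrors the original shadow-scheme behaviour and keeps
the all-noise false-confirmation rate far below $\alpha \cdot p$.

**5. Backward elimination.** The cohort is split once into internal-train
and holdout partitions (11 of 52 by default, scaled proportionally for
other cohort sizes, stratified by tumor type when labels exist). Genes
leave one at a time, worst Relief rank first. At each step the
gradient-boosted-tree regressor is tuned by repeated cross-validated RMSE
(5 repeats × 10 folds) on the internal-train partition over a small fixed
grid, refit, and scored on the holdout by the sum of two-fold and
four-fold accuracy. The returned signature maximizes that sum; ties go to
the smaller set (parsimony). A config switch (`criterion_on = "cv"`)
scores the criterion on cross-validation out-of-fold predictions instead,
for users uneasy about an 11-sample holdout; the holdout is the default
because it keeps the selection criterion strictly disjoint from the data
used for tuning.

The final model is refit on the *full* training cohort with the winning
step's hyperparameters — standard practice once model selection is done,
since discarding a fifth of a 52-sample cohort for the production model
wastes information. The elimination trace (an audit table of step, gene
set, CV RMSE, holdout accuracies) is retained on the object, and
re-evaluating the winning step at the recorded seed reproduces its row
exactly.

### The regressor

Both ensemble kinds sit behind one interface (`fit_regressor()`):
gradient-boosted trees for the regression stages, random forest inside
Boruta — the forest's built-in importance is what the shadow scheme needs,
while boosting fits small-$n$ regression better. The default tuning grid
is deliberately dominated by **depth-1 (stump) boosting** at learning
rates 0.3/0.1/0.05, with one depth-2 entry: stump boosting fits additive
functions, and expression–sensitivity relationships at $n \approx 50$ are
effectively additive — deeper trees mostly add variance. Boosting runs
single-threaded without row/column subsampling, so training is
deterministic given the data and seed.

Tree ensembles are piecewise-constant: they cannot extrapolate beyond the
training range of a gene and approximate steep continuous trends with
staircases. At $n \approx 50$ this puts a floor of roughly 0.3 log10 units
on the out-of-sample residual even for a perfectly selected signature —
worth remembering when interpreting fold-accuracy numbers near their
ceiling. A linear model would not have this floor, but linearity is an
assumption tree ensembles are specifically chosen to avoid.

## Tunables at a glance

| parameter | default | units / range | why |
|---|---|---|---|
| `alpha_corr` | 0.05 | p-value | permissive first cut, inclusive boundary |
| `top_n_relief` | 100 | genes | hand-off size to selection |
| `relief_k` | 10 | neighbors | standard RReliefF choice at $n \approx 50$ |
| `alpha_boruta` | 0.05 | p-value | binomial test level (Bonferroni across genes) |
| `boruta_max_iter` | 50 | iterations | undecided after this → tentative → excluded |
| `cv_repeats`, `cv_folds` | 5, 10 | — | repeated k-fold for hyperparameter RMSE |
| `holdout_size` | 11 of 52 | samples | single stratified split for the accuracy criterion |
| fold thresholds | 2, 4 | ratio | within-k is boundary-inclusive |
| z-score rule | z > 0 sensitive | — | strict inequality; z computed on $-\log_{10}$(M) |
| tumor-type rule | > 60% | percent | strict; neither side > 60% → mixed |
| `fdr_threshold` | 0.05 | FDR | BH-adjusted enrichment cut |

## The synthetic-data generator

`generate_dataset()` draws the study design the pipeline assumes:

* per-gene log2 expression i.i.d. normal with gene means
  $\sim U(4, 12)$ and sds $\sim U(0.5, 2)$ — the dynamic range of typical
  log-scale expression arrays;
* $y = \beta_0 + \sum_j \beta_j z_j + \delta_{\mathrm{blood}} + \varepsilon$,
  with $z_j$ the causal genes' expression standardized by their generative
  moments, $\varepsilon \sim N(0, \sigma^2)$, $\sigma = 0.3$ by default;
* a training cohort of 52 solid lines plus 6 blood-lineage lines carrying
  a resistance offset $\delta = -1.5$ (about 30-fold higher IC50) — the
  separable resistant subgroup the lineage exclusion is meant to remove;
* an independent 37-line solid-tumor blind cohort from the identical law;
* $\beta_0 = 6.5$, placing typical IC50s in the tens-of-nanomolar to
  tens-of-micromolar window where cytotoxic potencies live.

**Causal architecture.** The default is a *single* dominant driver with
$\beta = 1.5$. This is a deliberate design choice: the motivating biology
is a prodrug activated by one reductase, where the enzyme's expression is
the causal determinant and other signature members are correlates rather
than independent drivers. Secondary causal genes are available
(`n_secondary`, `beta_secondary = 0.4`) and are used throughout the test
suite to stress multi-gene selection; an optional block-correlation mode
(`block_rho`) attaches correlated passenger genes to each causal gene to
stress collinearity handling. With a dominant driver at $\beta = 1.5$ the
driver alone explains most of the target variance, so a correctly working
funnel should both recover it and assign it the bulk of the normalized
importance — the package's structural analog of a bioactivating enzyme
dominating a fitted signature.

**What the generator does not emulate** — and hence what passing tests do
not establish about real panels: genes are independent by default (real
expression has pervasive co-expression structure), there are no batch or
platform effects, no probe-level noise model, tumor-type labels carry no
expression signal, and the causal model is linear in standardized
expression. Results on synthetic data bound what the pipeline can do under
its own assumptions; they do not certify performance on any real cohort.

## Numerical and degenerate-input choices

* **Fold boundary.** "Within k fold" includes equality; the ratio test
  uses a $10^{-9}$ relative tolerance so floating-point representation of
  an exactly-k-fold pair still counts as within.
* **z = 0.** A sample exactly at the cohort mean is called *resistant*:
  the sensitive rule is strictly $z > 0$.
* **Ties.** Every ordering (correlates, Relief weights, importances) breaks
  ties by metric first, then lexicographic gene id — outputs are stable
  across platforms.
* **Degenerate targets.** Zero-variance $y$ yields a constant predictor
  with a warning; zero-variance prediction cohorts make z-scores undefined
  and raise an error directing users to the raw predictions; single-sample
  cohorts likewise cannot be z-scored.
* **Missing expression.** The reader rejects files with missing cells by
  default; per-gene median imputation is available but must be opted into,
  since silent imputation hides data problems.
* **Duplicate gene rows** are a hard error naming the gene — averaging
  duplicates silently would change results irreproducibly.
* **Wilcoxon.** Exact p-values when both groups have ≤ 10 observations and
  no ties; midranks with normal approximation and continuity correction
  otherwise.
* **Enrichment.** Upper-tail hypergeometric p per set (identical to
  one-sided Fisher), BH across sets, inclusive at the FDR threshold. The
  universe is the set of *measured* genes, not all annotated genes —
  enrichment should be judged against what the screen could have seen.
* **Seeds.** One master seed per derivation; stages derive their own seeds
  by fixed offsets so that adding or removing an optional stage does not
  shift the randomness of later ones. All generator and pipeline outputs
  are byte-reproducible given config + seed.

## Problem sizes used in the packaged studies

The test suite and the results script run the generator at its default
scale (52 + 6 training lines, 37 blind, 2000 genes) for whole-pipeline
checks, and at 40 lines × 150 genes for fast per-module checks; the Boruta
error-control study uses 100 features over 20 (all-noise) and 10 (planted)
replicates. These sizes were chosen so each study finishes in minutes on a
single core while staying at the cohort scale the method targets.

## Known limitations

* An 11-sample holdout makes the selection criterion granular (steps of
  1/11); signatures chosen on different seeds can differ in size by a few
  genes even when predictions barely change.
* Tree ensembles neither extrapolate outside the training expression range
  nor represent smooth trends exactly; near-ceiling fold accuracies are
  capped by that approximation floor, not by the selection pipeline.
* The pathway/network filters are only as good as the supplied GMT/SIF
  content; no identifier mapping is attempted, so gene symbols must match
  the expression matrix exactly.
* Boruta's tentative class is excluded from signatures; on tiny cohorts
  this can drop genuinely weak contributors. Raising `boruta_max_iter`
  reduces the tentative set at linear cost.
* z-score classification is within-cohort by construction: calls depend on
  the cohort's composition, and a cohort of uniformly resistant lines will
  still be split at its own mean.
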