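---
title: "Inferring master regulators of yeast replicative lifespan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring master regulators of yeast replicative lifespan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrnet)
```

## The problem and the model

Systematic screens of yeast deletion mutants produce two kinds of data that
rarely meet: per-strain replicative lifespan (RLS, the number of daughters a
mother cell produces before senescence, reported as percent change vs. wild
type) and per-strain genome-wide expression profiles (log2 fold-changes vs.
wild type). `mrnet` joins them under one working hypothesis: a deletion
changes lifespan *through* the expression changes it induces, and a small
set of genes — master regulators (MRs) — carries most of that signal.

The model is linear and additive. For mutant $i$ with expression profile
$x_{ij}$ over genes $j$,

$$y_i = \beta_0 + \sum_j \beta_j x_{ij} + \varepsilon_i,$$

where $y_i$ is the percent RLS change. With thousands of genes and only
hundreds-to-low-thousands of mutants, the coefficient vector is estimated by
LASSO, minimising

$$\mathrm{Cost}(\beta_0, \beta) = \sum_i w_i\Bigl(y_i - \beta_0 -
  \sum_j \beta_j x_{ij}\Bigr)^2 + \alpha \sum_j |\beta_j|$$

with the intercept unpenalised. Genes with nonzero $\hat\beta_j$ are the
model's master regulators; the sign of $\hat\beta_j$ predicts which
direction of perturbation should extend lifespan.

### Reliability weights

RLS estimates rest on wildly different numbers of microdissected mother
cells per strain — very commonly 5, occasionally thousands. The weight

$$w_i = \frac{n_i}{n_i + c}, \qquad c = 50 \text{ cells by default}$$

discounts shallow strains (a 5-cell strain gets $w = 1/11$) and saturates
for deeply assayed ones ($w \to 1$ beyond a few hundred cells).
`weight_sensitivity()` refits with $c \in \{30, 50, 80\}$ and reports the
Jaccard overlap of the selected gene sets; on synthetic panels the sets
overlap strongly, and the package treats $c$ as a robustness knob, not a
tuning parameter.

### The self-deletion singularity

In a deletion panel, the profile of mutant $i$ contains the log2 fold-change
of its *own deleted gene*, which is a large negative number (about $-8$
after pseudo-counting) regardless of anything lifespan-related. Left alone
it would dominate the regression. Two strategies are implemented
(`apply_self_handling()`):

* **self0** — set the $(i, \text{deleted gene of } i)$ entry to exactly 0;
* **nonlinear** — pass every entry through $g(x) = s\,\tanh(x/s)$. No
  particular saturating form is canonical; $\tanh$ was chosen because it is
  odd, smooth, exactly identity-sloped at 0, and hard-bounded by $\pm s$, so
  ordinary fold-changes (|x| ≲ 1) are essentially untouched while the $-8$
  self-entries are clipped to about $-s$. The scale $s$ (default 2 log2
  units, i.e. saturating around 4-fold changes) is exposed in every fitting
  function.

Both strategies are first-class throughout; fits under the two agree well on
synthetic data, mirroring their intended equivalence.

### Choosing the penalty

`cv_mrlasso()` selects $\alpha$ by k-fold cross-validation (default k = 10):
seeded random folds, the weighted squared error on held-out mutants (using
the same $w_i$) as the criterion, and ties broken toward the larger
$\alpha$, i.e. the sparser model. The default grid is 50 log-spaced points
descending four decades from the critical penalty $\alpha_{\max} =
2\max_j |\sum_i w_i x_{ij}(y_i - \bar y_w)|$, above which the fit is the
null model. Weights are used identically inside and outside the folds, and
the two self-handling strategies are tuned separately.

## The solver and its numerical choices

The objective is minimised by cyclic coordinate descent with an active-set
strategy (compiled code, warm starts along decreasing penalty paths):
repeated full sweeps locate the active set, inner sweeps iterate it to
stability, and a final full sweep verifies the optimality conditions for
excluded coordinates. Features are used on their native log2-FC scale — no
column standardisation — because fold-changes already share a scale and the
products $\beta_j x_{ij}$ are interpreted directly as per-gene lifespan
contributions downstream.

Convergence is declared when the largest per-coordinate objective decrease
in a sweep falls below `tol` times the weighted null deviance
(`tol = 1e-9` by default, capped at `1e5` sweeps). We first implemented an
absolute coefficient-change criterion; in the overparameterised deep end of
the penalty path (more genes than mutants, near-singular design) coordinate
changes decay extremely slowly even though the objective has long converged
— the minimiser there is not unique although its value is — making path
fitting orders of magnitude slower for no gain in any quantity the pipeline
consumes. The deviance-scaled criterion is the standard resolution for
coordinate-descent LASSO solvers; the test suite holds the solver to its
real contract by checking objectives against an independent pure-R
coordinate-descent oracle and against `glmnet` (at the verified penalty
mapping $\lambda = \alpha / 2\sum_i w_i$) to 1e-6 relative, and
coefficients against closed-form weighted least squares at $\alpha = 0$ to
1e-8.

Degenerate inputs: zero-variance features are dropped with a warning
(their coefficients are reported as 0); a constant response makes every
penalty yield the null model; non-convergence is carried in the fit object
and raised as a warning, never silently ignored.

## Downstream statistics

**Responsiveness across long-lived mutants** (`responsiveness()`).
Long-lived mutants are those with RLS extension $\ge 15\%$ at $p < 0.05$
that have expression data (`select_long_lived()`; the 15% bound is
inclusive, the p bound strict). For each gene, over the $N$ selected
mutants: $a$ = mean |log2-FC| (response magnitude), $b$ = |mean log2-FC|,
and $r = b/a \in [0, 1]$ (directional consistency; random signs give
$b \approx a/\sqrt N$, consistent signs give $r \to 1$). Genes with $a = 0$
have undefined $r$, reported as missing and excluded from downstream
comparisons. `compare_mr_background()` contrasts MR vs. non-MR
distributions of $a$, $b$ and $r$ with the two-sample Kolmogorov–Smirnov
test (asymptotic p-values — group sizes here are hundreds, where the
asymptotic and exact versions agree to far below any decision threshold).

**Peripheral genes and the PG–MR network** (`assign_peripheral_genes()`,
`build_pg_mr_network()`). A long-lived mutant whose lifespan the model
predicts well — relative discrepancy
$d = |L_1 - L_2| / (|L_1| + |L_2|) < 0.5$ strictly, with $d(0,0)$ defined
as 0 — and whose deleted gene is not itself a selected MR, is a peripheral
gene (PG). Each PG links to its top-10 MRs by the contribution
$\tilde x_{ij}\hat\beta_j$, computed on the same self-handled features used
in fitting so that the full contribution sum plus intercept reproduces the
model prediction exactly. Ranking is by *signed* contribution descending
(largest positive push toward extension first); the source procedure says
only "top contributing", so the absolute-value ranking is available via
`rank_by = "abs"`. Ties break by gene name for determinism. Stringency is
a parameter, not a result: `threshold_sensitivity()` sweeps
$d < \{0.3, 0.5, 0.7\}$ and top-$k \in \{5, 10, 20\}$; PG sets are nested
in the threshold and edge lists nested in $k$ by construction, and the
cross-setting intersection identifies the core network.

**TF-module scores** (`module_zscore()`, `score_all()`). The coordinated
response of a transcription factor's target set in a differential-expression
profile is scored by the Mann–Whitney rank-sum z: rank all profiled genes by
effect (average ranks on ties), form $U$ for targets vs. all other profiled
genes, and take $z = (U - \mu_U)/\sigma_U$ with the tie-corrected
$\sigma_U$. The score is rank-based (invariant under monotone transforms of
the effects) and signed (positive = targets collectively up). Modules with
$|z| > 2.5$ (strict) are called significantly changed; same-name modules
from different profiling conditions are merged by averaging
(`merge_same_name()`), timecourses are collapsed by `timecourse_mean()`,
and heatmap ordering uses average-linkage hierarchical clustering on
correlation distance (`cluster_order()`; a cosmetic choice nothing else
depends on — constant rows get the maximal distance instead of an undefined
correlation). The background for the rank-sum is all *profiled* non-target
genes, not the genome: genes absent from a profile carry no rank.

**DEG filtering** (`deg_filter()`) keeps genes with fold-change strictly
above 1.5 or strictly below 0.7 at $p < 0.05$. The thresholds live on the
ratio scale and are deliberately asymmetric in log space; log2 profiles are
converted via $2^x$ before comparison. **DE profiles from FPKM replicates**
(`compute_de_profile()`) use effect $= \log_2((\bar F_{case}+1)/(\bar
F_{ctrl}+1))$ and a Welch t-test on $\log_2(F+1)$ across replicates. The
source analyses say only that a differential-expression analysis was run in
R; Welch-on-log is the simplest defensible choice, and because published DEG
counts depend on the (unknown) original test, exact recounts of published
tables should be read with that caveat.

## The synthetic-data generator

`simulate_mutant_panel()` generates panels with exactly the structure the
regression assumes, so that every downstream stage is testable with known
ground truth and no external download. Per `sim_config()`:

* a sparse coefficient vector: `n_mr` genes get $|\beta| \sim U(2, 10)$
  percent per log2-FC, 65% positive (the sign mix of reported MR tables,
  29 positive / 15 negative, is ≈ 0.66);
* expression = i.i.d. Gaussian background (sd 0.25 log2 units, a typical
  compendium-wide dispersion) + zero-inflated Gaussian MR responses (each
  mutant perturbs each MR with probability 0.3, response sd 1) — the zero
  inflation reproduces the observation that an MR responds in a *subset* of
  mutants sharing a mechanism, not in all of them;
* a self-deletion entry of exactly $-8$ log2 units per mutant at its own
  deleted gene (a near-absent transcript after pseudo-counting);
* lifespan $y_i = \sum_j \beta_j x_{ij} + \varepsilon_i$ computed from the
  emitted expression (so the self-entry's contribution is included, exactly
  the singularity the self-handling strategies exist to regularise), with
  $\mathrm{sd}(\varepsilon_i) = \texttt{noise\_sd\_base}/\sqrt{w_i}$;
* mother-cell counts: 80% of strains at the modal count 5, the rest
  log-uniform between 10 and ~2000, mirroring published per-strain cell
  numbers; per-strain p-values are the two-sided normal tail of the
  observed change against its own measurement error;
* TF modules: gene sets sampled from the non-MR genes (overlap allowed, as
  real TF target sets overlap), shifted by `module_shift` (default $-1$
  log2 unit) in mutants whose *true* lifespan change exceeds +15%. Members
  carry zero coefficients, so planting never breaks the noise-free identity
  $y = X\beta$.

No aspect of the noise model linking cell counts to lifespan error is
published; the $1/\sqrt{w_i}$ law is this package's assumption, chosen to
make the weighting scheme the correctly specified estimator, so the tests
can *measure* what weighting buys rather than assume it. (What it buys, at
these noise scales, is recall: the weighted CV-fit recovers more of the
planted regulators in every seed tested; its support-level F1 is not
uniformly better, because cross-validation selects relatively deeper
penalties when the effective sample size is the weight sum, admitting more
false positives.) `noise_sd_base = 5` percent comes
from orders of magnitude typical of the assay: with a ~25-division mean RLS
and ~10-division between-cell spread, a 5-cell strain's percent-change
standard error is around 16–18%, which the $1/\sqrt{w}$ law reproduces
($5/\sqrt{1/11} \approx 16.6$).

What the generator does *not* emulate: correlated co-expression modules in
the background, survival-curve shapes (only the percent change is modelled),
raw counts/FPKM replicate noise for the panel itself, and strain mislabeling
or batch structure. Passing recovery tests on these panels therefore shows
the estimator is correct *under its own assumptions*, not that real
compendia satisfy them.

## Problem sizes used in the checks

The parameter-recovery checks run at 1000 mutants × 3000 genes with 30
planted MRs over five seeds — large enough for the p ≫ n regime and a
realistic long-lived fraction, small enough to iterate on a laptop; 5-fold
CV is used for both the weighted and the (flat-weight) comparison arm of
that check, while the package default remains 10-fold. The end-to-end
pipeline demonstration uses 300 × 600. The acceptance script
(`scripts/acceptance.R`) re-runs the 1000 × 3000 recovery with 10-fold CV
plus a 200 × 500 keep-one-out validation and writes every quantity it
computes to JSON.

## Known limitations

* Transcript-level only: regulators acting post-transcriptionally are
  invisible to the linear model, whatever the solver does.
* The linear additive model is a working approximation; interactions
  between expression changes are not modelled.
* LASSO selection among strongly correlated predictors is not unique; the
  reported support should be read together with the weighting-constant and
  stringency sensitivity reports rather than as a fixed gene list.
* Coefficient standard errors / selection inference are out of scope.
* The Welch-based DE p-values are a stand-in for whatever test produced any
  particular published DEG table; recounts can differ at the margin.
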