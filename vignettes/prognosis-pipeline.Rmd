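---
title: "Methods: receptor deconvolution, prognosis gene selection and survival screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: receptor deconvolution, prognosis gene selection and survival screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcprog)
```

This vignette is the package's account of its statistical methods: the
models behind each stage, the parameters that matter, the numerical
choices, and what the synthetic-cohort tests do and do not establish about
real data.

## Cohort definition

Tumour samples are partitioned by the five-year rule implemented in
`classify_prognosis()`: death strictly before the horizon (default 5
years) is Poor Prognosis; alive with follow-up strictly beyond it is Good
Prognosis; alive with follow-up at or below it is indeterminate and
Excluded. The rule leaves one case genuinely open — patients who died
*after* the horizon. They did survive past it, so the package assigns them
GP by default; `late_death = "Excluded"` drops them instead. The choice is
exposed because published cohort definitions are usually silent on this
case and the two options change the GP denominator.

Times are in years throughout. The comparison at the horizon uses strict
`<` for PP and strict `>` for alive-GP, so a follow-up of exactly 5.0
years, alive, is Excluded.

## Receptor positivity by mixture deconvolution

RNA-based receptor status treats the tumour population as a mixture of a
receptor-negative and a receptor-positive population on the log10
expression scale:

$$f(x) = w_1\,\varphi(x;\mu_1,\sigma_1) + w_2\,\varphi(x;\mu_2,\sigma_2),
\qquad \mu_1 < \mu_2 .$$

`fit_gmm1d()` estimates the five parameters by EM. Design points:

* **Estimator.** EM on the raw log10 values is the maximum-likelihood
  estimator for this model; it is preferred over histogram curve-fitting
  because it has no binning tuning parameter and is directly testable by
  simulation recovery. The suite cross-checks the fit against `mclust` on
  one fixture (our converged log-likelihood must not be materially lower).
* **Initialisation.** Hard responsibilities from a median split — fully
  deterministic. Random restarts (`n_restarts`) perturb the split quantile
  and are the only consumer of the `seed` argument; the best
  log-likelihood wins.
* **Monotonicity.** The EM log-likelihood is asserted non-decreasing at
  every iteration; a decrease is a hard error, not a warning.
* **Degeneracy.** Inputs with fewer than 10 finite values or zero variance
  are rejected. A variance floor (`var_floor = 1e-6` on the log10² scale)
  prevents component collapse; hitting it sets the `vfloor_hit` flag.
* **Zeros.** Expression is transformed as `log10(x + eps)` with
  `eps = 1e-3`, small relative to any plausibly expressed gene, so
  all-zero receptor measurements land far below any threshold.

The positivity threshold is the **density intersection** between the two
means: equating log densities gives a quadratic in $x$ (linear when
$\sigma_1 = \sigma_2$, handled by its closed form). Only the root inside
$(\mu_1, \mu_2)$ is biologically meaningful — the other quadratic root
lies in a tail where the minority component dominates again purely through
its heavier variance. If no root falls between the means (possible for
extreme weight ratios), the nearest root is returned and flagged. The
solver is verified against bisection of the density difference to 1e-6
over random parameter draws.

Calls are strict: a sample is positive iff log10 expression **exceeds**
the threshold, so a value exactly at the boundary is negative. Mixtures
are fitted on tumour samples only by default (`include_normals = FALSE`):
normal tissue is mostly receptor-low and would inflate the negative
component's weight and shift the intersection.

Subtype assignment is the total function of the three statuses:
hormone-positive (ER+ and/or PR+) splits into Luminal A (HER2−) and
Luminal B (HER2+); hormone-negative into HER2-enriched (HER2+) and Triple
Negative.

## Differential expression and gene selection

`differential_expression()` runs per-gene Welch (unequal-variance) t tests
between two sample groups on `log2(x + 1)` values. Welch is the default
because group variances in expression data routinely differ; the pooled
test is not offered since the Welch statistic reduces to it when variances
agree. Testing on the log scale stabilises variance; `scale = "linear"`
is available for sensitivity analysis.

The fold change reported and thresholded is, by default, **geometric**:
$\log_2 \mathrm{FC} = \overline{\log_2(x+1)}_B - \overline{\log_2(x+1)}_A$.
The alternative (`fc_method = "linear"`) is the ratio of linear-scale
group means with a pseudocount. The geometric definition is the package
default for a statistical reason: on log-normal expression the sample mean
is dominated by the right tail, and at $n = 50$ per group the
ratio-of-means estimator has a coefficient of variation near 0.5 — large
enough to push genuinely 4-fold genes under the 2-fold threshold roughly
10% of the time. The geometric estimator's error shrinks with the log-scale
SD and recovers planted effects far more reliably; it is also the
conventional log2FC of t-test pipelines.

Volcano classification: `over` iff FC ≥ 2 and BH-adjusted q < 0.05;
`under` iff FC ≤ 0.5 and q < 0.05; otherwise `ns`. BH adjustment is the
standard step-up procedure (`stats::p.adjust`), validated in the suite
against an independent implementation of the definition. Genes constant
across both groups are defined to `t = 0, p = 1, ns`.

`select_group_specific()` is pure set algebra over two DE tables sharing a
gene universe: over/under in PP-vs-Normal minus over/under in
GP-vs-Normal gives the PP-only sets, and symmetrically; intersections are
the shared sets. The selections partition the per-group significant sets,
which is asserted in tests.

`pca2()` projects samples onto the top two right singular directions of
the column-centred, per-gene standardised `log2(x+1)` matrix.
Standardisation is the default so that selection-set PCA is not dominated
by a few high-variance genes. Sign is fixed per component (largest-
magnitude loading positive) to make scores deterministic; rank-deficient
inputs flag the second component rather than erroring.

## Survival screening

`km_estimate()` is the product-limit estimator; ties between deaths and
censorings at the same time are resolved deaths-first (the standard
convention: censored subjects remain in the risk set at their own time).
`survival_at()` evaluates the curve as a right-continuous step function,
so a query exactly at an event time returns the post-jump value; queries
beyond the last observed time carry the last value forward and set an
`extrapolated` flag. Five-year fractions are read at exactly t = 5.0
years.

`logrank()` is the two-group log-rank test with hypergeometric variance at
each distinct event time. Degenerate inputs (no events, or zero variance)
return `chi2 = 0, p = 1` with a flag rather than NaN. Both kernels are
compared against `survival::survfit()`/`survdiff()` on 100 random censored
datasets to 1e-10 in the test suite; those packages are oracles only — the
screen runs entirely on the package's own kernels.

`tertile_stratify()` splits patients by expression rank into thirds of
sizes as equal as possible; when $n \bmod 3 = 1$ the extra patient goes to
the low tertile, when $n \bmod 3 = 2$ one extra goes to each extreme
(10 → 4/3/3, 11 → 4/3/4). Ties are broken by stable input order, making
the split deterministic; tied values spanning a boundary emit a warning.
The screen compares **top vs bottom tertile only** — the middle third is
deliberately excluded to sharpen the contrast, matching how such screens
are usually reported. Raw log-rank p values order the screen (screens of
this kind conventionally report unadjusted p); a BH-adjusted `q` column is
included for reference.

## Clinical statistics

* `fisher_exact()` uses the probability-mass two-sided rule — the p-value
  sums all tables with the observed margins whose probability does not
  exceed the observed table's — via `stats::fisher.test`, which implements
  exactly that definition; the suite verifies it against brute-force
  hypergeometric enumeration for tables with N ≤ 60. Demographic stage
  tests pool sub-stages into their main stage (I = I+IA+IB, etc.): the
  pooled counts reproduce the reference p-values the acceptance suite
  checks.
* `logistic_prognosis()` fits a **binomial** logistic regression of PP
  vs GP. With a two-class outcome the multinomial model collapses to
  binomial, so that is what the package implements. Predictors are
  dichotomised as is conventional for prognosis factors: age above the
  cohort median, and late stage (III–IV vs I–II). Possible separation is
  detected by coefficient magnitude (> 10 log-odds) and flagged with a
  warning rather than silently reported.
* `anova_tukey()` is one-way ANOVA with Tukey HSD via
  `stats::aov`/`stats::TukeyHSD` (studentized-range distribution), applied
  per immune-cell-type column of a deconvolution fraction table. The
  suite checks the two-group identity F = t² and null calibration.
* `pearson()` wraps `stats::cor.test` (t-approximation p).

## The synthetic cohort generator

`simulate_cohort()` emulates exactly the statistical structure the
pipeline assumes, with every parameter in `cohort_config()`:

* **Cohort sizes** default to 105 normal / 200 intended-GP / 101
  intended-PP, the group sizes of the emulated study design.
* **Expression** is log10-normal per gene: per-gene means drawn from
  N(1.5, 0.5²) log10 units and SDs uniform on [0.2, 0.6] — spanning
  tight housekeeping-like genes to noisy low-expression genes on an
  FPKM-like scale.
* **Receptor genes** are two-component mixtures in tumours with positive
  weights 0.7342 (ESR1), 0.578 (PGR), 0.1096 (ERBB2) — the positivity
  rates the thresholding stage should reproduce — and component means
  separated by roughly 2.5–4 component SDs, comparable to real receptor
  bimodality. Normal tissue draws from the negative component. The true
  threshold recorded in the ground truth is the numeric density
  intersection of the specified components.
* **Planted DE genes** (default 30 PP-only, 30 GP-only, 30 shared, log2
  effects ±2) are shifted on the log10 scale by `log2fc · log10(2)` in
  their designated intended group(s) only.
* **Survival** is exponential proportional hazards: log-hazard = log
  baseline + Σ coef · standardised log10 expression over the hazard genes
  (defaults: two genes at +1.1 and −0.8). Intended-PP tumours carry a
  baseline multiplied by `pp_hazard_ratio` (default 25 over a 0.02/yr GP
  baseline), so most die within five years. Censoring is independent
  exponential (0.03/yr) truncated at the follow-up horizon (12 yr).
  Group labels are then **re-derived** with `classify_prognosis()` — the
  generator exercises the classifier instead of asserting labels, so a
  minority of tumours flip group or become Excluded, as in real cohorts.
* **Covariates**: age is normal per group (means 58.2/54.3/63.7, the
  demographic structure the clinical statistics expect); stage and race
  are categorical draws with group-specific probabilities proportional to
  the emulated cohort's published counts.
* **Determinism**: the whole cohort is a pure function of the config;
  all randomness flows through `withr::with_seed(config$seed, ...)`.

What the generator does **not** emulate: count-level sampling noise
(values are continuous abundances, not negative-binomial counts), batch
effects, gene–gene correlation beyond the planted blocks, any dependence
between subtype and survival, and the generative model of immune-cell
deconvolution. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated under the assumed model — not that
the model captures every feature of real tumour transcriptomes.

## Problem sizes and tolerances in the test suite

The suite runs at sizes chosen to make the statistical checks decisive yet
quick: threshold recovery uses 20 cohorts of 2000 tumours (median
absolute error below 0.1 log10 units at 2.5-SD component separation); DE
calibration and recovery use ten 500-gene cohorts at 50 samples per group;
the survival screen's null calibration pools 1000 log-rank p-values from
ten cohorts and tests uniformity by Kolmogorov–Smirnov; logistic recovery
uses twenty n = 300 designs with a true odds ratio of 3. Exact kernels
(intersection solver, Kaplan–Meier, log-rank, Fisher) are held to
1e-6–1e-10 against independent oracles. The end-to-end example runs a
500-gene, 80-sample cohort.

## Known limitations

* The mixture model fixes k = 2; receptor distributions with a third
  (e.g. amplified) population will fold it into the positive component.
* Thresholds estimated on small tumour cohorts (n < 100) are noisy,
  especially for low-prevalence receptors like HER2; the acceptance
  checks quantify this at n = 2000.
* The screen's log-rank p-values are unadjusted by design; users screening
  thousands of genes should read the `q` column.
* The logistic model reports Wald intervals; profile-likelihood intervals
  would be preferable near separation, which is only flagged.
* `select_group_specific()` inherits the volcano thresholds; genes just
  under a threshold in one contrast and just over in the other move
  between the *-only and shared sets discontinuously.
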