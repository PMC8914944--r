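---
title: "Negative control outcomes and difference-in-differences for a fully treated cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Negative control outcomes and difference-in-differences for a fully treated cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nccdid)
```

## The estimation problem

When a treatment is introduced for an entire eligible subgroup — here the
motivating setting is a disease-modifying drug made available to every
registry patient carrying an eligible genotype — there are no
contemporaneous untreated comparators for the treated, and the positivity
assumption underlying standard covariate adjustment fails outright.
Analysts then fall back on *naive* comparisons: the treated group versus
its own pre-introduction history (the **time-period comparison**) or
versus patients whose genotype makes them ineligible (the **genotype
comparison**). Both are biased whenever genotype or calendar period is
associated with the untreated outcome — different genotypes can have
different disease trajectories, and population health drifts over time.

`nccdid` implements the negative-control correction of such comparisons.
Write $G \in \{0,1\}$ for eligible genotype, $P \in \{0,1\}$ for the
post-introduction period, and classify every person-period into the four
groups

| group | $P$ | $G$ | treated |
|-------|-----|-----|---------|
| A | 0 | 1 | no |
| B | 1 | 1 | **yes** |
| C | 0 | 0 | no |
| D | 1 | 0 | no |

Only group B is treated. The estimand is the average treatment effect in
the treated, $E(Y^{X=1} \mid P=1, G=1) - E(Y^{X=0} \mid P=1, G=1)$, whose
second term is never observed.

Each naive treatment effect (NTE) has a matching **negative control
effect (NCE)** built by switching the treatment label onto a group that
is in fact untreated:

* `NTE_P` contrasts B against A; its negative control `NCE_P` contrasts
  D against C — the same period contrast among genotype-ineligible
  persons, whom treatment cannot have touched in either period.
* `NTE_G` contrasts B against D; its negative control `NCE_G` contrasts
  A against C — the same genotype contrast on pre-introduction outcomes,
  which precede the treatment.

A nonzero NCE flags bias in the matching NTE. Under the untreated-world
model
$$E(Y^{X=0} \mid P, G) = \alpha + \beta_P P + \beta_G G + \gamma_{PG} P G,$$
the NTE bias equals $\beta_G + \gamma_{PG}$ (genotype comparison) or
$\beta_P + \gamma_{PG}$ (time-period comparison), while the NCE equals
$\beta_G$ or $\beta_P$. If $\gamma_{PG} = 0$ — no period-by-genotype
product term in the untreated world — the difference-in-differences
combination
$$\mathrm{NCCTE} = \mathrm{NTE} - \mathrm{NCE}$$
is unbiased for the causal effect. That identity is the whole package:
everything else is model fitting and uncertainty quantification around
it. The no-interaction assumption is untestable from the data; the
package's contribution is to make it the *only* structural assumption,
in place of the much stronger "no $G$ (or $P$) effect at all" that the
naive comparisons need.

## Outcome models

**Continuous outcomes** (e.g. ppFEV1, in percentage points) use the
step/slope model over the up-to-$J$ annual visits $j = 0, \dots, J-1$ of
a period:
$$E(Y_{ij} \mid X_i) = \beta_0 + \beta_{St} X_i + \beta_{Sl} X_i j + \beta_J j,$$
where $X_i$ is the (possibly label-switched) pseudo-treatment indicator
of the contrast. $\beta_{St}$ is the immediate level shift at visit 0
and $\beta_{Sl}$ the change in annual trend; $\beta_J$ is the secular
trend shared by both arms. Each of NTE and NCE is therefore a pair
(step, slope), and the corrected effect is the component-wise
difference.

**Count outcomes** (e.g. annual IV-antibiotic days) use a log-link
marginal model with year-specific treatment terms:
$$\log E(Y_{ij} \mid X_i) = \gamma_0 + (\text{visit terms}) +
  \sum_k \gamma_{Xk}\, X_i\, 1(j = k - 1),$$
so $\exp(\gamma_{Xk})$ is the rate ratio after $k$ years of treatment
(treatment year $k$ is visit $j = k-1$ of the post-introduction period:
visit 0 is the first annual review after introduction). Corrected rate
ratios divide: $\mathrm{NCCTE}_{RR} = \mathrm{NTE}_{RR} /
\mathrm{NCE}_{RR}$, i.e. subtraction on the log scale. The visit terms
default to one indicator per visit index (a saturated secular trend);
`visit_trend = "linear"` replaces them with a single linear-in-$j$ term.
The saturated default is deliberate: the linear-in-$j$ form is stated
for the continuous model only, and a saturated trend cannot be
mis-specified across four visits. No exposure offset is used — the
outcomes are annual counts over fixed one-year windows.

### Fitting

Both models are fitted by estimating equations with an **independence
working correlation**. For point estimation this working choice makes
the estimating equations identical to stacked-data ordinary least
squares (continuous) and to the Poisson quasi-score equations (counts),
which is how `fit_step_slope()` and `fit_count_effects()` solve them
(via `stats::.lm.fit` and `stats::glm.fit`; score convergence tolerance
`1e-10`, at most 100 iterations, non-convergence is an error). The
quasi-score equations only use the mean model, so overdispersed counts
give consistent point estimates; the Pearson dispersion is reported as a
diagnostic. Within-person dependence is *not* modelled in the mean fit
at all — it is absorbed entirely by the person-level bootstrap. A
person-clustered sandwich covariance is attached to `fit_step_slope()`
output as a diagnostic, but the package's reported intervals are always
bootstrap percentile intervals.

Collinearity is detected with a pivoted QR factorisation at relative
tolerance `1e-8` and reported with the names of the offending columns.
A count-model cell (an $X$-by-visit combination) whose outcomes are all
zero would drive its log rate to $-\infty$ and is an error on the full
data (a dropped resample inside the bootstrap).

## Covariate adjustment

Baseline covariates are measured in the year before visit 0 of each
period, so a person contributing to both periods has two baseline
vectors. Three adjustment modes are exposed:

* `"unadjusted"` — the model above as-is.
* `"conditional"` — encoded covariate columns enter the outcome model,
  giving conditional effect estimates (valid as common effects when the
  covariate effect is not modified by the contrast).
* `"standardized"` — g-computation: the outcome model is fitted among
  the $X=0$ records at a visit, its predictions are averaged over the
  empirical covariate distribution of the $X=1$ records, and the
  standardized mean is subtracted from the observed $X=1$ mean. On the
  count scale the analogous ratio of observed to standardized means is
  taken per treatment year. For the step/slope decomposition the
  standardized step is the visit-0 standardized difference and the
  standardized slope is the least-squares slope of the per-visit
  standardized differences on the visit index. Whether adjusted count
  analyses should condition or standardize is genuinely open in this
  design; the package exposes both and defaults to conditioning, which
  matches the continuous-outcome convention.

Encodings are declared per covariate (`covariate_spec()`): `identity`,
`binary`, and `count_baseline`, which expands a baseline count (such as
prior-year IV days) into a nonzero indicator plus a linear term among
the nonzeros — the spike at zero in such variables makes a single linear
term a poor summary. Missing covariate values are handled by complete
case deletion within each fitted model, with logged counts; the package
deliberately ships no imputation.

Standardization requires covariate overlap: for discrete covariate
columns a stratum present under $X=1$ but absent under $X=0$ is an
error; for continuous columns extrapolation beyond the $X=0$ support is
a warning, since a linear outcome model can formally extrapolate but the
result rests on the model rather than the data.

## Bootstrap inference

All three effects of a comparison are bootstrapped **jointly**:
`estimate_ncc()` draws one person-level resample of the whole cohort per
iteration (persons are the dependence unit; a resampled person carries
all their records in both periods, so someone contributing to groups A
and B is resampled as a unit), refits NTE and NCE on that resample, and
combines them. The corrected effect's interval therefore reflects the
joint sampling variation of all four groups, including the overlap of
persons across periods — resampling the two contrasts independently
would double-count shared persons.

Intervals are 95% percentile intervals over `B` resamples (default
1,000, matching common registry practice; below 100 a warning is
issued). P-values invert the percentile interval: the reported p is the
smallest $\alpha$ on the grid $\{0.001, \dots, 0.999\}$ at which the
$(1-\alpha)$ percentile interval excludes the null (0 for differences, 1
for rate ratios). This construction is consistent with the reported
intervals by design; it is a documented choice, not the only possible
bootstrap p-value. BCa intervals are not implemented. Resamples on which
a fit degenerates (a group emptied, a collinear design, an all-zero
count cell) are dropped and counted; more than 5% failures aborts with
an error rather than silently biasing the interval. Everything is
seeded: two runs with the same seed are bit-identical.

## The synthetic registry generator

Because the motivating registry data are not public, the package ships a
generator (`simulate_cohort()`, `simulate_count_cohort()`) whose mean
structure is exactly the untreated-world model above plus step/slope
treatment effects confined to the treated cell, and whose ground truth
is available in closed form (`ground_truth()`). It emulates:

* two genotype groups of configurable size, persons contributing to both
  periods with probability `p_both_periods` (default 0.7, loosely
  matching the overlap seen in registry group tabulations);
* up to `J = 4` annual visits per period with completely-at-random visit
  missingness (default 10%);
* within-person correlation via a Gaussian random intercept shared
  across a person's two periods (continuous) or a mean-1 gamma frailty
  (counts, variance = `dispersion`) — dependence the independence
  working model deliberately ignores, so that the bootstrap is exercised
  against genuinely clustered data;
* per-period baseline covariates whose means or prevalences may depend
  on $G$ and $P$ (the channel for scenario-2-style measured
  confounding), with linear effects on the continuous outcome;
* free-text genotype labels on the ineligible group (a two-allele
  mutation-pair naming scheme with realistic frequencies) to exercise
  the sensitivity restriction `restrict_genotype_subset()`.

Three presets name the canonical structures (`scenario_config()`):
`scenario1` ($G$ and $P$ unrelated to the untreated outcome: naive
effects unbiased, negative controls null), `scenario2` ($G$ and $P$ act
only through a measured baseline covariate: conditional adjustment
repairs the naive effects), and `scenario3` (direct dependence:
$\beta_P = 0.8$, $\beta_G = 2$; only the corrected effects are
unbiased). Shared defaults are chosen once as plausible magnitudes on
the ppFEV1 scale: baseline $\alpha = 70$, annual decline $\beta_J = -1$,
treatment step $\delta_{St} = 5$ and slope $\delta_{Sl} = 0.5$,
between-person SD 8 and residual SD 4; the count generator defaults to a
baseline 18 days/year and treatment rate ratios
$(0.5, 0.4, 0.4, 0.4)$ with frailty variance 0.5. These are fixed study
conditions for the package's validation suite, not tuning knobs.

The generator does **not** emulate real registry marginals
(age/sex/infection distributions), informative dropout, death or
transplant censoring, or measurement error. A passing recovery test
therefore demonstrates that the estimators do what the theory says under
the assumed structure — not that any particular registry satisfies that
structure.

One subtlety: a nonzero untreated-world interaction $\gamma_{PG}$ can be
configured, but its cell $(P=1, G=1)$ is exactly the treated cell, so
within the generator it is observationally indistinguishable from an
extra treatment step. `ground_truth()` accordingly reports the causal
step in the treated as $\delta_{St} + \gamma_{PG}$ and the corrected
estimator remains aligned with it; the parameter probes how the
no-interaction assumption shifts interpretation rather than creating a
recoverable bias.

## Validation problem sizes

The shipped test suite exercises, as the package's own validation
conditions: exact interpolation on noise-free panels; equality with
brute-force normal-equation and hand-rolled IRLS oracles to `1e-6` on 50
random unbalanced instances; scenario-3 recovery of
$(\delta_{St}, \delta_{Sl})$ at 2,000 persons per genotype group within
three Monte-Carlo standard errors for both comparisons, with naive-effect
bias matching $\beta_G$ and $\beta_P$; and bootstrap calibration over
300 simulated cohorts of 400 persons per group at $B = 200$ — 95%
interval coverage of the true corrected step within 93–97%, and a null
scenario-1 rejection rate at the 0.05 level within 3–8%.

## Numerical and formatting conventions

Visit indices are 0-based within period; calendar years are not part of
the core model (the estimators use only $(G, P, j)$), and aligning
visits to calendar years is left to the user preparing the input table.
CSV output writes doubles with 17 significant digits so that write/read
round trips are lossless. Results print differences to two decimals and
rate ratios as integer percent reductions, the conventional reporting
precisions for these quantities. Genotype labels for the sensitivity
restriction are matched as exact strings; the package ships no mutation
ontology.

## Known limitations

The correction removes additive (or log-additive) main effects of $G$
and $P$ only; an untreated-world interaction $\gamma_{PG} \ne 0$ of a
form that does not load on the treated cell is not identifiable here.
Exchangeable or autoregressive working correlations, mixed-effects
likelihoods and zero-inflated count models are out of scope, as are
multiple imputation and synthetic-control extensions. The bootstrap
percentile method can undercover slightly in small cohorts with few
clusters; the calibration suite quantifies this at its stated problem
sizes.
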