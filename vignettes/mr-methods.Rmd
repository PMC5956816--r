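---
title: "Methods: two-sample Mendelian randomisation in mriv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomisation in mriv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriv)
```

## The inference problem

Two-sample Mendelian randomisation (MR) asks whether an exposure causally
affects an outcome, using genetic variants as instrumental variables and
nothing but per-variant summary statistics from two independent GWAS: the
variant–exposure effects $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) and the
variant–outcome effects $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$, log-odds for a
binary outcome). A variant is a valid instrument if it is associated with
the exposure, independent of confounders, and affects the outcome only
through the exposure. Under validity, each variant's Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal
effect $\theta$; the estimators in this package differ in how much
instrument invalidity (pleiotropy) they tolerate while combining the
ratios. The package's worked example is the six-variant serum-magnesium
instrument set analysed against coronary artery disease; defaults
throughout are chosen for that setting but everything is configurable.

## Harmonisation

`harmonise()` inner-joins the exposure and outcome tables on variant id
and resolves allele orientation before any estimation:

- If the outcome's effect allele is the exposure's other allele (or vice
  versa), the outcome beta is negated and its allele frequency
  complemented.
- Palindromic variants (A/T, C/G) are ambiguous across strands. They are
  resolved by comparing allele frequencies only when both are available
  and both fall outside [0.42, 0.58]; otherwise the variant is dropped
  with a warning. The window is the conventional compromise between
  discarding too much and mis-assigning common alleles; the packaged
  example needs no such resolution (its effect alleles are reported
  directly on the exposure-raising orientation), so the rule exists for
  generic inputs.
- Published instrument tables often print only the trait-raising allele.
  When the non-effect allele is unrecorded, a match on the effect allele
  alone is accepted with an "unverified strand" note rather than refused:
  the alternative would make such tables unusable, and the note keeps the
  limitation visible.
- Finally every instrument is oriented so $\hat\beta_{Xj} > 0$ (both betas
  negated if needed). The Wald ratio is invariant to this, but MR-Egger is
  not: the sign of its intercept is only interpretable under a consistent
  exposure-raising orientation.

Variants with an exactly zero exposure beta (undefined ratio) or
irreconcilable alleles are dropped with warnings, and the dropped set is
kept as an attribute for audit. Harmonisation is idempotent, and
instrument counts never exceed either input table.

`substitute_proxies()` runs before harmonisation: when a target variant is
absent from the outcome table, a linked variant's association can stand in
for it, subject to a linkage threshold ($r^2 \ge 0.8$ by default; the
$r^2$ values are supplied metadata computed on an external reference
panel, never computed here). In the packaged example the outcome table
lacks rs7965584 and carries its proxy rs10858938 ($r^2 = 0.96$) instead.

## Estimators

All confidence intervals use normal quantiles (1.959964 at the default
95% level) rather than t quantiles, and p-values are two-sided normal.
With a handful of instruments this is a real choice: it matches the
convention of summary-data MR software, and reproduces intervals of the
form estimate ± 1.96·SE.

**IVW.** $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$ with
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ — algebraically identical to WLS
regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin (the
test suite asserts the equivalence to $10^{-10}$ against `lm()`).
Fixed-effects SE $(\sum_j w_j)^{-1/2}$. The random-effects model is
*multiplicative*: the fixed SE is inflated by $\max(1,\sqrt{Q/(J-1)})$.
The floor at 1 means apparent under-dispersion never narrows the interval,
and the multiplicative (rather than additive, DerSimonian–Laird-style)
form is what reproduces the published random-effects intervals for the
magnesium analysis.

**Cochran's Q** about the fixed-effects estimate, $\chi^2_{J-1}$
upper-tail p.

**Weighted median.** Ratios are sorted ascending and the estimate is the
linear interpolation of the ratio at standardised mid-cumulative weight
$p_j = (S_j - w_j/2)/S_{\text{total}} = 0.5$, with normalised IVW
weights — the convention that makes the estimator reduce to the ordinary
median under equal weights and stay invariant to splitting an instrument's
weight across duplicates. The SE is a parametric bootstrap (default
10,000 resamples): both betas are perturbed by their SEs, weights and
ratios recomputed, the median re-taken. A seed is required whenever the
bootstrap runs inside `mr_fit()`; the point estimate itself is
deterministic.

**MR-Egger.** WLS of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ *with* an
intercept, weights $1/\sigma_{Yj}^2$, implemented in closed form (and
cross-checked against `lm()` in the tests). SEs use the WLS covariance
with overdispersion $\max(1,\sqrt{Q_E/(J-2)})$, floored at 1 to mirror the
IVW convention. At least 3 instruments are required — with 2 the line fits
exactly and nothing is testable.

**SIMEX correction.** Exposure-side measurement error dilutes the Egger
slope by roughly $I^2_{GX}$, where
$I^2_{GX} = \max(0, (Q_{GX}-(J-1))/Q_{GX})$ and $Q_{GX}$ is the weighted
heterogeneity of the exposure betas (`i2_gx()`). `mr_egger_simex()`
corrects this by deliberately *adding* error: for each
$\lambda \in \{0.5, 1, 1.5, 2\}$ (defaults), each exposure beta is
perturbed by $\sqrt{\lambda}\,\sigma_{Xj}$ noise `b_reps` = 1000 times,
the Egger fit is averaged per $\lambda$, a quadratic in $\lambda$ is
fitted through the means (including the naive fit at $\lambda = 0$), and
the slope is read off at $\lambda = -1$. With $\sigma_{Xj} = 0$ the
extrapolation returns the naive slope exactly (the extrapolation
functional has unit sum, so this is an identity, not an approximation).
The reported SE is a jackknife over the pseudo-replicates: it quantifies
the Monte-Carlo uncertainty of the extrapolation itself, *not* the
sampling uncertainty of the slope — the naive Egger SE remains the
measure of statistical precision, and the SIMEX row's p-value should not
be read as a significance test of the causal effect. On strong instruments
(the packaged example has $I^2_{GX} = 0.87$) the correction is small by
construction; the suite also verifies on simulated weak-instrument data
($I^2_{GX} \approx 0.4$) that SIMEX moves the slope towards the truth.

**Heterogeneity-penalised model averaging (HPMA).** Every subset $S$ of
$\ge 2$ instruments gets IVW estimate $\hat\theta_S$, SE $se_S$ and
heterogeneity $Q_S$, and weight
$w_S \propto \big(\prod_{j\in S} p_j\big)\exp(-Q_S/2)$, where $p_j$ are
the normalised IVW weights. The composite function
$L(\theta) = \sum_S w_S\,\phi(\theta;\hat\theta_S, se_S)$ is evaluated on
a grid; the estimate is its mode, consistent when a *plurality* of
instruments shares the true ratio. Numerical choices: singleton subsets
are excluded ($Q$ is undefined below 2 and singletons would reward
arbitrarily heterogeneous data); subsets are enumerated exhaustively with
a hard guard at $J \le 20$ (no sampling fallback — the call errors rather
than silently approximate); the default grid spans
$[\min_S \hat\theta_S - 4\max_S se_S,\ \max_S \hat\theta_S + 4\max_S se_S]$
at 2001 points, and a mode on the boundary raises an error instructing a
wider grid rather than returning an untrustworthy argmax. The 95% region
is the highest-density superlevel set holding 95% of the grid mass; it can
be a union of disjoint intervals when instrument clusters disagree, in
which case all intervals are reported along with the enclosing hull and a
non-contiguity flag. The reported p-value is the two-sided tail mass of
$L$ about zero — a convenient analogue, not a calibrated frequentist test.

**Scaling.** Estimators work per 1 exposure unit; odds-ratio columns are
reported per `scale_factor` units (default 0.1, about one SD of serum
magnesium in mmol/L), preserving `or = exp(scale_factor * beta)`.
`rescale_estimate()` converts units explicitly.

## Diagnostics

`variance_explained()` uses the biallelic additive formula
$2f(1-f)\beta^2/\mathrm{SD}^2$; `f_statistic()` the one-parameter form
$r^2(n-2)/(1-r^2)$. The default exposure SD is 0.1 mmol/L; the packaged
table's printed variance fractions imply an SD slightly below 0.1 (its
betas are rounded to 3 decimals), so `instrument_strength()` prefers a
supplied `variance_explained` column over recomputation. Diagnostics never
gate estimation — weak instruments are reported, not filtered — because
silent filtering changes the estimand.

## The synthetic-data generator

`simulate_mr_study()` draws summary statistics from the generative model
the estimators assume: true exposure effects $\gamma_j$ (by default six
variants spanning 0.004–0.011 trait units, SE 0.001, matching the
magnesium instrument scale), direct effects $\alpha_j$ per pleiotropy
regime, true outcome effects $\Gamma_j = \theta\gamma_j + \alpha_j$, and
observed betas drawn normally with the supplied SEs (default outcome SE
0.011 log-odds, the scale of a large case–control GWAS). Regimes: `none`;
`balanced_inside` ($\alpha \sim N(0, sd)$, independent of $\gamma$ — the
InSIDE assumption holds by construction); `directional` (non-zero mean);
`plurality` (invalid instruments split into two clusters at
$\pm\alpha_{\text{mean}}$, with a validity check that the valid class
remains the largest). An `inside_violation` coefficient adds
$\kappa(\gamma_j - \bar\gamma)$ to invalid instruments' direct effects for
negative tests of MR-Egger. The last `round(frac_invalid * J)` variants
are the invalid ones, so callers can control "invalid by weight" through
the $\gamma$ ordering.

Outcome effects are generated directly on the log-odds scale — no
individual-level case–control sampling — because the estimators consume
only summary statistics. The generator deliberately omits LD between
variants, winner's-curse selection of instruments, and allele-frequency–
dependent power. Passing recovery tests therefore validates the
estimators' statistical logic under their own assumptions; it does not
certify behaviour on real data where instrument selection and LD pruning
precede analysis.

`recovery_experiment()` aggregates bias, empirical SE, RMSE and coverage
over seeded replicates, counting (not dropping) failed fits.

## Validation conditions used by the test suite

The suite's simulation checks run at sizes chosen to balance Monte-Carlo
resolution against a test run of about a minute: 2000 replicates for the
null type-I error of IVW (three-sigma binomial band about 0.05), 1000 for
coverage under no pleiotropy (band 0.92–0.98) and for the weighted-median
robustness comparison, 500 for the Egger intercept under balanced InSIDE
pleiotropy. The robustness experiment uses precise instruments
($\sigma_Y$ small relative to the pleiotropic separation): the median's
50%-breakdown guarantee is an asymptotic-in-precision property, and with
ratio noise comparable to the pleiotropic shift both estimators blur —
the experiment is designed where the guarantee is observable. SIMEX
Monte-Carlo checks use reduced `b_reps` for speed; the default 1000 is
used for reported analyses.

## Known limitations

- The packaged instrument tables carry betas rounded to 3 decimals. Most
  headline quantities are insensitive to this, but two are not: the
  random-effects IVW p-value recomputes as ≈ 0.17 and the Egger slope OR
  as ≈ 1.22, each a little away from the originally reported values
  (0.14, 1.19); and the HPMA 95% region, whose $\exp(-Q_S/2)$ weights are
  the most rounding-sensitive quantity in the package, recomputes wider
  (≈ 0.65–1.05 as ORs) than originally reported (0.71–0.96) while the mode
  agrees. The tests assert these quantities at tolerances the input
  precision supports instead of pretending to more.
- The packaged outcome table does not record non-effect alleles or
  outcome-side allele frequencies, so strand verification for the example
  runs in "unverified" mode, and the proxy rule's allele mapping is a
  synthetic placeholder.
- MR-Egger p-values use the normal, not t, distribution; with few
  instruments they are mildly anti-conservative.
- HPMA is exhaustive-enumeration only; large instrument sets need a
  different tool.
- Multi-outcome screening (`screen_outcomes()`) reproduces the analysis
  *layout* for risk-factor panels; applying it to real consortium GWAS
  requires the user to supply those tables.

## Interface notes

The package is function-first in the style of R modelling packages: the
analyst works with `read_associations()` → `harmonise()` → `mr_fit()` (or
the `mr_study()` orchestrator, which adds leave-one-out, diagnostics,
optional outcome screening and `write_mr_report()` for TSV/JSON output).
The fitted object supports `print`, `summary`, `coef`, `confint`, `plot`
(forest), `residuals` (signed root-Q contributions) and `simulate`
(parametric studies from the fitted design). Reports round ORs to 2
decimals and p-values to 2 significant figures for display while the JSON
keeps full precision; two runs with the same configuration and seed
produce byte-identical reports.
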