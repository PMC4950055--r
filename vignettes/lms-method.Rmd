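---
title: "Building birth-weight centile charts with the LMS method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building birth-weight centile charts with the LMS method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmschart)
```

## The problem and the model

Cross-sectional birth weights by gestational age are the standard proxy
for intrauterine growth in late pregnancy. A reference chart summarises
them as smooth centile curves; for infants with Down syndrome such a
chart matters clinically because their gestational-age distribution
peaks at 38 weeks and their weight falls increasingly below that of
unaffected babies after that age.

The LMS method represents the weight distribution at gestation $t$ by
three curves: the Box–Cox power $L(t)$ (skewness), the median $M(t)$
and the coefficient of variation $S(t)$. Under the
Box–Cox–Cole–Green (BCCG) distribution,

$$z \;=\; \frac{(y/\mu)^{L(t)} - 1}{L(t)\,S(t)} \sim N(0,1),
\qquad \log \mu = \log M(t) + \delta\,[\text{female}],$$

with the $L \to 0$ limit $z = \log(y/\mu)/S(t)$. Centiles follow from
$C = M\,(1 + L S z)^{1/L}$; chart lines are placed at
$z \in \{0, \pm\tfrac23, \pm\tfrac43, \pm 2\}$ and labelled as the
approximate 50th, 25th/75th, 9th/91st and 2nd/98th centiles. The labels
map to these exact $z$ values, not to `qnorm(0.02)` etc.: the
two-thirds-SD spacing defines the lines. The log link makes the sex
offset $\delta$ a constant *percentage* difference in the median,
reported as $100(1 - e^{\delta})$; $L$ and $S$ are pooled across sexes.

Two deliberate simplifications of the BCCG density: the positive-support
truncation factor $\Phi(1/(L S))$ is omitted (for $S \le 0.27$, as in
weight-for-gestation charts, the correction is below $10^{-8}$, and the
classical LMS formulation ignores it), and $|L| < 10^{-8}$ switches to
the lognormal-limit branch for numerical stability (fitted $L$ passes
through zero near 29–30 weeks on these data).

## Estimation

`fit_lms()` maximises the BCCG log-likelihood of the records penalized
by curvature (integrated squared second difference) penalties on
$L(t)$, $\log M(t)$ and $\log S(t)$:

* **Basis.** Cubic B-splines on equally spaced knots across the fit
  window (default 28–43 completed weeks; at most 10 basis functions,
  fewer if the data span fewer weeks). The second-difference penalty on
  the coefficients leaves straight lines unpenalized, so a penalized
  curve cannot drop below 2 effective degrees of freedom (edf); an edf
  of exactly 1 is implemented as a true constant (single intercept,
  no penalty).
* **Smoothness.** Each curve's penalty weight $\lambda$ is chosen by
  root-finding so that the trace of its hat matrix matches the
  configured edf. The edf is computed from the eigenvalues of the
  penalty whitened by the Cholesky factor of the weighted normal
  matrix, $\mathrm{edf}(\lambda)=\sum_k 1/(1+\lambda e_k)$, which is
  stable at any $\lambda$ (a direct solve degenerates once
  $\lambda P$ swamps $B'WB$). Defaults are edf 4/6/4 for $L/M/S$:
  enough for the published shapes ($L$ runs $-0.12$ to $1.02$; $S$
  dips at 38–40 weeks) while keeping roughly one effective parameter
  per two weeks of data. They are exposed in `fit_config()`.
* **Backfitting.** Each outer sweep gives every curve one penalized
  Fisher-scoring step holding the others fixed (expected per-record
  information: $1/S^2 + 2L^2$ for $\log\mu$, $2$ for $\log S$,
  $7S^2/4$ for $L$), then updates $\delta$ in closed form from the
  median score over female records. A step-halving safeguard accepts a
  block update only if the penalized log-likelihood does not decrease,
  so the objective is monotone within a cycle — an invariant the test
  suite asserts. Two cycles are run, re-matching $\lambda$ to the edf
  target at the start of each (weights change as the fit moves, and
  re-matching mid-iteration would change the objective being
  monitored). Convergence is a relative penalized log-likelihood
  change below `tolerance` (default $10^{-7}$); non-convergence is
  flagged on the returned object, not raised.
* **Starting values.** $L \equiv 1$; $\log M$ from a lightly penalized
  fit to weekly log-medians (girls pre-scaled by the raw sex
  log-median difference, which also initialises $\delta$); $\log S$
  from weekly $(\mathrm{IQR}/1.349)/\mathrm{median}$, clamped to
  $[0.01, 1]$. All are scale-free and robust; the fit itself is
  deterministic.
* **$SE(\delta)$** comes from inverting the joint expected information
  of the $M$-curve coefficients and $\delta$ (the penalty included),
  which accounts for the leakage between the female offset and the
  median curve; cross-information with $L$ and $S$ is neglected, as in
  the classical LMS scheme.
* **Window.** Records outside the fit window are excluded, never
  clamped; tables are reported from a narrower window (default 30–42
  weeks) than the fit (28–43) so the boundary weeks support the curves
  without being published.

With `edf = 1` on all curves and one sex the procedure reduces to a
plain three-parameter BCCG maximum-likelihood fit; the tests verify
agreement with an independent `optim()` fit of the same likelihood.

## The synthetic register

No individual-level register of Down syndrome births is public, so
`simulate_register()` provides a generative twin defined by
`simulation_config()`. Its defaults are the study conditions of the
England & Wales reference: exactly the published per-(sex, week) counts
(8,825 live births, 4,760 boys and 4,065 girls, weeks 28–43), weights
drawn from the published LMS parameters (standard-normal $z$, redrawn
on the negligible event $1 + LSz \le 0$ to preserve the BCCG shape),
birth years uniform on 1989–2011, no secular trend, no missingness, no
contamination. Counts are deterministic rather than multinomial so
that selection-flow totals are exactly assertable. Dials exist for a
linear trend in grams per year (additive on the final weight, since
that is the scale on which secular trends in birth weight are
reported), logistic weight-missingness in gestation (anchored at the
modal week 38), missing-at-random gestation, and contaminating
non-live or non-free-trisomy records that the selection stage must
remove. Simulated stillbirths are shifted by a configurable offset
(default −150 g): the true stillbirth deficit is unpublished, so this
knob is a placeholder, not a claim.

What the generator does *not* emulate: digit preference in recorded
weights, gestational-age misreporting, heart-anomaly substructure,
maternal covariates, or any termination-specific gestation profile.
Passing tests therefore demonstrate that the estimation machinery
recovers known truth under the model's own assumptions — not that the
model is robust to the artefacts of real register data.

## Analysis pipeline

`run_pipeline()` chains the published analysis: staged record selection
(outcome → karyotype → completeness → gestation window, in that fixed
order so each exclusion is charged to one stage), LMS fit, parameter
and centile tables, the constant percentage sex difference with a
normal-theory 95% CI, modal gestation (ties broken toward the lower
week), a secular-trend regression of SD score on birth year, a
logistic regression of weight-missingness on gestation (Wald test, as
standard GLM output reports), and an optional centile-by-centile
comparison against an external reference chart supplied as an LMS
table.

Two conversions deserve a note. The trend is estimated in SD-score
units and converted to grams per year by multiplying by $M \cdot S$
(an approximate SD in grams) at the records' modal week, averaged over
sexes — the published grams-per-year figure does not state its
conversion, so both scales are returned. And the comparison operation
is exact arithmetic on two LMS tables; the published median shortfalls
against the national all-births chart require that chart's parameters,
which are not bundled here, so the operation is verified by algebraic
properties (self-comparison is zero, a shifted chart differs by
exactly the shift, swapping charts negates the differences) rather
than by asserting those figures.

## Numerical choices and edge cases

* Centile tables round half away from zero to integer grams, matching
  printed chart tables; all internal arithmetic is unrounded.
  `evaluate_model()` rounds $L$ to two decimals and $S$ to three by
  default (the precision of published parameter tables); pass
  `digits = NULL` for full precision.
* `interpolate_lms()` is linear in $(L, \log M, \log S)$ between
  integer weeks: positivity-preserving and consistent with the log
  link.
* Degenerate inputs error early with identities attached: gap weeks in
  an LMS table, non-overlapping charts, all-equal birth years,
  single-state missingness, fewer than 50 usable records, or an edf
  request the week span cannot support.
* File formats are plain text: record CSV and LMS/centile TSV with
  empty-string missing values and a stable row order (week ascending,
  male before female), round-tripping exactly.

## Problem sizes

The bundled tests fit the full 8,825-record register in well under a
second, run 20 replicate register fits for the parameter-recovery
check, 100 replicates at one-tenth scale for secular-trend CI
coverage, and 200 for the missingness type-I error; the whole suite
completes in a few seconds on one core. These sizes were chosen to
give Monte-Carlo error comfortably inside the asserted tolerances.

## Known limitations

* Exact numerical replication of the published smoothed parameter
  table from raw data is impossible in principle: the original fit's
  smoothing degrees of freedom and convergence settings are unstated
  and the register is not public. Recovery is therefore demonstrated
  on synthetic registers with known truth.
* The four-parameter BCT/BCPE extensions (modelling kurtosis) are out
  of scope, as are charts for measurements other than
  weight-for-gestation and covariates other than sex and gestation.
* Model selection over edf grids is not automated; the edf knobs are
  exposed and the realized edf is reported on the fitted object.
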