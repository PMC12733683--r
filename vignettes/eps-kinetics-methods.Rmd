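---
title: "Methods: growth and product-formation kinetics in epskinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth and product-formation kinetics in epskinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epskinetics)
```

## The models

Batch growth of a yeast culture is described by the logistic equation,
$dX/dt = \mu_{max}(1 - X/X_{max})X$, whose solution the package evaluates
in the overflow-safe form
$X(t) = X_{max}\,/\,(1 + \tfrac{X_{max}-X_0}{X_0}e^{-\mu_{max}t})$.
The model assumes a single autocatalytic population with density-limited
growth: no lag phase, no death phase, no substrate term. `X` is a generic
biomass concentration; fitting OD600 readings directly is permitted and
common — the parameters are then in OD-equivalent units, and `μ_max` is
unaffected because it is a ratio of rates. No OD-to-dry-weight conversion
is applied or assumed.

Product formation follows the Luedeking–Piret law,
$dP/dt = \alpha X + \beta\,dX/dt$: `β dX/dt` is the growth-associated
synthesis rate and `α X` the non-growth-associated one. Along the logistic
trajectory the law integrates exactly to

$$P(t) = P_0 + \beta\,(X(t) - X_0) +
  \alpha\frac{X_{max}}{\mu_{max}}\ln D(t), \qquad
  D(t) = 1 - \frac{X_0}{X_{max}}(1 - e^{\mu_{max}t}),$$

using $\int_0^t X\,ds = (X_{max}/\mu_{max})\ln D(t)$.

**The α/β labelling.** Integrated forms of this model circulate in the
literature with the coefficient roles exchanged — the first coefficient on
the $(X - X_0)$ term and the second on the log term, which corresponds to
the rate law $dP/dt = \alpha\,dX/dt + \beta X$. The package fixes the
convention at the rate law — α multiplies biomass, β multiplies the growth
rate, matching the verbal definitions of "non-growth-associated" and
"growth-associated" — and derives the integral consistently. The two
parameterisations span the same model family; the test suite asserts the
exchange identity explicitly so the correspondence is never ambiguous.

Derived quantities: the specific production rate
$q_P(t) = (dP/dt)/X = \alpha + \beta\mu_{max}(1 - X(t)/X_{max})$ is
non-increasing whenever $\alpha,\beta \ge 0$, so its maximum over a batch
is the $t = 0$ value $q_{P,max} = \alpha + \beta\mu_{max}(1 - X_0/X_{max})$.
If a fitted coefficient is negative, monotonicity is not guaranteed and
`max_specific_production_rate()` falls back to a dense-grid search
(step 0.01 h over 0–120 h) and flags the result.

## Two-stage fitting

`fit_logistic()` and `fit_luedeking_piret()` implement sequential
estimation: biomass first, then product with the growth parameters held
fixed. Sequential fitting mirrors how these models are normally reported
(growth kinetics stand on their own, product kinetics are conditional on
them) and keeps each stage identifiable; a joint fit would let product
noise leak into the growth parameters.

Both stages minimise an unweighted residual sum of squares over the pooled
replicate observations with Levenberg–Marquardt (minpack.lm), relative
objective-decrease tolerance `1e-10`, at most 10,000 evaluations.
Replicates are pooled as independent observations rather than averaged —
averaging first discards within-time variance and changes the effective
weighting — but `average_replicates = TRUE` is available.

Starting values are data-driven and deterministic: `X0` from the earliest
observed biomass, `Xmax` from 1.05 × the maximum, `μ_max` from the
log-linear slope over the first three time points; for stage 2, `P0` from
the earliest product and (α, β) from ordinary least squares on the
finite-differenced rate form. A fixed table of multiplicative
perturbations of that start (five starts in total) guards against local
minima without consuming any RNG, so fitting is bit-reproducible by
construction. Parameters are bounded below (`X0, Xmax, μ_max > 0`,
`P0 ≥ 0`); α and β are unbounded, and negative estimates are kept and
flagged rather than clipped — clipping would bias the derived rates.

Goodness of fit is the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the observed mean.
(Reports of this quantity as a "correlation coefficient" are common in the
fermentation literature; the coefficient of determination is what is
actually computed here, as it is the standard fit-quality meaning.) A
constant response makes $R^2$ undefined; the logistic stage treats it as a
degenerate-data error, while the product stage accepts it — a product stuck
at $P_0$ is exactly the null-production model α = β = 0 — and returns
`NA` with a `constant_response` flag.

Cultures under strong stress can lose biomass late in the batch, which a
monotone logistic cannot represent. The fitter offers
`truncate_at_peak = TRUE` (drop observations after the time of maximum
mean biomass; off by default) and flags systematic late-time residuals
when the final time point sits far below the fitted curve.

## Classifying growth association

For exact parameter values, `classify_association()` thresholds
magnitudes at `tol` (default `1e-6` in the coefficient's own units). For a
*fitted* model this is not meaningful: an estimator of a truly-zero
coefficient is almost never exactly zero, so magnitude alone would call
every noisy fit "mixed". The `lp_fit` method therefore requires a
coefficient to be statistically distinguishable from zero:
$|\hat\theta| > \max(tol,\; t_{df,conf}\,\widehat{se}(\hat\theta))$.

Because measurement noise is multiplicative (constant CV), residual
variance grows with the curve, and the usual homoscedastic standard errors
from the least-squares fit are too small — they over-call small
coefficients as nonzero. The integrated product model is linear in
$(P_0, \alpha, \beta)$, so the package computes heteroscedasticity-robust
sandwich standard errors with the HC3 leverage correction, appropriate for
the small per-condition samples (24 observations), and compares against a
t quantile on the residual degrees of freedom. The default confidence
level is 0.999, deliberately stringent: when a term contributes nothing
the parsimonious label should win, and genuinely active terms in these
designs sit an order of magnitude above any conventional cutoff, so the
stringency costs no sensitivity.

A consequence worth knowing: classification reports what the *data can
support*, not the generating truth. Under the default heat-stress
scenario the non-growth-associated term dominates cumulative production so
thoroughly that β's contribution is within noise, and the honest label is
`non_growth_associated` even though the generating β is 0.5. The normal
scenario, where both terms contribute comparably, classifies as `mixed`
essentially always.

## Bootstrap uncertainty

`bootstrap_ci()` resamples replicate-time cases with replacement, refits
both stages per resample, and returns percentile intervals (default level
0.95), with failed resamples dropped and reported as a failure fraction.
It is seed-deterministic. The test suite checks interval behaviour at the
edges (zero width on exact data) and empirical coverage of `μ_max` across
100 simulated experiments with 100 resamples each — a problem size chosen
to give a stable coverage estimate while keeping the suite quick.

## The synthetic-data generator

`default_scenarios()` encodes the two emulated culture conditions of a
two-temperature EPS fermentation study: sampling at
6, 12, 24, 36, 48, 72, 96, 120 h, three replicates, and maximum specific
growth rates of 0.33528 h⁻¹ (heat stress, 30 °C) and 0.13286 h⁻¹ (optimal
temperature, 15 °C). The heat-stress α is constructed so that
$q_{P,max}$ equals 0.87670 h⁻¹ exactly, by inverting
$q_{P,max} = \alpha + \beta\mu_{max}(1 - X_0/X_{max})$.

The remaining generator parameters are package defaults, chosen once for
realism and well-conditioned fits rather than to reproduce any particular
dataset: `X0 = 0.1`, `Xmax = 6` (heat) and `10` (normal) — final biomass
is higher at the optimal temperature, as growth is inhibited under heat
stress — `P0 = 0.05` g/L, `β = 0.5`, and for the normal condition
`α = 0.05` h⁻¹ (an order of magnitude below the heat-stress value,
reflecting weak stress-driven induction). Measurement noise is
multiplicative Gaussian with CV 3%, truncated below at zero — the error
structure of OD and colorimetric assays, whose dispersion scales with the
signal. The true experimental noise magnitude is not known from published
figures alone; 3% is an assumption surfaced as the `noise_cv` parameter.

Sub-seeds for multi-condition studies are derived from the base seed and
the condition label by a 31-adic string hash folded into $[1, 2^{31}-2]$,
so adding a scenario never perturbs the draws of existing ones.

What the generator deliberately does **not** emulate: the late-time
biomass decline seen in stressed cultures after ~48 h (a logistic cannot
produce it; an optional exponential die-off mode exists solely to exercise
`truncate_at_peak`), lag phases, substrate depletion, autocorrelated or
additive error components, and plate-position or batch effects. Passing
recovery tests on these simulations therefore demonstrates that the
estimation machinery is correct and well-calibrated under the stated
noise model — not that real OD curves satisfy the logistic assumptions.

## Numerical choices

- $X(t)$ uses the $e^{-\mu t}$ parameterisation; $\ln D(t)$ is computed as
  $\mu t + \mathrm{log1p}(r e^{-\mu t}) + \ln(X_0/X_{max})$ with
  $r = (X_{max}-X_0)/X_0$, so neither overflows for large $\mu t$.
- In double precision $X(t)$ saturates to exactly $X_{max}$ once
  $e^{-\mu t}$ underflows; strict monotonicity holds analytically but is
  asserted numerically only below that saturation.
- Multi-start selection is by lowest residual sum of squares among
  converged starts; non-convergence is reported through the `converged`
  field, never silently.
- Grid step for the non-monotone $q_P$ search is 0.01 h, well below any
  structure the model can express over a 120 h window.

## Problem sizes

The recovery experiments behind the test suite and `scripts/acceptance.R`
use 100 simulated experiments per condition (8 time points × 3 replicates
each) for parameter-recovery means, classification rates and the
$R^2 > 0.9$ fraction, and 100 × 100 resamples for bootstrap coverage —
sizes at which the Monte-Carlo error of the summaries is a few tenths of a
percent, comfortably inside the tolerances being checked.

## Known limitations

- No substrate balance, temperature-dependent parameter model (Arrhenius /
  Ratkowsky), or alternative growth laws (Gompertz, Baranyi); the model
  family is fixed.
- Sequential fitting conditions stage 2 on stage-1 point estimates;
  growth-parameter uncertainty is propagated only through the bootstrap,
  not analytically.
- Unweighted least squares is the default even though the noise is
  multiplicative; at CV 3% the efficiency loss is negligible, but for much
  noisier data a variance-stabilising transform would be preferable.
- β is weakly identified whenever cumulative production is dominated by
  the α term (strong producers at high biomass); its interval and the
  classification reflect that honestly rather than hiding it.
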