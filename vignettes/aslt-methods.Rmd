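---
title: "Accelerated shelf-life testing of oxidisable foods: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated shelf-life testing of oxidisable foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxshelf)
```

## The problem

Fat-based products such as chocolate spreads fail by lipid oxidation long
before they fail microbiologically. The primary oxidation products are
hydroperoxides, quantified as the peroxide value (PV, meq active O2 per kg
oil); secondary aldehydes are tracked by the para-anisidine value (p-AnV),
and the two are combined in TOTOX = 2 PV + p-AnV. Waiting for a product to
go rancid at ambient temperature takes most of a year, so accelerated
shelf-life testing (ASLT) stores samples at several elevated temperatures,
fits degradation kinetics at each, extrapolates the rate to market
temperature with the Arrhenius law, and converts the extrapolated rate into
a shelf-life. `oxshelf` implements that chain end to end, with an S3 model
object (`aslt()`) orchestrating the stages and every stage also exposed as
a standalone function.

## Kinetic model and order selection

At constant temperature the index A is assumed to follow `dA/dt = k A^n`
with reaction order n in {0, 1, 2}. Each order has a linearising transform
— A, ln A, or 1/A against time — and `fit_order()` runs ordinary least
squares on that scale. `select_order()` compares the three transformed-scale
R² values and keeps the largest, breaking near-ties (difference below
1e-9) toward the lower order. Comparing R² across different response
transforms is statistically informal, because the residual scales differ;
it is nevertheless the standard screening procedure in food-stability work
and is retained deliberately, with this caveat. Day-0 observations are
included in every fit (no exclusion rule is justified by the data), and a
non-positive index value aborts the order-1/2 fits with the offending day
named, rather than silently dropping points.

For hydroperoxide accumulation in low-moisture spreads the first-order
model wins at essentially every temperature, and all downstream stages
(Arrhenius, shelf-life, thermodynamics) use the first-order rate constant
k in 1/day.

## Arrhenius stage

Across temperatures, `k(T) = k0 exp(-Ea/(R T))`; `fit_arrhenius()` regresses
ln k on 1/T, so the slope is −Ea/R (in K) and the intercept ln k0. At least
three distinct temperatures are required — with two, the line is exact by
construction and carries no information about lack of fit. The activation
energy is reported in kJ/mol (an Arrhenius Ea carries no per-K unit, even
though stability papers sometimes print "kJ/mol K"), and the temperature
sensitivity is summarised by `Q10 = exp(10 Ea/(R T1 T2))`, conventionally
at the 303.15/313.15 K pair.

Two conventions deserve explanation because both are explicit, logged
parameters rather than hidden constants:

* **Gas constant.** The default is R = 8.314 J/(mol K). Published
  stability tables are sometimes accompanied by a misprinted constant
  (e.g. 8.318), while the tabulated activation energies themselves are
  consistent with 8.314; the constant is configurable through
  `physical_constants()` precisely so that such provenance questions can
  be audited numerically.
* **`kelvin_mode`.** Storage temperatures are Celsius-derived values
  ending in .15 K, but published spreadsheet analyses frequently truncate
  them to whole Kelvin (288, 293, ..., 323) and propagate the truncation
  through every formula — including the 1/T regression itself. The
  difference is small (fourth decimal of k) but visible at the precision
  the literature prints. `kelvin_mode = "exact"` is the scientific
  default; `"integer"` reproduces the truncating convention and is what
  the reference-table reproductions in the test suite use. The mode is
  recorded in every fit object and run log.

## Shelf-life

Under first-order growth, the time for the index to climb from its measured
initial value `a0` to the quality limit is `t = ln(a_limit/a0)/k`, with the
PV limit defaulting to 10 meq O2/kg — the conventional onset of rancidity
of the fat phase. `a0` is deliberately an explicit, measured input: the
regression intercept is *not* used as a stand-in, because intercepts absorb
lack of fit and do not generally reproduce published shelf-life values.
The consumer-facing figure adds the product's age when the trial started
(default 5 months) at 30 days per month: `total = age + days/30`.

Two known inconsistencies of the bundled reference tables are documented
rather than "fixed": the reference brand's printed 107.3-day shelf-life is
not reconcilable with its printed initial PV (4.9e-4) and rate constant
(0.1032 1/day), which give about 96 days under the first-order formula;
and its per-temperature rate rows at 303.15 and 313.15 K are identical — a
transcription duplicate, flagged in `spread_reference()$rates`, whose
consequences are visible in the published 313 K free-energy cell as well.

## Activation thermodynamics

From transition-state theory, `dG = -R T ln(k h/(kB T))`, `dH = Ea - R T`,
`dS = (dH - dG)/T`. The Eyring ratio `k h/(kB T)` is dimensionless only if
k is in 1/s; the food-stability literature routinely enters k in 1/day,
which shifts every dG by `R T ln(86400)` (≈27 kJ/mol here) and produces the
familiar 75–84 kJ/mol range for lipid oxidation. Because the shift is
common to all samples and temperatures, comparative conclusions are
unaffected; `gibbs_free_energy(..., time_unit =)` makes the choice
explicit, defaulting to the literature convention. Positive dG at these
magnitudes marks the activation step as non-spontaneous (endergonic);
dS is summarised across temperatures as mean ± sample standard deviation,
since it is nearly temperature-invariant when the Arrhenius model holds.
`dG = dH - T dS` holds to machine precision by construction.

## Synthetic trials: what they emulate, and what they do not

`trial_design()`/`generate_trial()` simulate the data structure the
analysis assumes: `PV(t) = a0 exp(k(T) t) exp(e)` with
`e ~ N(0, sigma^2)` i.i.d., k(T) Arrhenius-consistent, four storage
temperatures (288.15/303.15/313.15/323.15 K), the nine-day sampling
schedule 0, 1, 3, 5, 8, 12, 16, 20, 31, and a flat p-AnV channel with
small noise (secondary oxidation barely moves over 31 days in low-moisture
products). Noise is multiplicative lognormal, not additive Gaussian, for
two reasons: simulated values stay strictly positive (so the log transform
never fails), and the ln-scale regression is then the correctly specified
estimator. The default sigma = 0.1 puts first-order R² in the 0.82–0.95
band typical of real PV trials. Default formulation parameters (a0 between
4.9e-4 and 9.0e-4 meq O2/kg, Ea 11.3–14.5 kJ/mol, k about 0.10–0.16 1/day
at the 293.15 K reference) are taken from the bundled reference study;
where an initial PV was not published (four of the six formulations) a
mid-range stand-in of 7.0e-4 is used and flagged `measured = FALSE`.

The generator does **not** model induction/lag phases, antioxidant
depletion, water-activity coupling, or the phase change of cocoa butter
near 306 K that perturbs real rates above that temperature. Passing the
recovery tests therefore demonstrates that the estimation chain is
self-consistent and precise under its own assumptions — not that those
assumptions hold for any particular real product.

## Numerical choices and problem sizes

* R² is computed as the squared Pearson correlation on the transformed
  scale (identical to the regression R² for a simple linear fit, without
  the perfect-fit warnings `summary.lm` emits on noiseless data); a
  zero-variance response returns R² = 0.
* Back-calculated hydroperoxide concentrations below zero are clamped to
  zero with a warning — blanks can exceed weak samples — except for
  negatives below 1e-10, which are rounding dust.
* The p-AnV formula defaults to the AOCS Cd 18-90 convention
  `25 (1.2 A_after - A_before)/m`; a "verbatim" mode reproducing the
  sign-flipped form found in some method sections is available for audit
  and records its mode in the result, since it yields negative values for
  any oxidising sample.
* Order-selection ties go to the lower order (parsimony); infeasible
  transforms are excluded and recorded, not silently skipped.
* Validation experiments use 200 replicates of four-temperature,
  nine-day trials — large enough that median recovery statistics are
  stable to a percent or two, and small enough that the whole suite runs
  in well under a minute. With the default noise, the full pipeline
  recovers Ea with a median relative error around 4%, and selects the
  first order in over 95% of series; when the same noise is instead
  applied directly to four k values, sampling theory caps the achievable
  Ea precision at a median error of about 17%, and the unit tests assert
  that theoretical precision rather than an arbitrary target.

## Limitations

Everything downstream of the kinetic stage inherits the assumptions of
linearised least squares and of Arrhenius behaviour over a 35 K span;
products that change phase inside the tested range (as chocolate spreads
do) violate the latter in ways the model can only average over. The
shelf-life extrapolation is a first-order point estimate with no interval:
the pipeline propagates no uncertainty from the kinetic fits, matching the
conventional presentation, and the recovery simulations are the honest
substitute for error bars. Dimension-carrying conventions (integer Kelvin,
k in 1/day inside the Eyring ratio) are reproduced for comparability with
the literature and are clearly flagged; use `kelvin_mode = "exact"` and
`time_unit = "second"` for dimensionally strict results.

## A worked run

```{r}
design <- trial_design(noise_sigma = 0.1, seed = 11)
trial <- generate_trial(design)
fit <- aslt(trial)
fit
predict(fit, 293.15)
```
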