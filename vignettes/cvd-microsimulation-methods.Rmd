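---
title: "Methods: counterfactual CVD microsimulation on synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual CVD microsimulation on synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvdmicrosim` implements an open-cohort, discrete-time microsimulation of
coronary heart disease (CHD) and stroke whose purpose is counterfactual
attribution: comparing a base-case that reproduces observed risk-factor
trends against scenarios in which selected exposure distributions are frozen
at a baseline year. This vignette documents the model, its assumptions, the
parameters that matter, and the numerical choices made where the design was
genuinely open. Everything here describes what the package computes; the
test suite and `scripts/acceptance.R` are the quantitative record.

## The synthetic world

No restricted survey, registry or vital-statistics data ship with the
package. Instead the `synthetic_data` generators produce every input from a
preset with known ground truth, so the whole pipeline can be validated
end-to-end against quantities that are true by construction.

The `japan_core` preset anchors its trends to published national figures
for Japan, 2001–2019: mean systolic blood pressure 140.1/135.3 mmHg
(men/women) in 2001 falling to 133.4/128.1; current-smoking prevalence
49.3%/14.1% falling by 18.4/6.8 percentage points; population totals
(thousands) 39,989 to 44,256 for men and 43,766 to 48,500 for women; crude
CHD incidence per 100,000 of 340 to 420 (men) and 190 to 300 (women), crude
stroke incidence 390 to 330 and 280 to 250; crude CHD mortality 90 to 83 and
65 to 45, crude stroke mortality 150 to 100 and 140 to 85; and an exchange
rate of 10.56 USD per 1000 JPY. Quantities the anchors do not pin down
(LDL-c, HbA1c, BMI, activity and diet trends; dispersions; age gradients;
relative risks; utility norms) were chosen once at values a practitioner
would call realistic for this population — e.g. a slight LDL-c and HbA1c
decline, BMI rising in men, activity and fruit/vegetable intake declining,
RR 1.5/1.8 per 20 mmHg SBP for CHD/stroke, current-smoker RRs of 2.0/1.9 —
and are configurable but deliberately not tuned thereafter. `flat_null` is
the global null: every trend time-constant and every RR equal to 1, so all
counterfactuals coincide with the base-case.

What the generator emulates: linear-in-year location trends between the two
anchor years (extended linearly before 2001 for the back-projected survey
years 1995–2000), age gradients centred at the population's reference age,
skewed positive-support distributions, Gaussian-copula dependence between
factors, Gompertz total mortality, and age curves for incidence
(exponential up to a peak age, default 85) and initial prevalence
(logistic in age). What it does not emulate: survey design effects and
nonresponse, measurement-device changes, cohort (birth-year) effects
distinct from age and period, migration, and secular change in case
fatality beyond the calibrated trends. Passing tests therefore demonstrate
that the estimator machinery is correct and internally consistent — not
that any particular real-world dataset would yield the same attribution.

Two internal-consistency devices matter. First, the population table is
built by an exact survival recursion — N(a+1, y+1) = N(a, y)(1 − q(a, s, y))
with 30-year-old entrants injected to follow the anchored totals — and the
epidemiological tables decompose that same q(a, s, y) into disease mortality
(a per-sex/year share of total mortality, tapering beyond age 85) plus
other-cause mortality. Second, prevalence for years after 2001 is
constructed forward from the model's own dynamics (2001 initial curve,
then incidence minus case fatality and other-cause deaths), and case
fatality is defined against prevalence *including same-year incident cases*
because the engine exposes those to that year's fatality. Without these two
choices the inputs would be mutually inconsistent and calibration would
distort the age structure of deaths.

## Exposure models

`fit_factor_model()` fits, per sex, a location surface over a cubic
polynomial in age and a linear term in calendar year — a deliberately light
distributional-regression basis that matches the generator's two-anchor
trends and keeps the dependency surface small. Families: shifted log-normal
(SBP, LDL-c, BMI; fixed support shifts 60/30/10), gamma with constant shape
(HbA1c, activity, fruit/vegetable), multinomial logit for smoking status and
a unit-shifted negative binomial for cigarettes/day among current smokers.
Fitting goes through `stats::lm` on the log scale, `stats::glm` with a
Gamma log link, `nnet::multinom` and `MASS::glm.nb`. Scale parameters are
constant per sex; evaluation outside the fitted age/year ranges is clamped
to the boundary, never extrapolated.

Individuals carry one lifetime rank per factor (plus one for
cigarettes/day), drawn from a Gaussian copula whose correlation matrix is
estimated from the survey by normal-scores correlation. Rank persistence —
no rank drift over the life course — is the simplest mechanism consistent
with individual-level life-course profiles, and the cross-factor copula
stands in for explicit covariate conditioning of one factor on another
(a single mechanism that achieves the observed clustering; explicit
conditioning is an extension point).

Smoking is one-way: never → current → past. A person's ever-smoker band is
fixed at entry from the fitted status probabilities, and a current smoker
quits exactly when their rank no longer exceeds the declining
current-smoking threshold; initiation at ages 30+ is not modelled. For
lagged (pre-entry) years the memoryless band rule is applied at the lagged
age and year.

Exposure lags default to 5 years for SBP, LDL-c, HbA1c, BMI, activity and
diet and 10 years for smoking — configurable stand-ins, capped at 10.

`freeze_at_year(spec, y0)` makes a counterfactual spec evaluate its
parameter surfaces at `min(year, y0)`: years at or after the baseline are
pinned, while earlier (lagged, back-projected) history passes through
unchanged. The pass-through is essential: pre-baseline exposure history is
shared between scenarios, so paired differences accrue only from
post-baseline divergence — freezing the pre-2001 years too would
manufacture spurious differences in the lagged early simulation years and
flip the sign logic of the long-lag (smoking) counterfactual. Freezing is
idempotent and leaves age and sex dependence untouched.

## Disease dynamics

Within a simulated year, events resolve in a fixed order chosen for
reproducibility under common random numbers: (1) first-ever CHD draw for
the CHD-free; (2) first-ever stroke draw for the stroke-free; (3) one
competing-risk death draw in which a single uniform is partitioned into
CHD-death, stroke-death and other-death intervals (case fatality applies to
prevalent cases including same-year incident ones; hazards are rescaled if
they sum above 1). Survivors accrue one case-year per prevalent disease.
Individual probabilities are clipped to [0, 0.99].

Relative risks are log-linear per unit, RR^((x − ref)/unit), floored at 1
below the reference except for the protective factors (activity,
fruit/vegetable intake), which carry RR < 1 per unit and are not floored.
Smoking is categorical (never = 1, past, current), with an optional
(cigarettes/20)^γ scaling that defaults to off. Risks combine
multiplicatively across the seven factors.

The stratum-mean normalisation p_i = p(a, s, y) · π_i / ⟨π⟩ preserves the
calibrated stratum rate exactly in the base-case. In counterfactuals the
denominator ⟨π⟩ remains the *base-case* stratum mean (evaluated under the
unfrozen models over the concurrent at-risk set), so counterfactual rate
changes flow only through the shifted risk-factor distributions; letting
each scenario renormalise against itself would absorb the shift and void
the comparison.

Calibration is iterative proportional fitting of multiplicative scalers per
(measure, sex, year): simulate the base-case, compare expected crude
incidence, disease mortality and other-cause mortality with the targets
implied by the input tables, multiply by target/simulated, repeat until the
maximum relative error is ≤ 2% (a balance of runtime against the 5%
internal-validation criterion) or 10 sweeps (warning, not fatal). The
scalers are computed once on the base-case and reused for counterfactuals
and for every outer uncertainty draw: epi-rate draws scale targets and
applied rates by the same multiplier, and RR draws are absorbed by the
mean-preserving normalisation, so the calibration fixed point is
approximately draw-invariant. Calibration is run at the same cohort size
and seed as the reported run, making the residuals directly meaningful for
that run.

### Crude-rate estimator

Reported rates (calibration, internal validation, the acceptance script)
use the conditional-expectation estimator Σ w_i p_i / Σ w_i rather than the
realised Bernoulli count — an unbiased, strictly lower-variance
(Rao–Blackwellised) estimator of the same quantity. Realised draws still
drive every state transition and all CPP/CYPP/DPP accounting; the
difference tables carry both realised (`cpp_*`) and expected (`cpp_*_exp`)
case columns.

## Common random numbers

Every stochastic decision is indexed, not sequential: the uniform deciding
(person id, year, event type) is generated from a seed derived
deterministically from those labels over the full id universe, which is
itself scenario-invariant because cohort entry depends only on the
population-count table. Consequently scenario differences are exactly zero
whenever frozen distributions coincide with base-case distributions, and
the `flat_null` preset yields identical event sequences in every scenario.
(Net QALYs under `flat_null` differ at the ~1e-5 relative level because the
diabetes disutility proxy — current-year HbA1c above 6.5% — responds to the
frozen HbA1c surface, whose fitted year slope is only statistically zero.)

## Health economics

QALY weights are max(0, U(agegroup, sex) − Σ disutilities) with additive
disutilities for prevalent CHD, stroke and proxied diabetes. Per-case-year
direct costs are derived by apportioning the preset's 2019 national cost
anchors over the 2019 prevalent case-years implied by the inputs (the same
per-case-year cost applies in all years; direct costs carry no
uncertainty). Indirect costs split into informal care (all ages, 40%) and
productivity (below age 65 only, 60%). All amounts are carried in JPY and
converted to USD (10.56 per 1000 JPY) only at reporting time; nothing is
discounted. The printed JPY/USD cell-pair consistency check is implemented
as rounding-interval overlap, since two 2-significant-figure cells need
only be roundings of a common unrounded value.

## Second-order Monte Carlo

Outer draws realise relative risks log-normally around their point
estimates (tabulated log-scale SEs), one log-normal multiplier per
(measure, disease, sex) for the epidemiological rates — moving rates
coherently across ages and years, as source-study uncertainty does — and
log-normal disutility and indirect-cost draws. One draw serves all nine
scenarios of an iteration. Summaries are empirical 2.5/50/97.5 percentiles
with the type-7 (linear interpolation) convention. Exposure-model
coefficient uncertainty is *not* resampled — a documented limitation; the
varied set is configurable through the input tables' interval columns.

## Problem sizes and numerical choices

Default desk-scale profile: 20 outer draws × 50,000 synthetic individuals,
nine scenarios, 2001–2019 — sized so a full ensemble completes comfortably
on a single CPU, with the original-scale 200 × 400,000 available by
argument. The test suite uses 8,000 survey records/year, 20,000-person
cohorts for scenario comparisons and 50,000 for the calibrated
reference run; sub-percent crude-rate agreement at these sizes is driven by
the expected-value estimator, not cohort size. Other numerical choices:
largest-remainder allocation of persons to (age, sex) strata with weights
summing exactly to the stratum counts; ranks clamped to (1e-9, 1 − 1e-9);
degenerate zero-dispersion families collapse exactly onto their location
surface; zero-width uncertainty intervals reproduce point estimates
exactly; empty normalisation strata fall back to the unscaled stratum rate.

## Known limitations

First-ever events only — no recurrence, severity grading or CHD/stroke
subtypes; no heart failure. Diabetes enters only as a utility decrement via
the HbA1c proxy. The population-structure check is read at desk scale as
band *shares* (within one percentage point per 5-year band): at 20,000–
50,000 individuals the realised mortality noise in elderly bands exceeds a
1% relative tolerance for any correct engine. Comorbidity clustering
(shared latent ranks) makes simulated stroke prevalence at high ages drift
a few percent below the input tables — the per-year calibration absorbs the
level but not the full age pattern. Finally, the synthetic anchors make
single-factor contributions directionally faithful (positive for SBP,
smoking, LDL-c, HbA1c; negative for BMI, activity, diet) but their
magnitudes are properties of the preset, not estimates for any real
population.
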