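---
title: "Methods: synthetic cohorts, the lifetime microsimulation and the cost-utility analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts, the lifetime microsimulation and the cost-utility analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dcea)
```

# Overview

`t2dcea` evaluates the cost-effectiveness of structured diabetes education
plus behavioural weight management (DEW) against standard diabetes
education alone (DE) in adults with recently diagnosed type 2 diabetes.
It has four layers:

1. a **synthetic cohort and trial generator**, replacing restricted
   participant-level data with draws that reproduce the published baseline
   moments and effect structure;
2. **trial-design and descriptive tools** — an ANCOVA-style sample-size
   calculation, categorical outcome summaries with unadjusted risk ratios,
   and the pattern-mixture delta adjustment for missing-data sensitivity;
3. a **within-trial (12-month) cost-utility analysis** with a
   nonparametric person-level bootstrap and acceptability curves;
4. a **lifetime annual-cycle microsimulation**: risk-factor trajectories
   with decaying intervention effects, configurable parametric risk
   equations with calibration, diabetes-remission medication offsets,
   discounted cost/QALY accrual, probabilistic sensitivity analysis and
   subgroup summaries.

This vignette records the modelling assumptions and every design decision
that was genuinely open, so the defaults can be audited and overridden.

# Synthetic cohort

Continuous risk factors are generated by a Gaussian copula: correlated
standard normals are pushed through each marginal's truncated-normal
quantile function. Two choices matter here.

**Moment matching under truncation.** Eligibility truncates several
marginals (BMI at 25 kg/m², age at 18 y, diabetes duration at 3 y).
Truncating a normal at its specified mean/SD would shift the realised
moments — a lower bound of 25 on a BMI of mean 34.6 (SD 6.8) inflates the
sample mean by about one unit. The generator therefore solves, per
variable, for the underlying normal parameters such that the *truncated*
distribution has exactly the requested mean and SD, so a user asking for
mean 34.6 gets a sample mean of 34.6. Infeasible requests (target mean
outside the bounds, or a mean/SD pair no truncated normal on those bounds
can achieve) raise a configuration error rather than silently drifting.

**Correlation structure.** The source publication reports only marginal
summaries (the underlying model population was supplemented from an
external primary-care database that is not available). The default
correlation matrix sets weight–BMI to 0.9, BMI–SBP to 0.2 and every other
pair to 0.1; all pairs are user-overridable, and a non-positive-semi-
definite override is rejected at specification time.

Discrete variables (sex, IMD quintile, diabetes-duration band, smoking and
treatment flags) are independent categorical draws at the published
frequencies. Smoking (15%), glucose-lowering medication (55%), statin
(55%) and antihypertensive (50%) prevalences are not published for this
cohort; the defaults are typical UK values for newly diagnosed type 2
diabetes and live in the configuration file.

The **synthetic trial** layer allocates 1:1 by permuted blocks of six
within sex × duration strata, mirrors the published arm differences at 6
and 12 months (weight −1.77 / −1.38 kg; HbA1c −1.83 / −0.84 mmol/mol) on
top of a common secular change (DE arm: −1.5 / −1.0 kg and −3 / −3
mmol/mol — modest regression toward better control after diagnosis, chosen
once as a realistic background), with individual change noise of SD 5 kg
and 9 mmol/mol. EQ-5D utilities are one minus a beta-distributed
disutility whose mean rises by 0.006 per BMI unit and 0.001 per mmol/mol
HbA1c (concentration parameter 20), using one latent quantile per person
so repeated measurements are correlated. Six-monthly healthcare costs are
gamma (mean £450, shape 2), with a −£100 per period arm effect so the
intervention arm is mildly cost-saving on healthcare use, matching the
direction of the trial's within-trial finding. Attrition (default 31%, the
trial's observed rate) is missing-completely-at-random by default; the
`mnar` option makes dropout increase with 12-month weight gain, preserving
the marginal rate, to exercise the pattern-mixture procedure. What passing
moment-recovery tests show is that the generator reproduces first and
second moments and frequencies — not the real data's higher-order
structure, item missingness patterns, or visit-time irregularity.

# Trial design calculations

The sample-size formula is the normal approximation for a two-arm
comparison of means with baseline adjustment, which deflates the follow-up
SD by $\sqrt{1-r^2}$:

$$ n_{\text{per group}} = \left\lceil 2\,(z_{1-\alpha/2}+z_{\text{power}})^2
   \left(\frac{\sigma\sqrt{1-r^2}}{\Delta}\right)^2 \right\rceil $$

The total is doubled, divided by $1-\text{attrition}$ and rounded up to an
even integer. With $\Delta=3$ mmol/mol, $\sigma=16$, $r=0.8$, 90% power,
5% two-sided alpha and 25% attrition this gives 576 (432 before attrition
inflation). Risk ratios are unadjusted ratios of arm proportions with the
usual log-scale delta-method interval; covariate-adjusted effect models
are deliberately out of scope (standard mixed-model machinery, not this
package's contribution). The delta adjustment multiplies *imputed* values
only by $1+f/100$; its exact inverse is $-100f/(100+f)$, which the test
suite uses as a round-trip identity.

# Within-trial cost-utility analysis

QALYs are trapezoidal areas under the utility measurements at 0, 6 and 12
months. Costs are healthcare use plus the per-person programme cost (£325
DEW; £158 DE in the mixed delivery scenario). The analysis is
complete-case by default with a mean-imputation switch; baseline-utility
regression adjustment is not applied (the published supplementary detail
specifying any adjustment is unavailable, so the package reports simple
arm-mean differences). Uncertainty comes from a paired nonparametric
bootstrap, resampling persons within arm (default 5,000 replicates,
seeded); the CEAC at threshold $\lambda$ is the fraction of replicates
with $\lambda\,\Delta\text{QALY}-\Delta\text{cost}>0$.

# Lifetime microsimulation

## Trajectories and intervention-effect decay

Each risk factor follows a common deterministic annual drift (defaults:
HbA1c +0.5 mmol/mol per year, reflecting progressive glycaemic
deterioration; BMI, SBP and cholesterol:HDL flat). The intervention arm's
HbA1c and BMI are offset from the common trajectory by a decaying effect:
the full 12-month effect at year 1, declining to exactly zero at 5 years
(HbA1c) and 10 years (BMI). The decline is linear by default — the
simplest shape consistent with fixed removal horizons — with an
exponential-to-zero alternative as a configuration option. Within the
first year the offset ramps linearly from zero so both arms share the
baseline state. Weight effects in kg convert to BMI units through a height
imputed from the cohort's mean weight and BMI (1.68 m). Effects enter as
additive offsets, not multiplicative factors; this is flagged as a choice
because the source model's internal convention is not published.

## Risk equations and calibration

The event engine is *coefficient-agnostic*: each outcome (MI, stroke,
congestive heart failure, IHD, amputation, blindness, foot ulcer, renal
failure, death) is a parametric annual hazard — exponential,
Weibull-in-duration, Gompertz-in-age or logistic — over named covariates,
with a calibration multiplier and statin/antihypertensive relative-risk
modifiers (applied to MI, stroke, CHF and mortality; other outcomes
default to RR 1). The shipped parameter file is **synthetic and
illustrative**: its coefficients were chosen once to give
epidemiologically plausible incidences for this population (≈1.4% annual
MI risk, ≈0.7% stroke, residual life expectancy ≈18 years at mean age 60)
and are clearly labelled non-proprietary; published coefficient sets can
be dropped in via the same file format.

Calibration bisects (on the log scale) the multiplier of one equation
until the simulated cumulative incidence over a horizon matches a target
(e.g. external trial data), within an absolute tolerance of 0.002 by
default, bounded in $[10^{-4}, 10^4]$. The same pre-drawn uniforms are
reused at every iteration (common random numbers), which makes incidence
monotone non-decreasing in the multiplier — the property that guarantees
bisection converges — and removes Monte-Carlo chatter between iterations.

Within each annual cycle outcomes are drawn in a fixed order
(alphabetical, death last); each outcome occurs at most once and its
history flag feeds later hazards. Simulation stops at death or age 100.

## Remission and economic accrual

A simulated person with HbA1c below 48 mmol/mol at year 1 is in remission
from year 1; remission ends permanently at the first year at or above 48
(the strict threshold means exactly 48 never qualifies). Remission removes
the annual diabetes medication cost (default £300) but — deliberately —
does not modify complication risks beyond what the HbA1c trajectory
already does. With the default drift (+0.5 mmol/mol/year) and the 5-year
effect horizon, simulated remission durations are short (≤4 years for
those entering just under threshold), consistent with the source
analysis's description of its own behaviour.

Costs per life-year are management (£450) plus medication plus event costs
(first-year vs subsequent-year); utilities are an age/sex baseline
(0.85 at age 60, −0.0035/year, +0.02 male) minus 0.006 per BMI unit above
25 minus additive event decrements, floored at the EQ-5D minimum of
−0.594. The direct BMI–utility link is included because the favourable
economics of weight management in this population runs substantially
through health-related quality of life, and 0.005–0.01 per BMI unit is the
standard range in the UK literature; it is also the main driver of the
model's incremental QALYs, so it is a PSA parameter. Additive decrement
combination follows the usual outcome-model convention. Both streams are
discounted at 3.5% per year (year 0 undiscounted; the intervention cost is
applied once, undiscounted, at entry). There is no half-cycle correction:
accrual is annual at cycle start, recorded as a configuration flag.

## PSA and subgroups

The PSA samples each uncertain parameter from a distribution matched to
its support — normal for effect sizes (SEs from the trial's confidence
intervals: 1.10 mmol/mol and 0.60 kg), gamma for costs (SE 10% of the
mean), beta for the BMI disutility, lognormal for calibration multipliers
(SD 0.15 on the log scale) — independently across parameters, since no
parameter covariance is published. Every draw re-runs both arms on the
same population with the same event uniforms (common random numbers across
arms *and* draws), so draw-to-draw variation isolates parameter
uncertainty. The default is 2,000 draws; the bundled tests and acceptance
script use 40–60 draws on populations of 300–1,000 persons over 15–40
annual cycles, sizes chosen so the full suite runs on a single CPU in
seconds while leaving Monte-Carlo error well inside the tested margins.

Subgroup analyses (diabetes duration <1 vs 1–3 years; BMI bands <28,
28–30, 30–35, 35–40, ≥40 kg/m², half-open on the left because the
published band labels overlap at their endpoints; IMD quintiles) partition
a *single* common-random-number run of the full population rather than
re-simulating each stratum. This keeps size-weighted subgroup increments
exactly consistent with the whole-population increments and is equivalent
in distribution to per-stratum runs with shared parameters.

# Reproducibility

A single global seed fans out to fixed per-stage child seeds (population,
trial, events, calibration, PSA, bootstrap), so any stage can be re-run in
isolation and reproduce exactly; every written report carries the seed and
an order-sensitive digest of the configuration. All randomness flows
through R's generator under `set.seed`; runs are byte-reproducible.

# Known limitations

- The shipped risk equations are illustrative; absolute lifetime costs and
  QALYs from the defaults are not estimates of any real population
  quantity. Arm *differences* are more meaningful than levels, but still
  inherit the illustrative parameterisation.
- Trajectories are deterministic given the configuration (no individual
  stochastic drift), so between-person variance in outcomes comes from
  baseline heterogeneity and event randomness only.
- Remission status depends on the HbA1c trajectory alone; medication
  cessation behaviour is not modelled in the lifetime layer.
- PSA draws are independent across parameters; correlated uncertainty
  (e.g. between risk-equation coefficients) is not representable in the
  current configuration schema.
- The within-trial analysis does not regression-adjust QALYs for baseline
  utility; with randomised arms this is unbiased but less efficient.
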