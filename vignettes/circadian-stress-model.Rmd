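---
title: "Modelling circadian heart rate under chronic stress: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian heart rate under chronic stress: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(circastress)
```

# The scientific problem

Chronic stress leaves physiological traces, but unlike acute stress its
signature is not a momentary spike: it shows up, if at all, in how heart
rate (HR) is organised over the day. `circastress` implements an analysis
chain for asking that question with chest-patch wearable data from a
free-living cohort of office workers: does a person's chronic-stress level
(the 10-item Perceived Stress Scale, PSS-10, scored 0–40) modulate their
circadian HR profile, and is that modulation different for men and women,
for younger and older people, and on workdays versus weekend days?

The package covers the whole chain: a synthetic-cohort generator that
stands in for the (non-deposited) raw recordings, accelerometer-based
non-wear detection, physiological artifact filtering, hourly aggregation,
a harmonic mixed-effects model with autocorrelated residuals, model
comparison, descriptive statistics, and reporting plots.

# The model

The unit of analysis is the mean HR of subject $i$ at hour of day
$t \in \{0.5, 1.5, \dots, 23.5\}$ (hour-bin centres) within day-type $d$
(workday = Friday/Monday, weekend = Saturday/Sunday):

$$
y_{idt} = x_{idt}^\top \beta + z_{idt}^\top b_{id} + \varepsilon_{idt},
\qquad b_{id} \sim N(0, \Psi), \qquad
\operatorname{corr}(\varepsilon_{idt}, \varepsilon_{idt'}) = \rho^{|t-t'|}.
$$

The fixed part is a four-harmonic cosinor — sine/cosine pairs with periods
24, 12, 8 and 6 h, linear in their coefficients — plus a linear hour term,
and the covariates weekend, gender, age and PSS with the interactions:
weekend × each harmonic, gender × 24 h harmonic, age × 24 h harmonic,
PSS × 24 h harmonic, gender × PSS, age × weekend, and the two three-way
terms gender × PSS × 24 h harmonic and age × weekend × 24 h harmonic
(34 columns in total; `final_model_terms()`). Amplitude
$\sqrt{a^2 + b^2}$ and acrophase are derived quantities
(`harmonic_amplitudes()`), never fitted directly, so the model stays
linear in $\beta$.

Random effects are a subject intercept, a subject-by-day-type intercept,
and — in the `"final"` structure — subject-by-day-type slopes for the hour
and each sin/cos pair, with day-type-specific variances and diagonal
$\Psi$. Residuals are AR(1) across the hour order within each
subject-by-day-type series. Estimation is maximum likelihood (so nested
models can be compared by likelihood ratio); restricted ML is deliberately
out of scope.

Coding conventions, stated here once and embedded in every output header:
gender 0 = male (reference), 1 = female; weekend 0 = workday; age and PSS
mean-centred (by default at the sample means of the included subjects, or
at explicit `centers`); the linear hour is centred at 12 h.

## Why the likelihood is owned by the package

The model pairs crossed random effects with an AR(1) residual correlation,
a combination not exposed by any single standard fitter under one
interface. The package therefore evaluates the marginal Gaussian
likelihood explicitly — per subject,
$y_i \sim N(X_i\beta,\ Z_i \Psi Z_i^\top + \sigma^2 R_i(\rho))$ — and owns
the optimizer. `nlme::lme` with `corAR1` can express the intercepts-only
variant and is used as an independent cross-check in the test suite (log
likelihoods agree to ~1e-7, standard errors to ~1e-5); the dense
multivariate-normal evaluation in the tests is a second, fitter-free
oracle.

## Numerical design

* $\beta$ is profiled out by generalized least squares and $\sigma^2$ by
  its closed-form ML estimate at every covariance iterate, so the
  optimizer works only on $\log(\Psi_{jj}/\sigma^2)$ and
  $\operatorname{atanh}\rho$ — unconstrained, well-scaled coordinates.
  Bounds ($\pm 20$ on log ratios, $|\operatorname{atanh}\rho| \le 3$) keep
  the covariance positive definite; variance components may legitimately
  hit the lower bound (a zero variance estimate).
* Subjects sharing a (day-type, hour) row pattern have identical marginal
  covariance, and every fixed column factorizes into a time-pattern column
  times a subject scalar; one Cholesky factorization per pattern group and
  Hadamard-product cross-products make a full-cohort evaluation cost
  milliseconds. A complete 328-subject fit with the final random structure
  takes about a second on one core.
* The optimizer is `nlminb` capped at 200 iterations; non-convergence is
  reported on the fit object and warned about, never hidden.
* Rank-deficient fixed designs raise an error naming the aliased columns.
  The pipeline enables a graceful degradation (`drop_aliased`) only for
  degenerate cohorts (fewer than 10 subjects), where subject-level
  covariates cannot all be identified; such fits carry their warning.
* AR(1) distances use the position within the observed series (missing
  hours close ranks). With complete data position and hour coincide.

## Model comparison

`lrt_compare()` computes $\chi^2 = 2\Delta\log L$ with degrees of freedom
equal to the difference in free-parameter count; `pss_lrt()` compares the
final model against the model stripped of every PSS-containing term —
PSS, gender × PSS, PSS × 24 h harmonic (2 columns), gender × PSS × 24 h
harmonic (2 columns) — a 6-df test. "Anova"-style term tests are
implemented as likelihood-ratio tests; Wald-type tests on the same fit
would be asymptotically equivalent but can differ numerically at moderate
cohort sizes. `model_ladder()` fits the additive build order (hour,
harmonics, weekend, gender, age, PSS, two-way terms, three-way terms) and
reports log likelihood and AIC ($2k - 2\log L$) per layer; the term
hierarchy rule (an interaction requires all its marginal terms) is
enforced at design construction.

# The synthetic cohort generator

No raw recordings are distributed with the package, so the generator is a
first-class module: it emulates the study conditions the analysis assumes
and carries its ground truth (`truth$beta`, realized random effects) so
recovery can be tested.

Demographics (`cohort_config()`): 328 subjects, 142 female; age normal
38.9 (SD 10.2) years, rounded and clipped to 18–67; PSS-10 normal 13.7
(SD 6.0), redrawn (not clipped) outside 0–40 so no mass piles up at the
bounds, with the female stratum two points above the male stratum around a
preserved cohort mean — matching the population the package models.

Heart rate (`effect_config()`): baseline 72.5 bpm for a male reference
subject with a +3.3 bpm female shift — calibrated once so the cohort
median of per-subject median hourly HR reproduces the target population
table (72.5 male / 75.8 female / 73.5 pooled) through the full pipeline.
Harmonic amplitudes 6 / 2 / 1 / 0.5 bpm with acrophases 15 / 13 / 17 /
11 h give a realistic 12–14 bpm day-night swing; weekends flatten each
harmonic slightly. The covariate modulations act linearly on the 24 h
amplitude: PSS at +0.08 bpm/point for men and −0.08 for women, age at
−0.06 bpm/year on workdays and −0.02 on weekend days (an older, flatter
rhythm, more so on workdays). Only the signs of these modulations are
anchored in the literature the package follows; the magnitudes are
synthetic defaults chosen to be plausible and detectable at the default
cohort size, not estimates from real data. Random-effect SDs: 7 bpm
between subjects, 1.5 bpm between day-types within subject, and
1.5 / 0.8 / 0.5 / 0.4 bpm for the harmonic slopes (0.05 for the hour
slope).

Internally the generator converts amplitude/acrophase plus modulations
into the model's own sin/cos coefficient vector
(`true_fixed_effects()`) and simulates $X\beta + Zb + \text{AR(1)}$, which
makes recovery experiments exact: fitted coefficients have a well-defined
truth, provided the design is centred at the generator's reference values
(`age_ref` = 38.9, `pss_ref` = 13.7).

Two noise scales are provided. The wearable stream
(`simulate_minute_streams()`) adds minute-scale AR(1) noise
($\rho = 0.9$, stationary SD 3 bpm) — but hourly means of minute AR(1)
noise are *not* AR(1), so `simulate_hourly()` generates the analysis table
directly with hour-scale AR(1) noise ($\rho = 0.3$, SD 1.5 bpm) for
recovery and size experiments where the fitted model must match the
generative one exactly.

Artifacts (`artifact_config()`): sensor-off episodes (0.5/day, 2–8 h —
overnight or sports removals) freeze the accelerometer features at zero
and replace HR with garbage; spike artifacts (5/day, +80 bpm) hit single
minutes; 2% of minutes lose their HR sample. Episode durations matter for
the non-wear detector: the centred 11-minute indicator window cannot flag
the ~5 boundary minutes at each episode edge, so detection sensitivity is
roughly $1 - 10/\bar{d}$; at the default durations that is above 95%.

Recording starts Thursday 08:00 so the Thursday-trimming step has real
work to do, and timestamps live in a single fixed-offset frame (UTC
standing in for local clock time; the study design is single-site, and
daylight-saving transitions are out of scope).

Reproducibility: every simulator is bit-reproducible given its seed, and
each stage hashes the seed into its own RNG stream, so passing the same
integer to `generate_cohort()` and a simulator cannot replay the deviates
that produced the covariates (which would alias random intercepts with
age).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: meals, sleep timing and activity are not
modelled (their HR signatures are folded into the harmonics); noise is
Gaussian AR(1) rather than heavy-tailed; non-wear is honest (features
exactly frozen) rather than adversarial; and HR effect sizes for the
PSS/age interactions are assumptions, not measurements.

# Preprocessing conventions

The filtering chain runs in a fixed order, and order matters:

1. **Trim** to Friday 00:00 – Monday 16:00 (half-open; Monday 15:59 is
   the last retained minute), giving an 88-hour window for everyone.
2. **Non-wear/malfunction**: per minute, the summed absolute first
   differences of the three accelerometer features (MXYZ, AVGM, AVGSD —
   per-minute magnitude, mean of per-axis means, mean of per-axis
   *population* SDs) over the 10 closest minutes (a centred 11-minute
   window, shifted inwards at series edges). Strictly below 5e-4 flags
   malfunction; an indicator that cannot be computed flags conservatively.
   The indicator is translation invariant and scales linearly with
   fluctuation size.
3. **HR plausibility**: per subject, the median ± 3 SD band is computed on
   all malfunction-cleaned minutes *first*, then the 30 bpm floor and the
   age-predicted ceiling $208 - 0.7 \times \text{age}$ are applied.
   Computing the band on the full cleaned series makes the filter
   idempotent; applying the floor first would shrink the band and remove
   different minutes (this order sensitivity is tested). An exactly-zero
   removal rate on artifact-free data is not attainable — unbounded
   Gaussian noise has tail mass outside any ±3 SD band — and measured
   removal is well under 0.1%.
4. **Hourly aggregation** pools valid minutes by hour of day × day-type
   (not per calendar hour): the full 24 × 2 grid is emitted per subject,
   so a complete 328-subject cohort yields exactly 15,744 rows, the
   structural count the analysis table must have. Cells with fewer than
   30 valid minutes (configurable) are emitted with a missing mean; the
   model excludes missing rows.
5. **Inclusion** requires at least 24 valid calendar hour-slots (before
   pooling) in *each* day-type; a slot is valid with ≥ 30 valid minutes.
   Workdays can contribute at most 40 slots (Friday 24 + Monday 16),
   weekends 48. Counting device-on time instead of valid-minute coverage
   is exposed through the same configuration, but valid-minute coverage
   is the default reading.

# Descriptive statistics

The population table reduces each subject's HR to the median of their
hourly means (within day-type for the workday/weekend strata) before
taking cohort medians — this makes the strata well-defined and keeps a
heavy user from dominating pooled quantiles. Quartiles use linear
interpolation (R type 7) throughout, so IQR values are reproducible
bit-for-bit; note that for three values 30/38/46 this convention gives
IQR 8, not the 16 a no-interpolation convention would give. Gender strata
are compared with the Mann-Whitney-Wilcoxon test, workday vs weekend HR
with the Wilcoxon signed-rank test; both report exact p values for small
tie-free samples and tie-corrected normal approximations otherwise, and
both are validated against exhaustive-enumeration oracles in the tests.
Whether the gender HR comparison should use per-subject medians or all
hourly values is not decidable a priori; both are available
(`compare_groups(hr_reduction=)`), defaulting to per-subject medians.

# Experiment sizes used by the test suite

The suite's simulation experiments are sized to be decisive yet
desk-scale: parameter recovery uses 50 replicates of the full 328-subject
cohort at hour-scale noise (mean bias per fixed effect under 5% or
0.05 bpm; mean 95% Wald coverage across effects within [90%, 99%], with a
binomial-consistent per-effect floor — at 50 replicates individual
coverages move in 2% steps, so per-effect bands tighter than that would
reject by pure Monte-Carlo chance). Size control uses 200 null replicates
at 60 subjects for the 6-df PSS likelihood-ratio test, compared against
the exact binomial 95% acceptance band around the nominal 5%. Generator
calibration runs the full minute-level pipeline over 10 seeds. The whole
suite runs in roughly ten minutes on one core.

# Known limitations

* Diagonal $\Psi$ is the supported structure; random-effect correlations
  are not estimated (the unstructured option was considered and deferred:
  nothing in the package's outputs depends on them).
* LRT p values for variance components sit on the boundary of the
  parameter space and are conservative; the package only tests fixed
  effects by LRT.
* Fixed-offset time handling: daylight-saving transitions inside a
  recording week are not modelled.
* The minute-scale AR(1) noise model makes the hourly residual
  correlation only approximately AR(1); inference on real minute-level
  data inherits that approximation.

# A minimal run

```{r, eval = FALSE}
profiles <- generate_cohort(cohort_config(n_subjects = 40, n_female = 17,
                                          seed = 1))
sim <- simulate_minute_streams(profiles, effect_config(), artifact_config(),
                               seed = 1)
prep <- preprocess_minutes(sim$minutes, profiles)
fit <- fit_harmonic_model(prep$hourly, profiles, random = "reduced")
glance(fit)
tidy(fit)[1:6, ]
pss_lrt(prep$hourly, profiles)
```
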