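# circastress

Circadian heart-rate modelling under chronic stress, for wearable cohort
studies.

`circastress` is an R package for a question that sits between
psychophysiology and biostatistics: does chronic stress — measured with
the 10-item Perceived Stress Scale (PSS-10, 0–40) — modulate the circadian
profile of heart rate (HR), and is that modulation different by gender, by
age, and between workdays and weekend days? It is aimed at researchers
analysing multi-day chest-patch recordings (minute-level HR plus
accelerometer features) from free-living cohorts, and at methodologists
who want a fully simulated, ground-truthed version of such a study.

## The model

Hourly mean HR of subject *i* in day-type *d* (workday vs weekend) at
hour-bin centre *t* is modelled as a four-harmonic cosinor mixed model
with AR(1) residuals, fitted by maximum likelihood:

```
y_idt = x_idt' β + z_idt' b_id + ε_idt,
b_id ~ N(0, Ψ)  (diagonal),
corr(ε_idt, ε_idt') = ρ^|t − t'|  within each subject × day-type series.
```

The fixed part contains sin/cos pairs for periods 24, 12, 8 and 6 h, a
linear hour term, the covariates weekend, gender, age and PSS, and the
interactions weekend × each harmonic, {gender, age, PSS} × circadian
(24 h) harmonic, gender × PSS, age × weekend, and the three-way terms
gender × PSS × H24 and age × weekend × H24 — 34 coefficients. Nested
models are compared by likelihood ratio (χ² with df = parameter-count
difference); the headline test drops every PSS term at once (6 df).

Around the model sits the full pipeline: a synthetic cohort generator
with known ground truth (328 subjects, 142 female, age 38.9 ± 10.2,
PSS 13.7 ± 6.0 by default), accelerometer-based non-wear detection
(summed absolute feature differences over the 10 closest minutes,
threshold 5e-4), HR artifact filtering (subject median ± 3 SD band, 30 bpm
floor, Tanaka ceiling 208 − 0.7 × age), hour-of-day × day-type
aggregation, inclusion criteria, Table-1-style descriptives with
Mann-Whitney and Wilcoxon signed-rank tests, and ggplot2 reporting.

## Worked example

```r
library(circastress)

profiles <- generate_cohort(cohort_config(n_subjects = 40, n_female = 17,
                                          seed = 1))
sim  <- simulate_minute_streams(profiles, effect_config(), artifact_config(),
                                seed = 1)
prep <- preprocess_minutes(sim$minutes, profiles)
fit  <- fit_harmonic_model(prep$hourly, profiles, random = "reduced")
fit
#> <harmonic_fit> ML, 1756 obs / 38 subjects
#>   logLik -3511.54  AIC 7099.08  (k = 38)
#>   sigma 2.298 bpm, AR(1) rho 0.683
#>   random-effect SDs (bpm):
#>     intercept_subject        6.358
#>     intercept_daytype        0.516
```

Two of the 40 simulated subjects lost too many hours to sensor-off
episodes and fail the 24-hours-per-day-type inclusion rule, leaving 38.
The residual autocorrelation (0.68) and the between-subject SD (6.4 bpm)
are recovered from data simulated with ρ-driven minute noise and a 7 bpm
subject intercept SD. The harmonic coefficients convert back to
amplitude/acrophase form:

```r
harmonic_amplitudes(fit)
#>   period amplitude acrophase
#> 1     24     5.81      14.9
#> 2     12     2.03       1.21
#> 3      8     0.872      0.946
#> 4      6     0.518      5.44
```

— a 5.8 bpm circadian amplitude peaking at 14.9 h against a generative
truth of 6 bpm at 15 h (the 12 h acrophase 1.21 is 13 h modulo its
period). The 6-df chronic-stress test on this small cohort:

```r
pss_lrt(prep$hourly, profiles)
#>   term            chisq    df     p
#> 1 pss (all terms)  8.86     6 0.182
```

At 40 subjects the PSS modulation (±0.08 bpm per PSS point on the 24 h
amplitude) is not yet detectable — as expected; power arrives at the
full 328-subject design. Descriptives mirror a population table:

```r
summarize_cohort(profiles, prep$hourly)   # age / pss / hr by stratum
#>   variable  stratum  n   median    iqr
#>   hr        male    22   72.0     9.6
#>   hr        female  16   73.1     5.3
#>   hr        total   38   72.9     7.8
#>   ...
```

`run_pipeline()` wraps the chain end to end, writing `subjects.csv`,
`hourly.csv`, `fit_report.json`, `term_tests.csv`, `table1.csv` and a
hash manifest so identical configs reproduce identical artifacts;
`render_report()` builds the hour-profile and per-hour age/PSS slope
figures from a pipeline bundle.

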