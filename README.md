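# telemsurv

Known-fate survival analysis for telemetry-tracked wildlife, built around
the study design used for continental-scale Eurasian lynx (*Lynx lynx*)
monitoring: individuals are captured, collared and followed until death or
censoring, so their fates are observed directly and detection probability
plays no role. The package is aimed at quantitative ecologists who need the
full chain from raw tracking records to cause-specific mortality rates,
harvest-compensation tests and covariate-driven survival models — and at
methodologists who want each link of that chain testable against synthetic
data with known truth.

## What it does

**Time scales.** Tracking records (`id`, sex, study area, birth date,
capture and end timestamps, fate, cause) are transformed into analysis-ready
*spells* on two scales: a continuous **age** scale with delayed entry (an
animal caught at age 915 days enters the risk set only then — left
truncation) and a recurrent **annual** scale with its origin at 1 May, the
birthing season. Spells are split at season boundaries, country-specific
hunting windows and age-class birthdays, so every piece has constant
covariates (the piecewise-constant-hazard convention). Splits conserve each
animal's tracked days exactly.

**Nonparametric estimation.** Survival uses the product-limit
(Kaplan–Meier) estimator with counting-process risk sets
`S(t) = prod_{t_i <= t} (1 - d_i / n_i)`. Cause-specific cumulative
incidence under competing risks uses weighted product-limit estimation: for
the cause under analysis, animals lost to a competing cause stay in the
risk set with a time-dependent weight built from product-limit estimates of
the censoring and truncation distributions, which makes the estimator
exactly equal to the Aalen–Johansen estimator (the tests assert agreement
to 1e-10). Medians, conditional survival `S(t)/S(s)` and one-cycle annual
rate tables by age class, sex and management type round this out.

**Additive vs. compensatory mortality.** For hypotheses H1–H6 (survival or
a mortality component against anthropogenic or hunting mortality across
study areas), every rate estimate is resampled from a beta distribution
with moments matched to its estimate and squared standard error; a
logit-link beta regression is fitted to each of the (by default) 10,000
sampled data sets; slopes are summarised by their mean and 90%
highest-posterior-density interval. Survival slopes are classified per draw
against the fitted no-hunting survival `S0`: positive trends are
compensatory or overcompensatory, trends at or below `-S0` additive or
superadditive, anything between partially compensatory.

**Landscape exposure.** Seasonal location fixes become landscape-scale use
areas by the fix-count rule (>= 25 fixes: 95% kernel-density isopleth;
1–24: union of sex- and latitude-specific travel-distance discs; 0: the
previous period carried forward), and covariate surfaces are averaged over
those areas (landscape scale) or at the fixes themselves (home-range
scale). Exposure matrices are reduced by PCA, retaining components that
explain at least 5% of the variance.

**Bayesian AFT models.** `aft_fit()` fits accelerated failure time models
by adaptive MCMC: covariates and a frailty rescale internal time,
`tau(t) = integral exp(x(s)'beta + w) ds`, with `S(t|x) = S0(tau(t))` for a
lognormal baseline (a piecewise-constant hazard on the accelerated scale is
available). `exp(-beta)` multiplies median survival time per unit covariate.
Frailties are IID normal by group or a Gaussian random field with
correlation `exp(-phi d)` over km between individuals' location centroids,
updated blockwise through a non-centred, whitened parameterisation. Model
comparison uses DIC and LPML (selection = union of the `ΔDIC < 2` and
`ΔLPML < 2` sets), effects are read through evidence ratios
`p / (1 - p)`, and fit is checked with conditional Cox–Snell residuals.

**Synthetic data.** Every stage is testable offline: the generator draws
cohorts with 1 May births, age-class-dependent capture, cause-specific
piecewise-constant hazards (season, sex, age class, hunting windows in
hunted areas only), exponential collar failure, GPS/VHF fix streams
(3.8 and 1.6 locations/day), spatially autocorrelated covariate rasters,
and study-area rate sets with a known compensation regime.

## Worked example

```r
library(telemsurv)

pop <- generate_population(sim_config(n = 300), seed = 42)
rec <- simulate_cohort(pop, hazard_spec(), censor_rate = 0.3, seed = 43)
ann <- assign_age_class(
  apply_hunting_periods(build_annual_scale(rec), pop$areas, pop$calendar,
                        mode = "annual"))
annual_rates(ann, pop$areas, empty = "drop")
```

```
 age_class sex management      quantity estimate    se
     adult   F     hunted      survival    0.792 0.042
     adult   M     hunted      survival    0.599 0.062
     adult   F  protected      survival    0.881 0.026
     adult   M  protected      survival    0.767 0.037
     adult   M     hunted legal_hunting    0.159 0.046
     ...
```

Adult females in hunted areas survive a cycle year with probability 0.79;
males pay a hunting toll (legal-hunting incidence 0.16/yr) on top of
illegal killing. Feeding per-area rate tables into the compensation test:

```r
rs   <- generate_rate_sets("partial", S0 = 0.85, n_areas = 12, seed = 44)
comp <- run_hypothesis_tests(rs, n_draws = 2000, seed = 45)
comp
```

```
Compensation tests (90% HPD)
  H1 survival ~ anthropogenic: mean beta -0.336 [-2.700, 1.953]  comp 41% / partial 59% / additive 0%
  H2 survival ~ hunting: mean beta -1.796 [-4.027, 0.695]  comp 9% / partial 90% / additive 1%
  H3 natural ~ anthropogenic: mean beta 2.132 [-3.973, 8.021]  (inconclusive)
  ...
```

The generating regime was partial compensation and the modal per-draw
label for survival-versus-hunting is indeed `partial` (90% of draws). An
AFT coefficient is read as an acceleration factor:

```r
acceleration_factor(0.41)
#   beta median_time_factor decline_factor
# 1 0.41              0.664           1.51
```

A male coefficient of 0.41 means male survival times are shortened by a
factor 0.66 — equivalently, female survival is about 1.5 times greater.

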