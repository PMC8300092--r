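---
title: "Methods: from feeding trials to national emission factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from feeding trials to national emission factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metanor)
```

`metanor` models enteric methane (CH4) from dairy cows at two scales.
The *basic* tier predicts daily CH4 production from diet descriptors
measured in feeding trials. The *operational* tier predicts the methane
conversion factor Ym and gross energy intake (GEI) from the two drivers
a national inventory actually tracks — annual milk yield and
concentrate share — and composes them into an annual emission factor.
This vignette documents the equations, the statistical conventions, the
feeding simulator that links the tiers, and the design choices and
limitations behind each.

## 1. Units and conversions

CH4 is carried in MJ/day throughout. Conversions use
1 L CH4 = 0.716 g and 1 g CH4 = 0.05565 MJ, so 1 kg CH4 = 55.65 MJ.
`convert_ch4()` chains any of L/day, g/day and MJ/day through grams.

```{r}
ch4_units$mj_per_kg_ch4
convert_ch4(500, "l_per_day", "mj_per_day")
```

## 2. Trial records

A trial record is a *treatment mean*: one row per dietary treatment in
one study, with the number of animals behind the mean (`n_obs`), the
measurement technique, DMI (kg/day), dietary fatty acids (FA), NDF and
optionally ether extract (EE) in g/kg DM, forage proportion, and
observed CH4 (MJ/day). `validate_trial_records()` enforces the schema
with row-indexed messages; `read_trial_table()`/`write_trial_table()`
round-trip the CSV form. A packaged synthetic database
(`inst/extdata/synthetic_feeding_trials.csv`; 99 records, 29 studies,
63 development / 36 evaluation) stands in for the confidential
experimental data this kind of analysis is normally built on.

## 3. The basic-model registry

Ten fixed-coefficient equations predict CH4 (MJ/day). Three were
developed with the mixed-model machinery in this package and the rest
are extant literature equations with comparable inputs:

```{r}
basic_model_registry()[, c("model_id", "label")]
```

The three in-house variants are, with CH4 in MJ/day:

- `model1`: `4.92 + 1.13 DMI − 0.118 FA`
- `model2`: `−3.01 + 1.19 DMI − 0.103 FA + 0.017 NDF`
- `model3`: `1.13 DMI − 0.114 FA + 0.012 NDF` (no intercept)

Extant equations that are published in g/day or L/day are converted at
prediction time with the constants of Section 1 (e.g. the nonlinear DMI
equation `(20 + 35.8 DMI − 0.5 DMI²) × 0.716 × 0.05565`).
`predict_ch4()` refuses to predict when a required diet descriptor is
absent rather than imputing.

## 4. Refitting: weighted linear mixed models

`fit_basic_model()` refits an equation on treatment means pooled across
studies, using `lme4::lmer` with:

- a single random intercept grouped by study, absorbing
  between-experiment level differences (ration background, lab, cow
  genotype);
- case weights proportional to `n_obs`, normalized to mean 1. Because
  the residual of a treatment mean shrinks with the number of animals
  averaged, `n_obs` weighting is the inverse-variance choice, and the
  synthetic generator (Section 7) draws residuals with SD
  `sigma_resid/√n_obs` so the two conventions are mutually consistent;
- REML estimation; Wald t p-values with residual degrees of freedom
  `n − p` (a simple convention, adequate at these sizes; no Satterthwaite
  correction is attempted);
- variance inflation factors `VIF_j = 1/(1 − R²_j)` computed on the
  fixed-effects design to flag collinear predictor sets, and a
  rank-deficiency error naming the collinear columns.

A likelihood-ratio screen (`screen_technique_effect()`, ML fits of
nested models) checks whether measurement technique (respiration
chamber, SF6 tracer, head hood, GreenFeed) shifts the CH4 level; a
technique term is only retained when the LRT p-value falls below the
screening threshold (default 0.1).

## 5. Evaluation: MSPE decomposition and CCC

`evaluate_predictions()` uses *population* moments (divide by n, not
n − 1) throughout, so the three MSPE components sum to the MSPE exactly:

- `ECT = (P̄ − Ō)²` — error of central tendency;
- `ER = (Sp − r·So)²` — error due to regression (slope ≠ 1);
- `ED = (1 − r²)·So²` — error due to disturbance,

with `So`, `Sp` the population SDs of observed and predicted and `r`
the Pearson correlation. RMSPE is reported as % of the observed mean.
Concordance is Lin's coefficient `CCC = r × Cb` with
`Cb = 2 / (v + 1/v + µ²)`, `v = So/Sp`, `µ = (P̄ − Ō)/√(So·Sp)`.
`rank_models()` evaluates any registry subset on a record set and
orders by descending CCC (ties broken by RMSPE), skipping — with a
warning — models whose required predictors are unavailable.

One caveat worth stating: several registry equations are nearly
parallel over realistic diet ranges (e.g. `model2` and the extant
DMI–FA–NDF equation differ by only a few tenths of an MJ across typical
records), so CCC rankings between such neighbours are not stable under
large between-study variability; ranking reliability should be judged
against the noise level of the evaluation set.

## 6. The feeding simulator

The operational tier needs a database of (ECM level, diet, GEI, CH4)
combinations covering the national production range. The simulator
builds one from feeding-standard principles:

- **Grid**: 15 annual ECM levels (5000–12000 kg) × 3 silage qualities
  (NEL 7.0/6.1/5.7 MJ/kg DM, each paired with a matching concentrate) ×
  22 biweekly timepoints over a 305-day lactation, plus a 60-day dry
  period on silage alone — 990 lactating and 45 dry records.
- **Lactation curve**: Wood's incomplete gamma
  `y(t) = a·t^0.25·e^(−0.004 t)` (peak near day 62), normalized so daily
  yields over days 1–305 sum to the annual ECM.
- **Energy requirement**: maintenance
  `0.33 × 600^0.75 × 1.125 = 45.0` MJ NEL/day for a 600-kg cow with an
  activity allowance, plus 3.45 MJ NEL per kg ECM. These two constants
  were calibrated against the energy balance of the reference
  feeding-grid table bundled in `inst/extdata/norfor_reference_grid.csv`
  and are exposed in `norfor_params()`.
- **Ration formulation**: silage to a fill cap of 14 kg DM/day, then
  concentrate up to a 65% share cap until the NEL requirement is met;
  shortfalls are flagged `feasible = FALSE` rather than thrown.
- **Diet composition and GEI**: diet NDF/CP/fat are DMI-weighted feed
  means; FA is taken as 0.80 × crude fat; gross energy from
  `0.0242 CP + 0.0366 fat + 0.017 (1000 − ash − CP − fat)` MJ/kg DM,
  with a single multiplicative calibration anchored so the mean GEI of
  the 6000-kg/best-silage series reproduces the reference value of
  298–300 MJ/cow/day.

`attach_ch4_ym()` then adds basic-model CH4 predictions and
`Ym = 100 × CH4 / GEI` to every record.

## 7. Operational models and emission factors

The published operational equations are frozen in
`operational_model_table` (ECM in kg/year, concentrate share in %):

- `Ym(S) = 7.11 − 7.0e−5 ECM − 4.1e−3 conc`
- `Ym(M) = 7.65 − 1.1e−4 ECM − 5.4e−3 conc`
- `Ym(N) = 7.71 − 1.0e−4 ECM − 4.4e−3 conc`
- `GEI = 159 + 0.02 ECM + 1.39 conc`

and the annual emission factor is
`EF = GEI × Ym/100 × 365 / 55.65` kg CH4/head/year:

```{r}
scenario_report(6000, 38, "ym_s", gei = 298)
```

`fit_operational()` refits the same linear form on a simulated
database. The random intercept is grouped by ECM production level,
treating the repeated weekly observations within a production level as
correlated. Grouping by timepoint instead conflates silage quality with
concentrate share (poorer silage requires more concentrate *and*
produces higher Ym at a given yield), which can flip the sign of the
concentrate slope; the ECM-level grouping recovers the expected
negative ECM and concentrate effects on Ym and positive effects on GEI.
On noiseless inputs the refit reproduces generating coefficients to
numerical precision.

## 8. Synthetic trial generator

`generate_trial_database()` produces seeded trial databases with the
error structure the mixed model assumes: CH4 = registry-model
prediction + study effect (SD `sigma_study`) + residual
(SD `sigma_resid/√n_obs`) + optional technique offset. Predictors are
uniform within configured ranges with study-level mean shifts
(`within_study_frac`) so studies differ systematically, as multi-study
compilations do. `generate_eval_split()` divides by whole studies only.
The generator underpins the package's parameter-recovery and ranking
checks; it makes no attempt to reproduce any particular published
study's values.

## 9. Known limitations

- The simulator is deliberately coarse: one cow type (600 kg), one
  lactation-curve shape, linear energy requirement in ECM, no body
  reserve mobilization, no grazing season. It reproduces the *structure*
  of a feeding-standard database, not any individual herd.
- Wald t p-values with residual df are approximate; for small numbers
  of studies the study-variance estimate itself is imprecise.
- The operational equations compress all diet information into
  concentrate share; two rations with equal share but different silage
  quality receive the same Ym, which is exactly the compromise an
  inventory model accepts.
- Registry equations are applied within the diet ranges they were
  developed for; extrapolation (e.g. the nonlinear DMI equation beyond
  ~35 kg DMI, where it turns over) is not guarded against beyond input
  validation.
- CCC-based ranking between near-parallel equations is unstable under
  strong between-study noise (Section 5); a ranking from a single
  36-record evaluation set should be read as indicative, not definitive.
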