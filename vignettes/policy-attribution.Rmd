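---
title: "Methods: from policy panels to preventable cancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from policy panels to preventable cancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pifcast)
```

`pifcast` chains four estimation stages — panel regression, counterfactual
scenario construction, incidence annualization, and Levin attribution — into
a projection of the cancer cases preventable by tobacco control policies in
the Eastern Mediterranean Region over 2025–2050. This vignette records the
model, its assumptions, the tunable parameters, and the design decisions
taken where more than one reasonable reading existed.

## The regression stage

Smoking prevalence (age-standardized, percent 0–100) is regressed on policy
exposures with country and year fixed effects, separately for men and women:

$$\mathrm{Prevalence}_{it} = \beta_0 + \sum_k \beta_k x_{k,it}
  + \mathrm{Country}_i + \mathrm{Year}_t + \varepsilon_{it}.$$

The country effects absorb time-invariant heterogeneity (culture, religion,
baseline epidemic stage); the year effects absorb region-wide shocks. The
unit of analysis is the country-year: models are unweighted, so a small
country contributes as much as a populous one — this is an ecological design
choice, not an oversight. Rows with a missing predictor are dropped listwise
per model; nothing is imputed.

Estimation is ordinary least squares on an explicit design matrix with
reference-cell dummies (first country and first year alphabetically /
numerically are the reference; their effects are reported as 0). At panel
sizes of roughly 100 rows per gender this is exact, transparent, and
numerically identical to the within-transformation; the test suite asserts
equality with R's `lm()` on the same dummies to 1e-8 on randomized panels.
Standard errors are classical OLS errors without clustering: they feed only
descriptive output, and all reported uncertainty comes from the bootstrap.

Three conventions deserve a note:

* **Multivariable model.** The combined-policy model includes *both*
  country and year effects alongside the three predictors, matching the
  description of the fixed-effects framework even where a compact equation
  display omits the country term.
* **R² components.** Within, between and overall R² are squared
  correlations between the linear predictor $x\hat\beta$ (fixed effects
  excluded, the panel-econometrics convention) and the response on
  country-demeaned values, country means, and raw values respectively. With
  the fixed effects included, the between component would be identically 1
  and carry no information. A degenerate component (zero variance) is
  returned as `NA` rather than a crash.
* **VIF.** Variance inflation factors are computed among the policy
  predictors only, $\mathrm{VIF}_k = 1/(1 - R^2_k)$, with $R^2_k$ from
  regressing predictor $k$ on the others. Perfect collinearity yields `Inf`,
  a signal rather than an error. A predictor with zero within-country
  variance is rejected by name, because it is indistinguishable from the
  country effects.

The interaction variant appends the raw (uncentered) `mpower × literacy`
product. Uncentered values keep the main coefficients interpretable as
effects at literacy 0 and make the nesting exact: forcing the interaction
coefficient to zero reproduces the main-effects pipeline bit for bit.

## Scenarios

Four counterfactuals are evaluated against the 2025 baseline:

| scenario | target rule | gap |
|---|---|---|
| `max_mpower` | MPOWER score to its maximum, 34 | `34 − current` |
| `affordability_plus10` | +10 units of the affordability index | always 10 |
| `max_literacy` | literacy to 100% | `100 − current` |
| `combined` | all three rules at once | all three gaps |

The 10-unit affordability increase reflects benchmarking against strong
tobacco-control countries, where the index sits around 10–15% of GDP per
capita versus under 5% in most EMR countries. The scenario reduction is
`Σ (−β_k × gap_k)`; counterfactual prevalence is the baseline minus the
reduction, floored at 0 (and capped at 100 for pathological positive-β
inputs — the symmetric guard). Single-policy scenarios use the matching
univariable coefficient and the combined scenario the multivariable ones;
this split follows the source methodology, which adjusts coefficients only
for the combined case, and it is recorded per row in the
`coefficient_source` column. The reduction is a one-time level shift applied
from 2025 and held constant through 2050 — no phase-in, no behavioural lag.

Gaps are computed from the 2025 policy values when observed, otherwise from
the latest observed year; `gap_source_year` records the earliest year used
so fallbacks are visible. Signed arithmetic is kept throughout: a
positive fitted coefficient produces a *negative* reduction (higher
counterfactual prevalence) rather than being silently truncated.

Under the interaction model the combined scenario uses marginal effects
evaluated at each country's own covariates:
$\partial \mathrm{Prev}/\partial \mathrm{MPOWER} = \beta_M + \beta_{ML}\,
\mathrm{literacy}$, and symmetrically for literacy. A positive interaction
with a negative main effect means the MPOWER effect attenuates where
literacy is high.

## Incidence and attribution

Projected case counts arrive as anchors at 2025, 2030, …, 2050 per country,
gender and site (13 tobacco-related sites; cervix exists only for women).
Annual values are interpolated with a constant increment
`(cases_{t+5} − cases_t)/5` inside each interval, so anchor years are
reproduced exactly and anchors on a straight line are interpolated with zero
error. Cumulative totals sum calendar years 2025 through 2050 **inclusive**
(26 values): the summation sentence is taken as the operational definition
even though a 25-year label also circulates; `cumulative_cases(year_from =
2026)` reproduces the 25-value alternative, and the two differ by about 4%
on typical growth paths. Fractional cases are carried unrounded everywhere;
`round_half_up()` exists for report formatting only.

Attribution is computed at the finest stratum and only then aggregated.
Levin's formula takes prevalence as a *proportion*; the package stores all
prevalences as percent and converts only inside `attribute_cases()`, and
`levin_paf()` rejects any `p > 1` outright — the cheapest way to make the
percent/proportion confusion impossible. Because the formula is nonlinear,
aggregation order matters: aggregate PAF and PIF are always case-weighted
ratios `Σ attributable / Σ total` and `Σ preventable / Σ total`, never means
of stratum fractions. Strata are keyed by (country, gender, site, scenario);
duplicated keys abort with a double-counting error. The smoking–cancer
relative risks are gender- and site-specific, treat "current smoking versus
all others" as the contrast, and apply to the whole 2025–2050 window — the
same constant-effect simplification as the prevalence shift.

## Uncertainty

The default bootstrap resamples **countries** with replacement (the
country-level reading): each draw becomes a pseudo-unit, the regressions are
refit, scenarios and attribution rerun, and the statistic recomputed on the
replicate's country universe. Percentile bounds (2.5/97.5 at the default
level) come from the empirical distribution; the point estimate is always
computed from the unresampled data and is invariant to `n_reps` and `seed`.
One master seed spawns an independent substream per replicate, so replicates
are order-independent. Failed replicates (singular refits) are dropped and
counted, with a hard error above 10%.

Country resampling is incoherent for a *single country's* interval, so for
country-level CIs the package offers `country_panel_rows` (resample that
country's panel years) combined with `rr_lognormal` (draw each relative risk
from a lognormal matched to its published CI). This is an interpretation —
the mechanism behind per-country intervals is genuinely underdetermined —
and is therefore never used as a default for regional results.

The incidence sensitivity multiplies every case count by a factor (0.9 and
1.1 reproduce the ±10% analyses) and provably commutes with aggregation;
PAF and PIF are unchanged by construction.

## The synthetic generator

`generate_study_bundle()` emulates the study conditions: 16 named EMR
countries, biennial 2010–2020 fit years plus a 2025 baseline, and exposures
in observed ranges (integer MPOWER 20–31, affordability 0–15% of GDP per
capita, literacy 30–100%, with a mild ~0.3 correlation between the latent
drivers of MPOWER and literacy so collinearity diagnostics and the
interaction sensitivity face realistic structure). Default true coefficients
are, for men, −0.26 (MPOWER, the upper bound of the reported per-unit
association), −0.35 (affordability) and −0.20 (literacy) percentage points
per unit, with weaker women's effects (−0.10/−0.08/−0.05) reflecting the
much lower and flatter female prevalence; intercepts and country-effect SDs
keep men's prevalence roughly within 0–60% and women's within 0–26%.
Residual SDs default to 1.5 (men) and 0.5 (women) percentage points. Where
the source states no value these are one-time choices of realistic
magnitudes, documented here and not revisited.

Prevalence is clipped to [0, 100]; the realised clipped fraction is attached
to every panel (`clip_fraction` attribute) and a warning fires above 5%,
because clipping biases recovery of the generating coefficients. Exact
parameter-recovery tests therefore run in clipping-free regimes. Anchors are
generated *exactly* linear (`base × (1 + growth × (year − 2025))`), making
interpolation error zero by construction, and relative risks are drawn
log-uniformly in [1.1, 10].

What the generator does **not** emulate: age structure, smoking histories
(never/former/current), policy-component heterogeneity within MPOWER,
measurement error in the exposures, non-linear incidence trajectories, and
water-pipe-specific risks. Passing tests demonstrate that the pipeline's
arithmetic and statistics are correct under the stated model — not that the
model captures every feature of real surveillance data.

## Numerical choices and degenerate inputs

* Exact-recovery tolerances are 1e-8 (estimator identities) and 1e-9
  (interpolation on linear truth); conservation across aggregation levels is
  asserted to 1e-6 relative.
* CSV round-trips are bit-exact: doubles are written with 17 significant
  digits and parsed with the correctly rounded base parser.
* Ties and references: the first country and year (sorted) are the
  fixed-effect references; scenario rows keep a fixed scenario order.
* Degenerate inputs fail early with typed conditions: schema errors name the
  missing column, validation errors name the offending (country, year,
  gender), completeness errors name the stratum and missing anchor years,
  singular designs name the collinear predictor.
* Problem sizes in the shipped checks (chosen for thorough yet quick runs):
  16-country bundles for end-to-end properties, 200 replicate seeds for the
  unbiasedness check, 200 outer × 500 inner replicates on 40 units for
  bootstrap coverage, and a 1,000-replicate bootstrap in the full run.

## Known limitations

Associations are treated as causal by assumption; time-varying confounders
(economic growth, enforcement intensity) are outside the fixed-effects
design. Coefficients are uniform across countries within gender. Prevalence
changes translate into risk changes with no latency. Published relative
risks are imported, not re-estimated, and projection anchors are consumed
as given — the ±10% scaling is the only acknowledgement of their
uncertainty. The per-country bootstrap mechanism is an interpretation, as
described above.
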