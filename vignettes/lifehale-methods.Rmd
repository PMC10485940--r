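---
title: "Methods: subpopulation life tables and Sullivan HALE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subpopulation life tables and Sullivan HALE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifehale)
library(dplyr)
```

`lifehale` estimates period life expectancy (LE) and Sullivan healthy life
expectancy (HALE) for subpopulations observed through aggregated registry
data: per-age person-years of exposure and death counts, possibly sparse, plus
age-banded unhealthy-prevalence schedules. This vignette is the package's own
account of the model, its assumptions, the tunable parameters, and the
numerical choices made where the design was genuinely open.

## The life-table model

The input unit is one group and sex: contiguous single ages from the group's
first (registration) age to the oldest observed age, with exposure `E_x` in
person-years and death counts `D_x`. The chain is:

**Rates.** `m_x = D_x / E_x`. A zero-exposure age carries no information and
is flagged `NA`; it must be imputed (below), never treated as a zero rate.

**Probabilities.** `q_x = m_x / (1 + (1 - a_x) m_x)`, capped at 1. The
separation factor `a_x` — the mean fraction of the year lived by those dying
in the interval — is 0.05 for males and 0.13 for females at age 0 (infant
deaths cluster early; these are the classic Coale–Demeny indicator values) and
0.5 at all later ages, which is exactly the midpoint person-years formula
`L_x = (l_x + l_{x+1})/2`. A cap is required because the raw expression tends
to `1/(1 - a_x) > 1` at extreme rates.

**Graduation.** Raw `q_x` series from small groups are jagged. We graduate
with a symmetric moving-weight formula in the Greville tradition, implemented
as a local least-squares cubic over a window of `order` ages (a degree-3
Savitzky–Golay filter). This construction has the property that defines
actuarial graduation of this class: polynomials up to degree three — constants
included — pass through unchanged, while isolated small-count spikes are
attenuated. Endpoints shrink the window one-sidedly and keep the cubic fit, so
they are graduated too and the reproduction property still holds there.
Published weight tables can be substituted through the `weights` argument. The
default window is 9, the conventional order; orders 7–9 give near-identical
tables on realistic schedules, which is why we do not expose order selection
machinery. Series shorter than the window are passed through with a warning
rather than half-graduated. The open-interval probability is forced to 1 and
kept out of the graduation window.

**Recursion and closure.** With radix `l_0` = 100,000 (convention):
`d_x = l_x q_x`, `l_{x+1} = l_x - d_x`, `L_x = l_{x+1} + a_x d_x`,
`T_x = sum(L_y, y >= x)`, `e_x = T_x / l_x`. The terminal age is an open
interval with `q = 1`; its person-years use the exponential closure
`L_omega = l_omega / m_omega`, with `m_omega` the (extended) rate at the
closure age. Conservation (`sum(d_x)` equals the radix) and monotone
survivorship hold exactly by construction and are asserted in the tests.

**Chiang intervals.** The sampling variance of `e_x` propagates binomial
variation of each `q_j`:

- `S2_p[j] = q_j^2 (1 - q_j) / D_j`
- `S2_e[x] = (1/l_x^2) * sum_j l_j^2 [(1 - a_j) + e_{j+1}]^2 S2_p[j]`

and the 95% interval is `e_x +/- 1.96 * sqrt(S2_e[x])`. We square the
propagation bracket, as in Chiang's published estimator; a `literal_bracket`
flag reproduces the unsquared variant for sensitivity analysis, since the
formula is sometimes printed without the square. Ages with `q` strictly inside
(0, 1) but no observed deaths — typically model-extended old ages — contribute
zero variance, with a single collapsed warning. Intervals are computed at
every age, not only at reporting ages.

## Old-age extension

Registry data at the oldest ages are unreliable, so rates beyond a fit window
are replaced by a fitted parametric hazard. The registry holds nine families
(see `?extension_families` for formulas): Gompertz, Weibull, Kannisto,
Heligman–Pollard old-age term, Denuit–Goderniaux, Coale–Kisker, Makeham,
log-quadratic, and Perks — the canonical candidates of the old-age extension
literature. The set is configurable, so a different published collection can
replace any entry.

Three numerical choices matter:

- **Criterion.** All families minimise the same loss — the sum of squared
  errors of `log m_x` on the fit window — so criteria are comparable across
  families. Least squares on the log scale is the conventional, scale-
  appropriate fit for hazards spanning two orders of magnitude.
  Linear-in-parameters families are solved exactly by `lm()`; the rest use
  Nelder–Mead from deterministic data-driven starting values (a logit-linear
  or Gompertz pre-fit), restarted once, so the fit is reproducible bit for bit.
- **Near-tie rule.** Criteria within `1e-8 + 1e-6 * best` of the minimum are
  tied, and the earliest family in registry order wins. The registry orders
  simpler families ahead of the families that nest them (Makeham, Perks and
  log-quadratic each nest simpler members), so a three-parameter
  generalisation cannot displace the generating family on a machine-precision
  margin. Without this rule, selection among nested families would be decided
  by optimizer noise.
- **Splice and blend.** By default observed rates are kept throughout the fit
  window and the model takes over one age past it, up to `max_age` 100
  (extensible to 110 when integrating oracles). A linear-in-log ramp over 5
  ages (configurable; 0 gives a sharp splice) prevents an artificial jump in
  `q_x` from propagating into the deaths column.

The default fit window is ages 65–84, bracketing the range where subgroup data
are still usable but no longer reliable; large populations with good
oldest-old data may prefer 75–94 (`study_config(fit_window = )`). A
`family_overrides` option forces a named family for specific groups — e.g.
keeping a conventional family for the general population while selecting
freely for subgroups.

## Sparse-type imputation

Small disability types lack deaths at many ages. Their rates are related to
the standard (all-subgroup) table by a relational model on the logit scale:
`logit(m_x^type) = a + b * logit(m_x^std)`, fitted by unweighted least squares
over the observed ages (an exposure-weighted option exists). We read the
"regression between the two rate series" as this logit-linear link because
rates are proportions: the link is invertible, maps predictions back into
(0, 1), and in the small-rate regime `logit ~ log`, so a constant hazard ratio
`r` appears as slope 1, intercept `log r`. With fewer than three overlapping
ages the regression is unidentified and a constant-ratio fallback (slope fixed
at 1) is used, with a warning. Observed cells are never altered; imputation is
always per sex, since standard tables are sex-specific throughout.

Abridged (five-year) reports take survivorship, expectation and standard error
at the group-start age of the complete table — so abridged `e_x` equals the
complete-table value exactly — and sum person-years within groups. Group
starts below the registration age clamp to it (a type first registered at 12
reports groups 12–14, 15–19, …, 85+).

## Sullivan HALE

Given a per-age proportion unhealthy `pi_x` under some definition (e.g.
claims-based hospitalisation, self-rated health, or two-week illness),
`HALE_x = sum_i L_i (1 - pi_i) / l_x` for `i >= x`, including the open
interval with its own prevalence. Two identities are exact and tested at
`1e-12`: `pi == 0` gives `HALE == LE`, and constant `pi == c` gives
`HALE == (1 - c) LE`.

Age-banded survey prevalence is expanded to single ages as a step function by
default (assumption-light, reproducible); a monotone-spline alternative sits
behind a flag. Ages below the youngest band inherit its value with a warning,
because registration ages can precede the first survey bin. The schedule
abstraction accepts either person-proportions or mean day-fractions — both are
values in \[0, 1\] multiplying person-years — so definitions built from
"percentage of days sick" work unchanged.

Confidence intervals adapt the Chiang variance by replacing the bracket with
`(1 - a_j)(1 - pi_j) + HALE_{j+1}`, treating prevalence as fixed. That default
matches how near-degenerate claims-based HALE intervals behave in practice,
where the mortality term dominates; an optional binomial prevalence-variance
term `sum (L_j/l_x)^2 pi_j (1 - pi_j) / n_j` can be switched on when
denominators are available.

## The synthetic generator

Restricted registry and claims microdata cannot ship with the package, so
`synthetic_scenario()` generates registries with known truth:

- a Gompertz–Makeham hazard `mu(x) = A + B c^x` with proportional subgroup
  hazards; the cumulative hazard is closed-form, so the oracle
  `analytic_le()` only carries quadrature error (composite Simpson, 0.05-year
  grid, horizon `max_age + 10`);
- per-age true rates taken as the exact central death rate of the continuous
  hazard over each interval (not the hazard at the integer age — at realistic
  Gompertz slopes that shortcut alone biases table LE by ~0.5 years against
  the continuous truth);
- stationary-population exposure (proportional to the survival integral,
  scaled by `exposure_scale`), Poisson death counts given exposure, and a
  seeded blanked subset of ages emulating sparse types;
- logistic prevalence-by-age curves per definition,
  `pi(x) = floor + (ceiling - floor)/(1 + exp(-slope (x - midpoint)))`.

Defaults were calibrated once: the baseline hazard (`A = 3e-4`,
`B = 1.507e-5`, `c = 1.105`) anchors the reference male LE at birth near 81.3
years, the order of a contemporary low-mortality male population; the default
disabled hazard ratio 3.14 yields an LE near 68.5 years, the order observed in
registered disabled populations; and the three default prevalence curves put
the claims-based HALE above the two survey-based ones at birth, reproducing
the characteristic ordering. Exposure scales (1.5e6 and 1e5 person-years per
unit of survival integral) match the magnitudes of a national population and a
registry aggregated over five years.

What the generator does **not** emulate: a real age pyramid (exposure is
stationary by construction, though a custom vector can be supplied), cohort
effects and mortality trend (the pipeline is period-only), survey nonresponse,
delayed death registration, and non-proportional subgroup hazards. Passing
recovery tests therefore demonstrates correctness of the estimation chain
under the stated generating process, not robustness to these real-data
features.

## Test and script problem sizes

The suites run synthetic registries at 101 ages with the default exposure
scales; interval calibration uses 500 replicates of a binomial death process
with cohorts of 20,000 per age (built without graduation, since Chiang's
estimator assumes independent binomial `q_x` and graduation would distort
calibration for reasons outside the estimator); extension recovery uses
noise-free 25-age windows for each of the nine families; imputation recovery
uses nine subgroup types with hazard ratios 0.8–4.0 and 20–50% of ages masked.
These sizes make the whole suite run in seconds while keeping Monte Carlo
error well inside the asserted tolerances.

## Known limitations

- Period tables only; no cohort or projected tables, and no estimation of
  delayed death reporting.
- The nine-family registry is a documented stand-in for whichever exact
  collection a given national office uses; the `families` argument exists
  precisely so the published set can be dropped in.
- The imputation link assumes a stable logit-linear relation across ages; a
  type whose excess hazard is strongly age-varying will be imputed with bias
  (the mask-and-recover tests bound this under proportional hazards only).
- HALE treats prevalence as exogenous and fixed by default; health-mortality
  correlation at the individual level is outside the Sullivan framework.
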