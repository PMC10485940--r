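# lifehale

Life tables and healthy life expectancy for subpopulations.

`lifehale` implements the full estimation chain used to compare the life
expectancy (LE) and healthy life expectancy (HALE) of registered subpopulations
— such as people with disabilities, by type and severity — against a reference
population, from raw age–sex schedules of person-years and death counts. It is
aimed at epidemiologists and demographers working with aggregated registry or
claims data, where subgroups are small, oldest-old rates are unreliable, and
some age cells are missing entirely.

## What it computes

Starting from a schedule of exposures and deaths for one group and sex:

1. **Central death rates** m_x = D_x / person-years, with zero-exposure ages
   flagged missing rather than zero.
2. **Death probabilities** q_x = m_x / (1 + (1 − a_x) m_x), where the
   separation factor a_x is 0.05 (males) / 0.13 (females) at age 0 and 0.5
   afterwards.
3. **Graduation** of q_x by a symmetric moving-weight formula in the Greville
   tradition (local least-squares cubic, 9th-order window by default), exact on
   cubic polynomials.
4. **Old-age extension**: nine parametric hazard families (Gompertz, Weibull,
   Kannisto, Heligman–Pollard old-age term, Denuit–Goderniaux, Coale–Kisker,
   Makeham, log-quadratic, Perks) are fitted by least squares of log m_x on a
   configurable window; the best-fitting family replaces the unreliable
   oldest-old rates up to age 100, with a log-linear splice ramp.
5. **Life-table recursion** d_x = l_x q_x, l_{x+1} = l_x − d_x,
   L_x = l_{x+1} + a_x d_x, T_x = Σ_{y≥x} L_y, e_x = T_x / l_x, with
   exponential closure of the open interval (L_ω = l_ω / m_ω).
6. **Chiang confidence intervals**: S²_{p_j} = q_j²(1 − q_j)/D_j and
   S²_{e_x} = l_x^{-2} Σ_{j≥x} l_j² [(1 − a_j) + e_{j+1}]² S²_{p_j},
   interval e_x ± 1.96 S_{e_x}.
7. **Sparse-type imputation**: missing subgroup rates are filled through a
   logit-scale relational link, logit(m_x^{type}) = a + b·logit(m_x^{standard}),
   fitted on the observed ages.
8. **Sullivan HALE** under any number of prevalence definitions:
   HALE_x = Σ_{i≥x} L_i (1 − π_i) / l_x, with Chiang-type intervals.
9. **Abridged reports and difference tables**: five-year age groups (first age,
   then 5, 10, …, 85+) and reference-minus-group gaps in LE and HALE at every
   report age.

A synthetic-registry generator with a known Gompertz–Makeham ground truth
(`synthetic_scenario()`, `simulate_schedule()`, `simulate_prevalence()`,
`analytic_le()`) stands in for restricted registry/claims microdata, so every
stage has an end-to-end recovery test.

## Worked example

Simulate a reference population and a disabled subgroup from the calibrated
default scenario, run the whole pipeline, and read off at-birth results:

```r
library(lifehale)
library(dplyr)

sc <- synthetic_scenario(seed = 2024)
mortality <- bind_rows(
  simulate_schedule(sc, "reference"),
  simulate_schedule(sc, "disabled")
)
prevalence <- bind_rows(lapply(c("reference", "disabled"), function(g) {
  p <- simulate_prevalence(sc, g, "NHIS")
  tibble(definition = "NHIS", sex = "male", group_id = g,
         age_lo = p$age, age_hi = p$age, pi = p$pi)
}))

study <- run_study(mortality, reference_group = "reference",
                   standard_group = "disabled", prevalence = prevalence)

study$abridged |> filter(age_start == 0) |>
  select(group_id, ex, lo95, hi95, hale_NHIS)
#> # A tibble: 2 × 5
#>   group_id     ex  lo95  hi95 hale_NHIS
#>   <chr>     <dbl> <dbl> <dbl>     <dbl>
#> 1 reference  81.3  81.3  81.3      73.6
#> 2 disabled   68.6  68.5  68.7      64.9

study$differences |> filter(age == 0) |> select(group_id, metric, diff)
#> # A tibble: 4 × 3
#>   group_id  metric     diff
#>   <chr>     <chr>     <dbl>
#> 1 disabled  ex        12.7
#> 2 reference ex         0
#> 3 disabled  hale_NHIS  8.63
#> 4 reference hale_NHIS  0
```

The disabled group's life expectancy at birth is 68.6 years against 81.3 for
the reference — a 12.7-year gap, within Monte Carlo noise of the scenario's
analytic truth (12.79 years, from `analytic_le()`). The `hale_NHIS` column is
the claims-style healthy life expectancy; its gap is smaller here because both
groups share the same prevalence curve in this scenario. `study$extension`
records which old-age family was selected per group, and
`autoplot(study$tables[["male.disabled"]])` draws the expectancy profile with
its confidence band.

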