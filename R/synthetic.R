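#' Define a synthetic registry scenario with known ground truth
#'
#' Emulates the structure of an aggregated disability registry: a
#' Gompertz-Makeham baseline hazard `mu(x) = A + B * c^x`, proportional
#' subgroup hazards, group-specific first (registration) ages, stationary
#' person-years of exposure, Poisson death counts, seeded missing age cells
#' for sparse subgroups, and age-increasing logistic unhealthy-prevalence
#' curves per definition. Every quantity the pipeline estimates has a
#' closed-form or numerically integrable truth here, so recovery can be
#' checked end to end without the restricted data.
#'
#' Default baseline parameters are calibrated so the reference male cohort
#' has a life expectancy at birth of about 81.3 years (the order of a
#' contemporary low-mortality male population); the default `disabled` group
#' hazard ratio is calibrated to a life expectancy near 68.5 years, the
#' order observed for registered disabled populations.
#'
#' @param makeham_A Age-independent background hazard (per year).
#' @param gompertz_B,gompertz_c Senescent hazard parameters.
#' @param groups A tibble with columns `group_id, sex, hazard_ratio,
#'   first_age, exposure_scale, missing_age_fraction`.
#' @param prevalence_curves A tibble with columns `definition, floor,
#'   ceiling, midpoint, slope` defining logistic prevalence-by-age curves
#'   `pi(x) = floor + (ceiling - floor) / (1 + exp(-slope * (x - midpoint)))`.
#' @param max_age Oldest simulated age (default 100).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `"synthetic_scenario"`.
#' @export
synthetic_scenario <- function(makeham_A = 3e-4,
                               gompertz_B = 1.507e-5,
                               gompertz_c = 1.105,
                               groups = default_groups(),
                               prevalence_curves = default_prevalence_curves(),
                               max_age = 100L,
                               seed = 1L) {
  groups <- tibble::as_tibble(groups)
  required <- c("group_id", "sex", "hazard_ratio", "first_age",
                "exposure_scale", "missing_age_fraction")
  if (!all(required %in% names(groups))) {
    rlang::abort(paste0("groups must have columns: ", paste(required, collapse = ", ")),
      class = "lifehale_validation_error"
    )
  }
  if (makeham_A < 0 || gompertz_B <= 0 || gompertz_c <= 1) {
    rlang::abort("need A >= 0, B > 0, c > 1", class = "lifehale_validation_error")
  }
  if (any(groups$hazard_ratio <= 0) ||
    any(groups$missing_age_fraction < 0 | groups$missing_age_fraction >= 1)) {
    rlang::abort("hazard ratios must be positive and missing fractions in [0, 1)",
      class = "lifehale_validation_error"
    )
  }
  structure(
    list(
      makeham_A = makeham_A, gompertz_B = gompertz_B, gompertz_c = gompertz_c,
      groups = groups, prevalence_curves = tibble::as_tibble(prevalence_curves),
      max_age = as.integer(max_age), seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}

#' @rdname synthetic_scenario
#' @export
default_groups <- function() {
  tibble::tribble(
    ~group_id,   ~sex,   ~hazard_ratio, ~first_age, ~exposure_scale, ~missing_age_fraction,
    "reference", "male", 1.0,           0L,         1.5e6,           0,
    "disabled",  "male", 3.14,          0L,         1.0e5,           0
  )
}

#' @rdname synthetic_scenario
#' @export
default_prevalence_curves <- function() {
  tibble::tribble(
    ~definition, ~floor, ~ceiling, ~midpoint, ~slope,
    "NHIS",      0.010,  0.95,     84,        0.100,
    "PH",        0.050,  0.95,     78,        0.095,
    "DF",        0.080,  0.95,     76,        0.090
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> mu(x) = %.3g + %.3g * %.4f^x, max_age %d, seed %d\n",
    x$makeham_A, x$gompertz_B, x$gompertz_c, x$max_age, x$seed
  ))
  print(x$groups)
  invisible(x)
}

scenario_group <- function(scenario, group) {
  g <- dplyr::filter(scenario$groups, .data$group_id == group)
  if (nrow(g) != 1) {
    rlang::abort(sprintf("group '%s' not in scenario", group),
      class = "lifehale_validation_error"
    )
  }
  g
}

# Gompertz-Makeham hazard and its exact cumulative integral.
gm_hazard <- function(scenario, hr, x) {
  hr * (scenario$makeham_A + scenario$gompertz_B * scenario$gompertz_c^x)
}

gm_cum_hazard <- function(scenario, hr, from, to) {
  lc <- log(scenario$gompertz_c)
  hr * (scenario$makeham_A * (to - from) +
    scenario$gompertz_B * (scenario$gompertz_c^to - scenario$gompertz_c^from) / lc)
}

# Survival from `from` to t (vectorised over t).
gm_survival <- function(scenario, hr, from, t) {
  exp(-gm_cum_hazard(scenario, hr, from, t))
}

#' Analytic remaining life expectancy in a scenario
#'
#' The ground-truth oracle: numeric integration (composite Simpson on a
#' 0.05-year grid) of the survival function `exp(-integral of mu)` from
#' `age` to `max_age + 10`. The cumulative Gompertz-Makeham hazard is exact,
#' so the only error is the quadrature itself.
#'
#' @param scenario A `"synthetic_scenario"`.
#' @param group A group id in the scenario.
#' @param age Age at which remaining life expectancy is evaluated.
#' @return Years of remaining life expectancy.
#' @export
analytic_le <- function(scenario, group, age = NULL) {
  g <- scenario_group(scenario, group)
  if (is.null(age)) age <- g$first_age
  horizon <- scenario$max_age + 10
  simpson_integral(
    function(t) gm_survival(scenario, g$hazard_ratio, age, t),
    age, horizon, n = 4L * ceiling(horizon - age) * 5L
  )
}

# Composite Simpson with an even number of panels.
simpson_integral <- function(f, a, b, n = 400L) {
  if (n %% 2 == 1) n <- n + 1L
  x <- seq(a, b, length.out = n + 1)
  y <- f(x)
  h <- (b - a) / n
  h / 3 * (y[1] + y[n + 1] + 4 * sum(y[seq(2, n, 2)]) + 2 * sum(y[seq(3, n - 1, 2)]))
}

#' True per-age central death rates and stationary exposure
#'
#' The generator's truth at the single-age resolution the pipeline sees:
#' `mx` is the exact central death rate of the continuous hazard over
#' `[x, x+1)` — deaths over person-years within the interval — and
#' `exposure` is the stationary-population person-years, proportional to the
#' survival integral over the interval scaled by the group's
#' `exposure_scale`.
#'
#' @inheritParams analytic_le
#' @return A tibble `age, mu, mx, exposure` over the group's age range.
#' @export
true_schedule <- function(scenario, group) {
  g <- scenario_group(scenario, group)
  ages <- seq(g$first_age, scenario$max_age)
  S_lo <- gm_survival(scenario, g$hazard_ratio, g$first_age, ages)
  S_hi <- gm_survival(scenario, g$hazard_ratio, g$first_age, ages + 1)
  person_years <- purrr::map_dbl(ages, function(a) {
    simpson_integral(
      function(t) gm_survival(scenario, g$hazard_ratio, g$first_age, t),
      a, a + 1, n = 20L
    )
  })
  tibble::tibble(
    age = ages,
    mu = gm_hazard(scenario, g$hazard_ratio, ages),
    mx = (S_lo - S_hi) / person_years,
    exposure = g$exposure_scale * person_years
  )
}

#' Simulate a mortality schedule from a scenario
#'
#' Person-years are the stationary exposure of [true_schedule()]; death
#' counts are Poisson with mean `exposure * mx` (exposure-based counts, as
#' in aggregated registry data). A seeded random subset of ages — the
#' group's `missing_age_fraction`, never including the first age — is
#' blanked to `NA` to emulate sparse subgroup reporting. Fully deterministic
#' given the scenario seed.
#'
#' @inheritParams analytic_le
#' @return A validated mortality schedule tibble.
#' @export
simulate_schedule <- function(scenario, group) {
  g <- scenario_group(scenario, group)
  truth <- true_schedule(scenario, group)
  gi <- match(group, scenario$groups$group_id)
  out <- with_local_seed(scenario$seed + 1000L * gi, {
    deaths <- stats::rpois(nrow(truth), truth$exposure * truth$mx)
    py <- truth$exposure
    if (g$missing_age_fraction > 0) {
      candidates <- truth$age[-1]
      n_blank <- floor(g$missing_age_fraction * length(truth$age))
      blank <- sample(candidates, min(n_blank, length(candidates)))
      deaths[truth$age %in% blank] <- NA_real_
      py[truth$age %in% blank] <- NA_real_
    }
    tibble::tibble(
      group_id = group, sex = g$sex, age = truth$age,
      person_years = py, deaths = as.numeric(deaths)
    )
  })
  mortality_schedule(out)
}

#' Simulate an unhealthy-prevalence schedule
#'
#' Logistic prevalence-by-age under one definition:
#' `pi(x) = floor + (ceiling - floor) / (1 + exp(-slope * (x - midpoint)))`.
#' With `denom` supplied, observed proportions are binomially sampled around
#' the curve; otherwise the curve itself is returned (the deterministic
#' truth).
#'
#' @inheritParams analytic_le
#' @param definition A definition present in the scenario's
#'   `prevalence_curves`.
#' @param denom Optional respondents per age for binomial sampling.
#' @return A tibble `definition, sex, group_id, age, pi, denom`.
#' @export
simulate_prevalence <- function(scenario, group, definition, denom = NULL) {
  g <- scenario_group(scenario, group)
  curve <- dplyr::filter(scenario$prevalence_curves, .data$definition == !!definition)
  if (nrow(curve) != 1) {
    rlang::abort(sprintf("definition '%s' not in scenario", definition),
      class = "lifehale_validation_error"
    )
  }
  ages <- seq(g$first_age, scenario$max_age)
  pi_x <- curve$floor + (curve$ceiling - curve$floor) /
    (1 + exp(-curve$slope * (ages - curve$midpoint)))
  if (!is.null(denom)) {
    gi <- match(group, scenario$groups$group_id)
    pi_x <- with_local_seed(scenario$seed + 2000L * gi, {
      stats::rbinom(length(ages), denom, pi_x) / denom
    })
  }
  tibble::tibble(
    definition = definition, sex = g$sex, group_id = group,
    age = ages, pi = pi_x, denom = if (is.null(denom)) NA_real_ else denom
  )
}

# Run code under a temporary RNG state so simulation is reproducible without
# clobbering the caller's stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
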