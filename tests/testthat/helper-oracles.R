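# Independent oracles used across the suite. These deliberately avoid the
# package's own recursion/vectorised code paths: plain loops and fine-grid
# quadrature only.

# Life expectancy at the first age by explicit survival-product summation,
# same closure convention as the tables (open interval L = l / m).
brute_force_e0 <- function(qx, ax, mx_at_closure) {
  n <- length(qx)
  qx[n] <- 1
  l <- 1
  total <- 0
  for (i in seq_len(n)) {
    d <- l * qx[i]
    l_next <- l - d
    L <- if (i < n) l_next + ax[i] * d else l / mx_at_closure
    total <- total + L
    l <- l_next
  }
  total
}

# Remaining LE at `age` under a piecewise-constant hazard: rate m_step[i] on
# [ages[i], ages[i]+1), integrated on a fine grid to the end of the last
# interval.
piecewise_hazard_le <- function(ages, m_step, age, dt = 0.01) {
  t_grid <- seq(age, max(ages) + 1, by = dt)
  m_at <- m_step[findInterval(pmin(t_grid[-length(t_grid)], max(ages)), ages)]
  S <- exp(-cumsum(m_at * dt))
  sum(c(1, S[-length(S)]) + S) * dt / 2
}

# Local least-squares cubic graduation, fitted with lm() per window: the
# reference implementation the moving-weight version must agree with.
local_cubic_oracle <- function(y, order) {
  n <- length(y)
  h <- (order - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    df <- data.frame(x = idx - i, y = y[idx])
    out[i] <- unname(predict(lm(y ~ x + I(x^2) + I(x^3), data = df),
      newdata = data.frame(x = 0)
    ))
  }
  out
}

# A bare schedule tibble around given per-age rates (exposure-consistent
# deaths), for tests that want exact noise-free inputs.
schedule_from_mx <- function(mx, ages, sex = "male", group_id = "toy",
                             exposure = 1e6) {
  tibble::tibble(
    group_id = group_id, sex = sex, age = ages,
    person_years = rep(exposure, length(ages)),
    deaths = exposure * mx
  )
}

# Published at-birth life expectancy and claims-based HALE (years) for the
# Korean registered-disability study population, 2014-2018; used as keyed-in
# inputs for the difference-report worked examples.
published_birth_values <- function() {
  tibble::tribble(
    ~group_id,      ~sex,     ~age, ~ex,    ~hale_NHIS,
    "non_disabled", "male",   0,    81.32,  73.32,
    "disabled_all", "male",   0,    68.54,  58.98,
    "mild",         "male",   0,    73.87,  65.43,
    "severe",       "male",   0,    61.53,  50.48,
    "non_disabled", "female", 0,    87.38,  75.58,
    "disabled_all", "female", 0,    71.43,  59.24,
    "mild",         "female", 0,    78.25,  67.51,
    "severe",       "female", 0,    62.41,  49.72
  )
}

# Noise-free mx series from each extension family on a given age grid, with
# parameters in realistic old-age ranges; the generating truth for recovery
# tests, kept separate from the fitting code.
family_truth_mx <- function(family, ages) {
  switch(family,
    gompertz = 2e-5 * 1.1^ages,
    weibull = (0.05 / 75^6) * ages^6,
    kannisto = {
      u <- 1e-5 * 1.12^ages
      u / (1 + u)
    },
    heligman_pollard = {
      u <- 1.5e-5 * 1.115^ages
      u / (1 + u / 2)
    },
    denuit_goderniaux = exp(-0.0015 * (ages - 130)^2),
    coale_kisker = exp(-15.95 + 0.2 * ages - 5e-4 * ages^2),
    makeham = 0.01 + 2e-5 * 1.1^ages,
    log_quadratic = exp(-7.885 + 0.04359 * ages + 2.726e-4 * ages^2),
    perks = {
      u <- 1e-5 * 1.13^ages
      u / (1 + 4 * u)
    },
    stop("unknown family")
  )
}

# Extend a family's truth beyond the observed ages and return remaining LE at
# `age` by piecewise-constant-hazard integration to age 110.
family_truth_le <- function(family, obs_ages, age, max_age = 110) {
  ages <- min(obs_ages):max_age
  piecewise_hazard_le(ages, family_truth_mx(family, ages), age)
}
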