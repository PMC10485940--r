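#' Separation factors by age and sex
#'
#' The separation factor `ax` is the average fraction of the year lived by
#' those dying within the age interval. Infant deaths cluster early in the
#' first year, so age 0 uses the Coale-Demeny indicator values 0.05 (male) and
#' 0.13 (female); every later age uses the midpoint 0.5, consistent with the
#' midpoint person-years formula `Lx = (lx + lx+1) / 2`.
#'
#' @param sex `"male"` or `"female"`.
#' @param ages Integer vector of contiguous ages.
#' @return Numeric vector of `ax` values aligned to `ages`.
#' @export
assign_ax <- function(sex, ages) {
  if (!sex %in% c("male", "female")) {
    rlang::abort(sprintf("unknown sex label '%s'", sex),
      class = "lifehale_validation_error"
    )
  }
  a0 <- if (sex == "male") 0.05 else 0.13
  ifelse(ages == 0L, a0, 0.5)
}

#' Convert central death rates to death probabilities
#'
#' Uses the standard actuarial identity `qx = mx / (1 + (1 - ax) * mx)`,
#' capped at 1. At extreme rates the uncapped expression tends to
#' `1 / (1 - ax)`, which exceeds 1, hence the cap.
#'
#' @param mx Central death rate(s), `>= 0`.
#' @param ax Separation factor(s) in `[0, 1]`.
#' @return Death probabilities in `[0, 1]`; `NA` rates propagate.
#' @export
mx_to_qx <- function(mx, ax) {
  ok <- is.na(mx) | mx >= 0
  if (!all(ok)) {
    rlang::abort("mx must be non-negative", class = "lifehale_validation_error")
  }
  if (any(ax < 0 | ax > 1)) {
    rlang::abort("ax must lie in [0, 1]", class = "lifehale_validation_error")
  }
  pmin(mx / (1 + (1 - ax) * mx), 1)
}

# Inverse of mx_to_qx, used when a binomial death probability must be turned
# back into a central rate (e.g. simulation-based coverage checks).
qx_to_mx <- function(qx, ax) {
  qx / (1 - (1 - ax) * qx)
}

#' Life-table recursion from death probabilities
#'
#' The classical single-year recursion: `dx = lx * qx`, `lx+1 = lx - dx`,
#' `Lx = lx+1 + ax * dx` (the midpoint formula when `ax = 0.5`),
#' `Tx = sum(Ly, y >= x)` and `ex = Tx / lx`. The final age is the open-ended
#' interval: its death probability is forced to 1 and its person-years are
#' closed exponentially as `L = l / m` using the central rate at the closure
#' age.
#'
#' @param qx Death probabilities in `[0, 1]`, one per age; the last value is
#'   treated as 1 regardless.
#' @param ax Separation factors aligned to `qx`.
#' @param ages Integer ages aligned to `qx`.
#' @param radix Starting cohort size `l` at the first age (default 100,000).
#' @param mx_at_closure Central death rate in the open interval, used for its
#'   person-years; if `NA` or 0 the open interval contributes `ax * l` years.
#' @return A tibble with columns `age, ax, qx, lx, dx, Lx, Tx, ex`.
#' @export
build_life_table <- function(qx, ax, ages, radix = 1e5, mx_at_closure = NA_real_) {
  if (radix <= 0) {
    rlang::abort("radix must be positive", class = "lifehale_validation_error")
  }
  if (any(qx < 0 | qx > 1, na.rm = TRUE) || anyNA(qx)) {
    rlang::abort("qx must be complete and lie in [0, 1]",
      class = "lifehale_validation_error"
    )
  }
  n <- length(qx)
  qx[n] <- 1
  lx <- radix * cumprod(c(1, 1 - qx[-n]))
  dx <- lx * qx
  Lx <- c(lx[-1], 0) + ax * dx
  if (is.finite(mx_at_closure) && mx_at_closure > 0) {
    Lx[n] <- lx[n] / mx_at_closure
  }
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, NA_real_)
  tibble::tibble(age = ages, ax = ax, qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex)
}

#' Chiang confidence intervals for life expectancy
#'
#' Chiang's variance of `ex` propagates the binomial variation of each death
#' probability:
#' `S2_p[j] = qx[j]^2 * (1 - qx[j]) / D[j]` and
#' `S2_ex[x] = sum(l[j]^2 * ((1 - a[j]) + e[j+1])^2 * S2_p[j], j >= x) / l[x]^2`,
#' with the 95% interval `ex +/- 1.96 * se`. Ages with no observed deaths but
#' a non-degenerate `qx` (typically model-extended old ages) contribute zero
#' variance; a single collapsed warning reports them.
#'
#' @param lifetable A tibble from [build_life_table()] (or [life_table()]).
#' @param deaths Observed death counts aligned to the table's ages (`NA`
#'   where unobserved).
#' @param literal_bracket If `TRUE`, use the unsquared bracket
#'   `(1 - a) + e[j+1]` — a sensitivity variant of the estimator, not the
#'   default.
#' @param quiet Suppress the zero-deaths warning.
#' @return The table with `se_ex`, `lo95`, `hi95` columns appended.
#' @export
chiang_ci <- function(lifetable, deaths, literal_bracket = FALSE, quiet = FALSE) {
  lt <- lifetable
  n <- nrow(lt)
  stopifnot(length(deaths) == n)
  q <- lt$qx
  mortal <- q > 0 & q < 1
  d <- ifelse(is.na(deaths), 0, deaths)
  no_info <- mortal & d <= 0
  if (any(no_info) && !quiet) {
    rlang::warn(sprintf(
      "%d age(s) with qx in (0,1) but no observed deaths contribute zero variance (ages %s%s)",
      sum(no_info), paste(utils::head(lt$age[no_info], 5), collapse = ", "),
      if (sum(no_info) > 5) ", ..." else ""
    ))
  }
  s2p <- ifelse(mortal & d > 0, q^2 * (1 - q) / d, 0)
  e_next <- c(lt$ex[-1], 0)
  e_next[is.na(e_next)] <- 0
  bracket <- (1 - lt$ax) + e_next
  if (!literal_bracket) bracket <- bracket^2
  contrib <- lt$lx^2 * bracket * s2p
  s2ex <- ifelse(lt$lx > 0, rev(cumsum(rev(contrib))) / lt$lx^2, NA_real_)
  dplyr::mutate(
    lt,
    se_ex = sqrt(s2ex),
    lo95 = .data$ex - 1.96 * .data$se_ex,
    hi95 = .data$ex + 1.96 * .data$se_ex
  )
}

#' Complete life table from a mortality schedule
#'
#' The full standard-table chain for one group and sex: central death rates,
#' separation factors, death probabilities, optional graduation of `qx`
#' ([greville_smooth()], 9th order by default), the life-table recursion and
#' Chiang 95% confidence intervals. Old-age extension, when wanted, is applied
#' to the schedule beforehand with [extend_mortality()].
#'
#' @param data A mortality schedule; if it already carries an `mx` column
#'   (e.g. from [extend_mortality()] or [impute_rates()]) those rates are
#'   used, otherwise rates are computed from deaths and exposure. Rates must
#'   be complete; impute gaps first.
#' @param radix Starting cohort size (default 100,000).
#' @param smooth_order Odd graduation window for `qx`, or `NULL` to skip
#'   graduation.
#' @param ci Compute Chiang confidence intervals (default `TRUE`).
#' @param literal_bracket,quiet Passed to [chiang_ci()].
#' @return A tibble of class `"lifetable"` with columns
#'   `age, mx, ax, qx, lx, dx, Lx, Tx, ex, se_ex, lo95, hi95` plus the
#'   carried `deaths`, and attributes `group_id`, `sex`, `radix`,
#'   `closure_age`.
#' @examples
#' sched <- simulate_schedule(synthetic_scenario(seed = 1), "reference")
#' lt <- life_table(sched)
#' head(lt)
#' @export
life_table <- function(data, radix = 1e5, smooth_order = 9, ci = TRUE,
                       literal_bracket = FALSE, quiet = FALSE) {
  if (!"mx" %in% names(data)) {
    data <- compute_mx(data)
  } else {
    data <- dplyr::arrange(tibble::as_tibble(data), .data$age)
  }
  if (anyNA(data$mx)) {
    rlang::abort(
      "schedule has missing rates; impute them first (see impute_rates())",
      class = "lifehale_validation_error"
    )
  }
  sex <- data$sex[1]
  ages <- data$age
  ax <- assign_ax(sex, ages)
  qx <- mx_to_qx(data$mx, ax)
  if (!is.null(smooth_order)) {
    # closure q is forced to 1 later; keep it out of the graduation window
    qx[-length(qx)] <- greville_smooth(qx[-length(qx)], order = smooth_order)
  }
  lt <- build_life_table(qx, ax, ages,
    radix = radix,
    mx_at_closure = data$mx[length(ages)]
  )
  lt <- dplyr::mutate(lt,
    mx = data$mx,
    deaths = if ("deaths" %in% names(data)) data$deaths else NA_real_,
    .after = "age"
  )
  if (ci) {
    lt <- chiang_ci(lt, lt$deaths, literal_bracket = literal_bracket, quiet = quiet)
  }
  structure(
    lt,
    group_id = data$group_id[1],
    sex = sex,
    radix = radix,
    closure_age = ages[length(ages)],
    class = c("lifetable", class(lt))
  )
}

#' Write a life table to CSV
#'
#' Full double precision; any report rounding happens at the reporting layer,
#' never here.
#'
#' @param lifetable A `lifetable` tibble.
#' @param path Output file.
#' @export
write_lifetable_csv <- function(lifetable, path) {
  cols <- intersect(
    c("age", "mx", "ax", "qx", "lx", "dx", "Lx", "Tx", "ex", "se_ex", "lo95", "hi95"),
    names(lifetable)
  )
  readr::write_csv(dplyr::select(tibble::as_tibble(lifetable), dplyr::all_of(cols)), path)
  invisible(path)
}
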