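#' Registry of old-age mortality model families
#'
#' Nine parametric families conventionally used to extend central death rates
#' `mx` beyond the ages where registry data are reliable. Each family is
#' defined by an analytic formula for the hazard-scale rate `m(x)`:
#'
#' * `gompertz`: `m = B * c^x` — exponential senescence.
#' * `weibull`: `m = A * x^B` — power-law ageing.
#' * `kannisto`: `m = B*c^x / (1 + B*c^x)` — logistic deceleration with
#'   asymptote 1.
#' * `heligman_pollard`: the old-age term `q/(1-q) = G*H^x` of the
#'   Heligman-Pollard law, expressed on the rate scale (with midpoint
#'   separation) as `m = G*H^x / (1 + G*H^x / 2)`.
#' * `denuit_goderniaux`: log-quadratic with closure constraints
#'   `m(130) = 1`, `m'(130) = 0`, i.e. `log m = cc * (x - 130)^2`.
#' * `coale_kisker`: log-quadratic with the constraint that the rate reaches
#'   a fixed value at age 110 (1.0 for males, 0.8 for females) — the constant
#'   deceleration of the rate of mortality increase.
#' * `makeham`: `m = A + B * c^x` — Gompertz plus age-independent background.
#' * `log_quadratic`: unconstrained `log m = a + b*x + cc*x^2`.
#' * `perks`: `m = B*c^x / (1 + D*c^x)` — logistic with free asymptote `B/D`.
#'
#' All families are fitted by least squares of `log m` on the fit window (the
#' common criterion that makes them comparable); linear-in-parameters members
#' are solved exactly, the rest by Nelder-Mead from deterministic data-driven
#' starting points. The registry order doubles as the near-tie priority in
#' [select_extension()]: simpler families precede the families that nest them,
#' so a nested generalisation cannot displace the generating family on a
#' machine-precision margin.
#'
#' @param families Optional character subset to retain, in registry order.
#' @return A named list of family definitions (name, number of parameters,
#'   formula text, and a fitting function).
#' @export
extension_families <- function(families = NULL) {
  reg <- list(
    gompertz = list(
      npar = 2, formula = "m = B * c^x",
      fit = function(x, logm, sex) {
        co <- stats::coef(stats::lm(logm ~ x))
        params <- c(B = exp(unname(co[1])), c = exp(unname(co[2])))
        list(params = params, predict = function(z) log(params["B"]) + z * log(params["c"]))
      }
    ),
    weibull = list(
      npar = 2, formula = "m = A * x^B",
      fit = function(x, logm, sex) {
        stopifnot(all(x > 0))
        co <- stats::coef(stats::lm(logm ~ log(x)))
        params <- c(A = exp(unname(co[1])), B = unname(co[2]))
        list(params = params, predict = function(z) log(params["A"]) + params["B"] * log(z))
      }
    ),
    kannisto = list(
      npar = 2, formula = "m = B*c^x / (1 + B*c^x)",
      fit = function(x, logm, sex) {
        m <- pmin(exp(logm), 1 - 1e-9)
        co <- stats::coef(stats::lm(stats::qlogis(m) ~ x))
        pred <- function(th, z) {
          u <- exp(th[1] + z * th[2])
          log(u) - log1p(u)
        }
        th <- refine_fit(c(unname(co[1]), unname(co[2])), pred, x, logm)
        params <- c(B = exp(th[1]), c = exp(th[2]))
        list(params = params, predict = function(z) pred(th, z))
      }
    ),
    heligman_pollard = list(
      npar = 2, formula = "m = G*H^x / (1 + G*H^x/2)",
      fit = function(x, logm, sex) {
        m <- pmin(exp(logm), 2 - 1e-9)
        u <- m / (1 - m / 2)
        co <- stats::coef(stats::lm(log(u) ~ x))
        pred <- function(th, z) {
          u <- exp(th[1] + z * th[2])
          log(u) - log1p(u / 2)
        }
        th <- refine_fit(c(unname(co[1]), unname(co[2])), pred, x, logm)
        params <- c(G = exp(th[1]), H = exp(th[2]))
        list(params = params, predict = function(z) pred(th, z))
      }
    ),
    denuit_goderniaux = list(
      npar = 1, formula = "log m = cc * (x - 130)^2, m(130)=1, m'(130)=0",
      fit = function(x, logm, sex) {
        w <- (x - 130)^2
        cc <- sum(w * logm) / sum(w^2)
        params <- c(cc = cc)
        list(params = params, predict = function(z) cc * (z - 130)^2)
      }
    ),
    coale_kisker = list(
      npar = 2, formula = "log m = a + b*x + cc*x^2, m(110) = 1 (M) / 0.8 (F)",
      fit = function(x, logm, sex) {
        mstar <- if (identical(sex, "female")) 0.8 else 1.0
        y <- logm - log(mstar)
        x1 <- x - 110
        x2 <- x^2 - 110^2
        co <- stats::coef(stats::lm(y ~ 0 + x1 + x2))
        b <- unname(co[1])
        cc <- unname(co[2])
        a <- log(mstar) - 110 * b - 110^2 * cc
        params <- c(a = a, b = b, cc = cc)
        list(params = params, predict = function(z) a + b * z + cc * z^2)
      }
    ),
    makeham = list(
      npar = 3, formula = "m = A + B * c^x",
      fit = function(x, logm, sex) {
        m <- exp(logm)
        A0 <- 0.5 * min(m)
        co <- stats::coef(stats::lm(log(pmax(m - A0, 1e-12)) ~ x))
        pred <- function(th, z) log(exp(th[1]) + exp(th[2] + z * th[3]))
        th <- refine_fit(c(log(A0), unname(co[1]), unname(co[2])), pred, x, logm)
        params <- c(A = exp(th[1]), B = exp(th[2]), c = exp(th[3]))
        list(params = params, predict = function(z) pred(th, z))
      }
    ),
    log_quadratic = list(
      npar = 3, formula = "log m = a + b*x + cc*x^2",
      fit = function(x, logm, sex) {
        co <- stats::coef(stats::lm(logm ~ x + I(x^2)))
        params <- c(a = unname(co[1]), b = unname(co[2]), cc = unname(co[3]))
        list(
          params = params,
          predict = function(z) params["a"] + params["b"] * z + params["cc"] * z^2
        )
      }
    ),
    perks = list(
      npar = 3, formula = "m = B*c^x / (1 + D*c^x)",
      fit = function(x, logm, sex) {
        m <- pmin(exp(logm), 1 - 1e-9)
        co <- stats::coef(stats::lm(stats::qlogis(m) ~ x))
        pred <- function(th, z) {
          th[1] + z * th[2] - log1p(exp(th[3] + z * th[2]))
        }
        th <- refine_fit(c(unname(co[1]), unname(co[2]), unname(co[1])), pred, x, logm)
        params <- c(B = exp(th[1]), c = exp(th[2]), D = exp(th[3]))
        list(params = params, predict = function(z) pred(th, z))
      }
    )
  )
  if (!is.null(families)) {
    unknown <- setdiff(families, names(reg))
    if (length(unknown) > 0) {
      rlang::abort(paste0("unknown extension families: ", paste(unknown, collapse = ", ")),
        class = "lifehale_validation_error"
      )
    }
    reg <- reg[intersect(names(reg), families)]
  }
  reg
}

# Two-stage Nelder-Mead polish of a nonlinear family from a deterministic
# start; the restart guards against premature simplex collapse.
refine_fit <- function(start, pred, x, logm) {
  sse <- function(th) {
    r <- pred(th, x) - logm
    sum(r * r)
  }
  fit <- stats::optim(start, sse, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14)
  )
  fit <- stats::optim(fit$par, sse, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-14)
  )
  fit$par
}

#' Fit one old-age extension family
#'
#' Least-squares fit of `log mx` on the fit window. Ages in the window with
#' zero or missing rates are excluded (with a warning) since the criterion
#' lives on the log scale.
#'
#' @param data A mortality schedule; rates are taken from its `mx` column or
#'   computed from deaths and exposure.
#' @param family A family name from [extension_families()].
#' @param fit_window `c(age_lo, age_hi)` of ages used for fitting.
#' @return An object of class `"extension_fit"`: family, fitted parameters,
#'   fit window, `criterion` (sum of squared log-rate errors on the window)
#'   and a rate predictor.
#' @export
fit_extension <- function(data, family, fit_window) {
  fam <- extension_families()[[family]]
  if (is.null(fam)) {
    rlang::abort(sprintf("unknown extension family '%s'", family),
      class = "lifehale_validation_error"
    )
  }
  if (!"mx" %in% names(data)) data <- compute_mx(data)
  win <- dplyr::filter(data, .data$age >= fit_window[1], .data$age <= fit_window[2])
  usable <- !is.na(win$mx) & win$mx > 0
  if (any(!usable)) {
    rlang::warn(sprintf(
      "%d age(s) in the fit window with zero or missing rates excluded", sum(!usable)
    ))
    win <- win[usable, ]
  }
  if (nrow(win) < fam$npar + 2) {
    rlang::abort(
      sprintf(
        "fit window [%d, %d] leaves %d usable ages; need at least %d for family '%s'",
        fit_window[1], fit_window[2], nrow(win), fam$npar + 2, family
      ),
      class = "lifehale_validation_error"
    )
  }
  x <- win$age
  logm <- log(win$mx)
  fit <- fam$fit(x, logm, win$sex[1])
  resid <- fit$predict(x) - logm
  structure(
    list(
      family = family,
      npar = fam$npar,
      formula = fam$formula,
      params = fit$params,
      fit_window = fit_window,
      criterion = sum(resid^2),
      predict_log_mx = fit$predict,
      data = tibble::tibble(age = x, mx = win$mx, fitted_mx = exp(fit$predict(x))),
      sex = win$sex[1],
      group_id = win$group_id[1]
    ),
    class = "extension_fit"
  )
}

#' Select the best-fitting extension family
#'
#' Fits every candidate family on the same window with the same criterion
#' (sum of squared log-rate errors) and returns the minimiser. Families whose
#' fit fails to converge or produces a non-finite criterion are excluded.
#' Criteria within `1e-8 + 1e-6 * best` of the minimum are treated as ties
#' and resolved by registry order, which places each family ahead of the
#' families that nest it — a parsimony-first rule that keeps nested
#' three-parameter members from winning on a machine-precision margin.
#'
#' @inheritParams fit_extension
#' @param families Character vector of candidate family names (default: all
#'   nine).
#' @return The winning `"extension_fit"`, with the full selection table (one
#'   row per family with its criterion) attached as the `selection` element.
#' @export
select_extension <- function(data, fit_window, families = names(extension_families())) {
  fits <- purrr::map(families, function(f) {
    tryCatch(fit_extension(data, f, fit_window), error = function(e) e)
  })
  names(fits) <- families
  ok <- purrr::map_lgl(fits, function(f) {
    inherits(f, "extension_fit") && is.finite(f$criterion) &&
      all(is.finite(f$predict_log_mx(seq(fit_window[1], fit_window[2]))))
  })
  selection <- tibble::tibble(
    family = families,
    npar = purrr::map_dbl(fits, function(f) if (inherits(f, "extension_fit")) f$npar else NA_real_),
    criterion = purrr::map_dbl(fits, function(f) {
      if (inherits(f, "extension_fit")) f$criterion else NA_real_
    }),
    converged = ok
  )
  if (!any(ok)) {
    rlang::abort(
      sprintf("no extension family converged on window [%d, %d]", fit_window[1], fit_window[2]),
      class = "lifehale_stage_error"
    )
  }
  crit <- selection$criterion
  crit[!ok] <- Inf
  best <- min(crit)
  tied <- which(crit <= best + 1e-8 + 1e-6 * best)
  chosen <- fits[[tied[1]]]
  chosen$selection <- selection
  chosen
}

#' Extend a mortality schedule with a fitted old-age model
#'
#' Keeps observed rates below `splice_age`, replaces rates at and above it by
#' the model, and appends pure extrapolation up to `max_age`. An optional
#' linear-in-log ramp over `blend_width` ages eases the transition so no
#' artificial jump in `qx` propagates into the deaths column of the table.
#' Death probabilities are recomputed downstream by [life_table()] from the
#' extended rates.
#'
#' @param data A mortality schedule (with or without an `mx` column).
#' @param fit An `"extension_fit"`.
#' @param splice_age First age taken from the model (default: one past the
#'   fit window, i.e. observed data are kept throughout the window).
#' @param max_age Last age of the extended schedule (default 100).
#' @param blend_width Ages over which observed and model log-rates are
#'   linearly mixed, starting at `splice_age`; 0 gives a sharp splice.
#' @return A schedule tibble with columns `group_id, sex, age, person_years,
#'   deaths, mx, source` where `source` is `observed`, `blend` or `model`.
#' @export
extend_mortality <- function(data, fit, splice_age = fit$fit_window[2] + 1L,
                             max_age = 100L, blend_width = 5L) {
  if (!"mx" %in% names(data)) data <- compute_mx(data)
  if (max_age < splice_age) {
    rlang::abort("max_age must be at least splice_age", class = "lifehale_validation_error")
  }
  first_age <- min(data$age)
  ages <- seq(first_age, max_age)
  out <- tibble::tibble(
    group_id = data$group_id[1], sex = data$sex[1], age = ages
  ) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(data), "age", "person_years", "deaths", "mx"),
      by = "age"
    )
  model_log <- fit$predict_log_mx(ages)
  if (any(!is.finite(model_log))) {
    rlang::abort("extension model produced non-finite rates", class = "lifehale_stage_error")
  }
  obs_log <- log(out$mx)
  w <- rep(0, length(ages))
  w[ages >= splice_age] <- 1
  if (blend_width > 0) {
    ramp <- ages >= splice_age & ages < splice_age + blend_width & is.finite(obs_log)
    w[ramp] <- (ages[ramp] - splice_age + 1) / (blend_width + 1)
  }
  new_log <- ifelse(w > 0 & is.finite(obs_log), (1 - w) * obs_log + w * model_log,
    ifelse(w > 0, model_log, obs_log)
  )
  out$mx <- exp(new_log)
  out$source <- dplyr::case_when(
    w == 0 ~ "observed",
    w < 1 ~ "blend",
    TRUE ~ "model"
  )
  # model-extended ages carry no observed counts
  out$person_years[out$source == "model" & out$age > max(data$age)] <- NA_real_
  out$deaths[out$source == "model" & out$age > max(data$age)] <- NA_real_
  out
}

#' @export
print.extension_fit <- function(x, ...) {
  cat(sprintf(
    "<extension_fit> %s (%s), window %d-%d, criterion %.4g\n",
    x$family, x$formula, x$fit_window[1], x$fit_window[2], x$criterion
  ))
  print(x$params)
  invisible(x)
}

#' Tidy an extension fit
#'
#' @param x An `"extension_fit"`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @method tidy extension_fit
#' @export
tidy.extension_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of an extension fit
#'
#' @param x An `"extension_fit"`.
#' @param ... Unused.
#' @method glance extension_fit
#' @export
glance.extension_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    npar = x$npar,
    criterion = x$criterion,
    n_ages = nrow(x$data),
    age_lo = x$fit_window[1],
    age_hi = x$fit_window[2]
  )
}

#' Plot observed versus fitted old-age log rates
#'
#' @param object An `"extension_fit"`.
#' @param max_age Oldest age to extrapolate in the display.
#' @param ... Unused.
#' @method autoplot extension_fit
#' @export
autoplot.extension_fit <- function(object, max_age = 100, ...) {
  grid <- tibble::tibble(age = seq(object$fit_window[1], max_age, by = 0.25))
  grid$mx <- exp(object$predict_log_mx(grid$age))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$mx)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "age", y = "central death rate (log scale)",
      title = sprintf("Old-age extension: %s", object$family),
      subtitle = object$formula
    )
}
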