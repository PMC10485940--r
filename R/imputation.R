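#' Fit a logit-scale link between a standard and an observed rate series
#'
#' Sparse subgroups (small disability types) lack death counts at many ages.
#' Their observed central rates are related to the standard (all-subgroup)
#' life table through a relational model on the logit scale,
#' `logit(observed) = a + b * logit(standard)`, fitted by least squares over
#' the ages where both are observed. In the small-rate regime `logit ~ log`,
#' so a subgroup with a constant hazard ratio `r` appears as `b ~ 1`,
#' `a ~ log(r)`.
#'
#' With fewer than three observed ages the regression is unidentified and a
#' constant-ratio fallback is used: slope fixed at 1, intercept the mean
#' logit difference (logged via warning).
#'
#' @param standard_mx Rates from the standard table at the fit ages, in
#'   `(0, 1)`.
#' @param observed_mx Observed subgroup rates at the same ages, in `(0, 1)`.
#' @param ages Optional age labels, recorded in the fit object.
#' @param weights Optional exposure weights for the least-squares fit.
#' @return An object of class `"rate_link"` with `intercept`, `slope`,
#'   `fit_ages`, `residual_sd` and `method`.
#' @export
fit_rate_link <- function(standard_mx, observed_mx, ages = seq_along(standard_mx),
                          weights = NULL) {
  keep <- !is.na(standard_mx) & !is.na(observed_mx)
  s <- standard_mx[keep]
  o <- observed_mx[keep]
  ages <- ages[keep]
  if (any(s <= 0 | s >= 1 | o <= 0 | o >= 1)) {
    rlang::abort("rates must lie strictly in (0, 1) on the logit scale",
      class = "lifehale_validation_error"
    )
  }
  if (length(s) < 3) {
    rlang::warn("fewer than 3 observed ages: constant-ratio fallback link")
    d <- stats::qlogis(o) - stats::qlogis(s)
    res <- list(intercept = mean(d), slope = 1, residual_sd = stats::sd(d), method = "constant_ratio")
  } else {
    ls <- stats::qlogis(s)
    lo <- stats::qlogis(o)
    fit <- stats::lm(lo ~ ls, weights = weights)
    res <- list(
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      residual_sd = stats::sigma(fit),
      method = "logit_linear"
    )
  }
  structure(c(res, list(fit_ages = ages)), class = "rate_link")
}

#' Predict subgroup rates from a standard series through a link
#'
#' @param object A `"rate_link"`.
#' @param standard_mx Standard rates in `(0, 1)`.
#' @param ... Unused.
#' @return Predicted subgroup rates in `(0, 1)`.
#' @export
predict.rate_link <- function(object, standard_mx, ...) {
  stats::plogis(object$intercept + object$slope * stats::qlogis(standard_mx))
}

#' @export
print.rate_link <- function(x, ...) {
  cat(sprintf(
    "<rate_link> logit(obs) = %.4f + %.4f * logit(std)  [%s, %d ages, resid sd %.3g]\n",
    x$intercept, x$slope, x$method, length(x$fit_ages), x$residual_sd
  ))
  invisible(x)
}

#' @rdname tidy.extension_fit
#' @method tidy rate_link
#' @export
tidy.rate_link <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname glance.extension_fit
#' @method glance rate_link
#' @export
glance.rate_link <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_ages = length(x$fit_ages),
    residual_sd = x$residual_sd
  )
}

#' Impute missing subgroup rates from the standard table
#'
#' Observed ages are never altered. Ages with missing exposure or deaths
#' receive the link-transformed standard rate, producing a contiguous
#' schedule ready for [life_table()]. If no link is supplied one is fitted
#' from the overlapping ages.
#'
#' @param data A subgroup mortality schedule with gaps encoded as `NA`
#'   exposure/deaths (or `NA` in an existing `mx` column).
#' @param standard A standard-table schedule or life table covering all of
#'   the subgroup's ages, with an `mx` column (computed if absent).
#' @param link Optional pre-fitted `"rate_link"`.
#' @return The schedule with a complete `mx` column and a logical `imputed`
#'   column.
#' @export
impute_rates <- function(data, standard, link = NULL) {
  if (!"mx" %in% names(data)) data <- compute_mx(data)
  std <- standard
  if (!"mx" %in% names(std)) std <- compute_mx(std)
  std_mx <- std$mx[match(data$age, std$age)]
  if (anyNA(std_mx)) {
    rlang::abort("standard table does not cover all subgroup ages",
      class = "lifehale_validation_error"
    )
  }
  missing_idx <- is.na(data$mx)
  if (is.null(link)) {
    obs <- !missing_idx & data$mx > 0 & data$mx < 1 & std_mx > 0 & std_mx < 1
    link <- fit_rate_link(std_mx[obs], data$mx[obs], ages = data$age[obs])
  }
  out <- dplyr::mutate(tibble::as_tibble(data), imputed = missing_idx)
  out$mx[missing_idx] <- predict(link, std_mx[missing_idx])
  attr(out, "rate_link") <- link
  out
}

#' Abridge a complete life table to five-year age groups
#'
#' Reporting layout: group starts at the first age, then multiples of five up
#' to the open group (85+ by convention). Survivorship, remaining expectation
#' and its standard error are taken at the group-start age of the complete
#' table (so abridged `ex` is exactly the complete-table `ex` there);
#' person-years are summed within groups. Group starts below the table's
#' first age are clamped to it, mirroring subgroup registration ages (e.g. a
#' type first registered at age 12 reports a first group starting at 12).
#'
#' @param lifetable A complete `lifetable` tibble (optionally carrying HALE
#'   columns from [sullivan_hale()]).
#' @param group_starts Integer vector of group-start ages (default
#'   `seq(0, 85, 5)`).
#' @return A tibble with one row per age group: `age_group, age_start, nqx,
#'   lx, nLx, Tx, ex, se_ex, lo95, hi95` plus any `hale*` columns present.
#' @export
abridge_life_table <- function(lifetable, group_starts = seq(0L, 85L, 5L)) {
  lt <- tibble::as_tibble(lifetable)
  first_age <- min(lt$age)
  starts <- sort(unique(pmax(group_starts, first_age)))
  if (!all(starts %in% lt$age)) {
    rlang::abort("complete table does not span all group starts",
      class = "lifehale_validation_error"
    )
  }
  ends <- c(starts[-1] - 1L, max(lt$age))
  open <- c(rep(FALSE, length(starts) - 1), TRUE)
  grp <- purrr::map2(starts, ends, function(lo, hi) dplyr::filter(lt, .data$age >= lo, .data$age <= hi))
  at_start <- lt[match(starts, lt$age), ]
  lx_next <- c(at_start$lx[-1], 0)
  out <- tibble::tibble(
    age_group = ifelse(open, paste0(starts, "+"), paste0(starts, "-", ends)),
    age_start = starts,
    nqx = ifelse(open, 1, ifelse(at_start$lx > 0, 1 - lx_next / at_start$lx, NA_real_)),
    lx = at_start$lx,
    nLx = purrr::map_dbl(grp, function(g) sum(g$Lx)),
    Tx = at_start$Tx,
    ex = at_start$ex
  )
  carry <- intersect(
    c("se_ex", "lo95", "hi95", grep("hale", names(lt), value = TRUE)),
    names(lt)
  )
  dplyr::bind_cols(out, at_start[, carry, drop = FALSE])
}
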