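#' Expand grouped prevalence to single ages
#'
#' Survey and claims prevalence arrives in age bands. The default expansion
#' is a step function: every single age inherits its band's proportion
#' unhealthy. Ages below the youngest band (e.g. registration ages preceding
#' the first survey bin) inherit the youngest band's value, with a warning.
#' A monotone-spline alternative is available behind `method = "spline"`.
#'
#' @param grouped A tibble with columns `age_lo`, `age_hi`, `pi` and
#'   optionally `denom` (one definition, group and sex at a time).
#' @param target_ages Integer ages the expansion must cover.
#' @param method `"step"` (default) or `"spline"` (monotone interpolating
#'   spline through band midpoints).
#' @return A tibble `age, pi, denom` over `target_ages`.
#' @export
expand_prevalence <- function(grouped, target_ages, method = c("step", "spline")) {
  method <- rlang::arg_match(method)
  g <- dplyr::arrange(tibble::as_tibble(grouped), .data$age_lo)
  if (any(g$pi < 0 | g$pi > 1)) {
    rlang::abort("prevalence pi must lie in [0, 1]", class = "lifehale_validation_error")
  }
  if (nrow(g) > 1 && any(g$age_lo[-1] != g$age_hi[-nrow(g)] + 1L)) {
    rlang::abort("prevalence bands must be contiguous", class = "lifehale_validation_error")
  }
  if (!"denom" %in% names(g)) g$denom <- NA_real_
  uncovered_above <- target_ages > max(g$age_hi)
  if (any(uncovered_above)) {
    rlang::abort(
      sprintf("prevalence bands end at %d but ages up to %d are required",
        max(g$age_hi), max(target_ages)
      ),
      class = "lifehale_validation_error"
    )
  }
  below <- target_ages < min(g$age_lo)
  if (any(below)) {
    rlang::warn(sprintf(
      "%d age(s) below the youngest prevalence band inherit its value", sum(below)
    ))
  }
  idx <- findInterval(pmax(target_ages, min(g$age_lo)), g$age_lo)
  out <- tibble::tibble(age = target_ages, pi = g$pi[idx], denom = g$denom[idx])
  if (method == "spline") {
    mids <- (g$age_lo + g$age_hi) / 2
    sp <- stats::splinefun(mids, g$pi, method = "hyman")
    out$pi <- pmin(pmax(sp(pmin(pmax(target_ages, min(mids)), max(mids))), 0), 1)
  }
  out
}

#' Healthy life expectancy by the Sullivan method
#'
#' Down-weights each age's person-years lived by the proportion healthy:
#' `hale[x] = sum(L[i] * (1 - pi[i]), i >= x) / l[x]`, including the open
#' interval with its own prevalence. The identities `pi == 0 => hale == ex`
#' and `pi == c => hale == (1 - c) * ex` hold exactly.
#'
#' Confidence intervals adapt Chiang's life-expectancy variance: the
#' propagation bracket becomes `(1 - a[j]) * (1 - pi[j]) + hale[j+1]`, with
#' prevalence treated as fixed (the default, matching the near-degenerate
#' intervals typical of claims-based prevalence). An optional binomial
#' prevalence-variance term `sum((L[j]/l[x])^2 * pi[j] * (1 - pi[j]) /
#' denom[j])` can be added when denominators are available.
#'
#' @param lifetable A `lifetable` tibble (from [life_table()]).
#' @param prevalence Either a per-age tibble `age, pi[, denom]` covering the
#'   table's ages, or a grouped tibble with `age_lo, age_hi, pi[, denom]`
#'   (expanded via [expand_prevalence()]).
#' @param definition Label recorded on the output (e.g. `"NHIS"`).
#' @param ci Compute confidence intervals (requires the table's `deaths`
#'   column for the mortality term).
#' @param prevalence_variance Add the binomial prevalence term (requires
#'   `denom`).
#' @param quiet Suppress the zero-deaths warning from the variance sum.
#' @return The life table with `pi`, `hale`, `se_hale`, `hale_lo95`,
#'   `hale_hi95` columns appended and a `definition` attribute.
#' @export
sullivan_hale <- function(lifetable, prevalence, definition = "unhealthy",
                          ci = TRUE, prevalence_variance = FALSE, quiet = FALSE) {
  lt <- lifetable
  prev <- tibble::as_tibble(prevalence)
  if (!"age" %in% names(prev) && all(c("age_lo", "age_hi") %in% names(prev))) {
    prev <- expand_prevalence(prev, lt$age)
  }
  prev <- prev[match(lt$age, prev$age), ]
  if (anyNA(prev$pi)) {
    rlang::abort("prevalence does not cover all life-table ages",
      class = "lifehale_validation_error"
    )
  }
  if (any(prev$pi < 0 | prev$pi > 1)) {
    rlang::abort("prevalence pi must lie in [0, 1]", class = "lifehale_validation_error")
  }
  pi_x <- prev$pi
  healthy_L <- lt$Lx * (1 - pi_x)
  hale <- ifelse(lt$lx > 0, rev(cumsum(rev(healthy_L))) / lt$lx, NA_real_)
  out <- dplyr::mutate(lt, pi = pi_x, hale = hale)
  if (ci) {
    d <- if ("deaths" %in% names(lt)) ifelse(is.na(lt$deaths), 0, lt$deaths) else rep(0, nrow(lt))
    q <- lt$qx
    mortal <- q > 0 & q < 1
    no_info <- mortal & d <= 0
    if (any(no_info) && !quiet) {
      rlang::warn(sprintf(
        "%d age(s) with qx in (0,1) but no observed deaths contribute zero HALE variance",
        sum(no_info)
      ))
    }
    s2p <- ifelse(mortal & d > 0, q^2 * (1 - q) / d, 0)
    hale_next <- c(hale[-1], 0)
    hale_next[is.na(hale_next)] <- 0
    bracket <- (1 - lt$ax) * (1 - pi_x) + hale_next
    contrib <- lt$lx^2 * bracket^2 * s2p
    s2 <- ifelse(lt$lx > 0, rev(cumsum(rev(contrib))) / lt$lx^2, NA_real_)
    if (prevalence_variance) {
      if (!"denom" %in% names(prev) || anyNA(prev$denom)) {
        rlang::abort("prevalence_variance requires denominators at every age",
          class = "lifehale_validation_error"
        )
      }
      pv <- lt$Lx^2 * pi_x * (1 - pi_x) / prev$denom
      s2 <- s2 + ifelse(lt$lx > 0, rev(cumsum(rev(pv))) / lt$lx^2, NA_real_)
    }
    out <- dplyr::mutate(out,
      se_hale = sqrt(s2),
      hale_lo95 = .data$hale - 1.96 * .data$se_hale,
      hale_hi95 = .data$hale + 1.96 * .data$se_hale
    )
  }
  attr(out, "definition") <- definition
  out
}
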