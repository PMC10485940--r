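#' Graduate death probabilities with a local-cubic moving formula
#'
#' Actuarial graduation in the Greville tradition: each interior value is
#' replaced by a symmetric weighted moving combination of its neighbours whose
#' weights reproduce polynomials up to degree three exactly. We implement the
#' weights as a local least-squares cubic over a window of `order` ages
#' (equivalently, a Savitzky-Golay degree-3 filter), which has the defining
#' reproduction property; alternative published weight sets can be supplied
#' via `weights`. Near the series ends the window shrinks one-sidedly while
#' keeping the cubic fit, so endpoints are graduated rather than dropped and
#' cubic reproduction still holds there.
#'
#' Because the weights reproduce cubics, a constant series comes back
#' unchanged and smooth schedules are essentially untouched; isolated spikes
#' from small death counts are attenuated.
#'
#' @param qx Numeric vector of death probabilities in `[0, 1]` (`NA` allowed
#'   only as a full pass-through: any `NA` skips graduation with a warning).
#' @param order Odd window width, 5 or more; 9 is the conventional default.
#' @param weights Optional numeric vector of length `order` summing to 1,
#'   replacing the interior local-cubic weights (endpoints still use the
#'   shrinking-window cubic).
#' @return Graduated probabilities, clamped to `[0, 1]`, same length as `qx`.
#' @examples
#' q <- 0.001 * exp(0.08 * (0:40)) + rnorm(41, 0, 1e-4)
#' plot(0:40, q, log = "y")
#' lines(0:40, greville_smooth(q))
#' @export
greville_smooth <- function(qx, order = 9, weights = NULL) {
  stopifnot(is.numeric(qx), length(order) == 1L)
  if (order < 5 || order %% 2 == 0) {
    rlang::abort("graduation order must be an odd integer >= 5",
      class = "lifehale_validation_error"
    )
  }
  n <- length(qx)
  if (n < order || anyNA(qx)) {
    rlang::warn(sprintf(
      "series of length %d %s graduation window (%d): input passed through",
      n, if (anyNA(qx)) "with missing values or shorter than" else "shorter than", order
    ))
    return(qx)
  }
  h <- (order - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    if (!is.null(weights) && lo == i - h && hi == i + h) {
      out[i] <- sum(weights * qx[lo:hi])
    } else {
      out[i] <- local_cubic_fit(qx[lo:hi], at = i - lo + 1L)
    }
  }
  pmin(pmax(out, 0), 1)
}

# Fitted value at position `at` of an OLS cubic over the window values.
# Centring the abscissa keeps the design well conditioned.
local_cubic_fit <- function(y, at) {
  x <- seq_along(y) - at
  X <- cbind(1, x, x^2, x^3)
  beta <- qr.coef(qr(X), y)
  beta[1]
}
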