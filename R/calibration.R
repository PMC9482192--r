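#' Aequorin calibration model
#'
#' The empirical calibration links the fractional aequorin consumption rate
#' \eqn{k} (counts per second divided by total counts remaining, units
#' \eqn{s^{-1}}) to free cytosolic calcium via
#' \deqn{pCa = c_1 \cdot (-\log_{10} k) + c_0,
#'   \qquad [\mathrm{Ca}^{2+}] = 10^{-pCa}.}
#' The default constants are the widely used empirical values for
#' cytosolic aequorin reconstituted with native coelenterazine; both are
#' exposed so that alternative calibrations can be swapped in.
#'
#' @param c1 slope of the calibration line (dimensionless, > 0).
#' @param c0 intercept (pCa units).
#' @param rate_floor smallest admissible rate \eqn{k} (s^-1); rates below
#'   this are clamped (and flagged by callers) to avoid `log10(0)`.
#' @param count_floor floor applied to background-corrected counts.
#' @return An object of class `aeq_calibration`.
#' @examples
#' cal <- aeq_calibration()
#' calcium_from_rate(1, cal)   # 10^-c0, the intercept case
#' @export
aeq_calibration <- function(c1 = 0.332588, c0 = 5.5593,
                            rate_floor = 1e-12, count_floor = 0) {
  stopifnot(is.numeric(c1), length(c1) == 1L, is.finite(c1), c1 > 0,
            is.numeric(c0), length(c0) == 1L, is.finite(c0),
            is.numeric(rate_floor), length(rate_floor) == 1L, rate_floor > 0,
            is.numeric(count_floor), length(count_floor) == 1L,
            count_floor >= 0)
  structure(list(c1 = c1, c0 = c0, rate_floor = rate_floor,
                 count_floor = count_floor),
            class = "aeq_calibration")
}

#' @export
print.aeq_calibration <- function(x, ...) {
  cat(sprintf("aequorin calibration: pCa = %g * (-log10 k) + %g\n",
              x$c1, x$c0))
  invisible(x)
}

#' Consumption rate from free calcium
#'
#' Inverse direction of the calibration: the per-second fractional
#' consumption rate of the aequorin pool at a given free calcium
#' concentration.
#'
#' @param ca free calcium concentration (molar, > 0); vectorised.
#' @param model an [aeq_calibration()].
#' @return rate fraction \eqn{k} in s^-1, never below `model$rate_floor`.
#' @export
rate_from_calcium <- function(ca, model = aeq_calibration()) {
  stopifnot(inherits(model, "aeq_calibration"))
  if (!is.numeric(ca) || any(!is.finite(ca)) || any(ca <= 0))
    stop("`ca` must be finite and strictly positive (molar)")
  pca <- -log10(ca)
  k <- 10^(-(pca - model$c0) / model$c1)
  pmax(k, model$rate_floor)
}

#' Free calcium from consumption rate
#'
#' @param k fractional consumption rate (s^-1); values in `(0, rate_floor)`
#'   are clamped to the floor when `clamp = TRUE`.
#' @param model an [aeq_calibration()].
#' @param clamp clamp sub-floor rates instead of erroring.
#' @return calcium concentration (molar).
#' @export
calcium_from_rate <- function(k, model = aeq_calibration(), clamp = TRUE) {
  stopifnot(inherits(model, "aeq_calibration"))
  if (!is.numeric(k) || any(!is.finite(k)))
    stop("`k` must be finite")
  if (clamp) {
    k <- pmax(k, model$rate_floor)
  } else if (any(k <= 0)) {
    stop("`k` must be strictly positive (s^-1)")
  }
  pca <- model$c1 * (-log10(k)) + model$c0
  10^(-pca)
}

#' One forward emission step of the aequorin pool
#'
#' Consumption is first order at rate \eqn{k(\mathrm{Ca})}: over a bin of
#' width `tau` a pool `pool` emits `pool * (1 - exp(-k tau))` expected
#' counts and retains the remainder. Emitted and remaining sum to the
#' initial pool exactly.
#'
#' @param pool active aequorin units (>= 0).
#' @param ca free calcium (molar) during the bin, or `NULL` to pass `rate`
#'   directly.
#' @param tau bin width (s, > 0).
#' @param model an [aeq_calibration()].
#' @param rate optional explicit consumption rate (s^-1), bypassing the
#'   calibration (used for the saturating discharge).
#' @return list with `emitted` (expected counts) and `remaining` (pool).
#' @export
emission_step <- function(pool, ca = NULL, tau = 1,
                          model = aeq_calibration(), rate = NULL) {
  stopifnot(is.numeric(pool), all(pool >= 0), is.numeric(tau), tau > 0)
  k <- if (is.null(rate)) rate_from_calcium(ca, model) else rate
  keep <- exp(-k * tau)
  remaining <- pool * keep
  list(emitted = pool - remaining, remaining = remaining)
}
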