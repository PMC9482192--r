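#' Photon-count trace from one luminometer well
#'
#' Container for one well's raw (or background-corrected) photon counts at
#' fixed integration time `tau`. Phase markers are bin indices: `injection`
#' is the last baseline bin (the stimulus is injected at the end of that
#' bin) and `discharge` the last pre-discharge bin; bins
#' `discharge + 1 ... N` record the terminal CaCl2/ethanol discharge that
#' consumes the remaining aequorin pool.
#'
#' @param counts non-negative finite numeric vector of counts per bin.
#' @param tau integration time (s, > 0), 1 s for the plate protocol.
#' @param injection index of the last pre-injection bin (>= 1).
#' @param discharge index of the last pre-discharge bin
#'   (`injection < discharge < length(counts)`).
#' @param corrected logical; has background correction been applied?
#' @param clamped logical per-bin vector marking floor-clamped bins.
#' @param warn character vector of quality warnings.
#' @return object of class `lum_trace`.
#' @export
lum_trace <- function(counts, tau = 1, injection, discharge,
                      corrected = FALSE, clamped = NULL, warn = character()) {
  stopifnot(is.numeric(counts), length(counts) >= 3L,
            all(is.finite(counts)), all(counts >= 0),
            is.numeric(tau), length(tau) == 1L, tau > 0)
  n <- length(counts)
  injection <- as.integer(injection)
  discharge <- as.integer(discharge)
  if (!(injection >= 1L && injection < discharge && discharge < n))
    stop("phase markers must satisfy 1 <= injection < discharge < length(counts)")
  if (is.null(clamped)) clamped <- logical(n)
  stopifnot(length(clamped) == n)
  structure(list(counts = as.numeric(counts), tau = tau,
                 injection = injection, discharge = discharge,
                 corrected = isTRUE(corrected), clamped = clamped,
                 warn = warn),
            class = "lum_trace")
}

#' @export
print.lum_trace <- function(x, ...) {
  cat(sprintf(
    "lum_trace: %d bins x %g s (baseline %d | response %d | discharge %d)%s\n",
    length(x$counts), x$tau, x$injection, x$discharge - x$injection,
    length(x$counts) - x$discharge,
    if (x$corrected) ", background-corrected" else ""))
  invisible(x)
}

#' Total luminescence counts remaining per bin
#'
#' The calibration denominator: for each bin, the sum of its own counts and
#' all later counts through the end of the discharge window (an estimate of
#' the aequorin pool still active at the start of the bin). The result is
#' non-increasing; element 1 equals the total counts of the trace.
#'
#' @param trace a [lum_trace()] or a bare numeric count vector.
#' @param inclusive include the current bin in the remaining total
#'   (the package-wide convention; exclusive is offered for comparison
#'   with software that sums strictly later bins).
#' @return numeric vector of remaining totals, same length as the counts.
#' @export
lmax_remaining <- function(trace, inclusive = TRUE) {
  counts <- if (inherits(trace, "lum_trace")) trace$counts else trace
  stopifnot(is.numeric(counts), all(is.finite(counts)))
  rem <- rev(cumsum(rev(counts)))
  if (!inclusive) rem <- c(rem[-1L], 0)
  rem
}

#' Subtract the empty-well background from a trace
#'
#' Bins are clamped at the count floor (default 0) and flagged when the
#' correction would drive them negative. If every bin is consumed by the
#' correction a `"background_exceeds_signal"` warning flag is set.
#'
#' @param trace a [lum_trace()].
#' @param background_rate background count rate (counts/s, >= 0), typically
#'   from [estimate_background()].
#' @param count_floor floor for corrected counts.
#' @return the corrected [lum_trace()].
#' @export
background_correct <- function(trace, background_rate, count_floor = 0) {
  stopifnot(inherits(trace, "lum_trace"),
            is.numeric(background_rate), length(background_rate) == 1L,
            is.finite(background_rate), background_rate >= 0)
  corr <- trace$counts - background_rate * trace$tau
  clamped <- trace$clamped |
    (background_rate > 0 & corr <= count_floor)
  corr <- pmax(corr, count_floor)
  warn <- trace$warn
  if (background_rate > 0 && all(trace$counts <= background_rate * trace$tau))
    warn <- union(warn, "background_exceeds_signal")
  lum_trace(corr, tau = trace$tau, injection = trace$injection,
            discharge = trace$discharge, corrected = TRUE,
            clamped = clamped, warn = warn)
}

#' Mean background count rate of designated empty wells
#'
#' @param counts numeric vector, or list of vectors (one per empty well),
#'   of raw counts from wells containing no tissue.
#' @param tau integration time (s).
#' @return background rate in counts/s.
#' @export
estimate_background <- function(counts, tau = 1) {
  if (is.list(counts)) counts <- unlist(counts, use.names = FALSE)
  stopifnot(is.numeric(counts), length(counts) > 0, all(is.finite(counts)))
  mean(counts) / tau
}

#' Calibrated cytosolic calcium trace
#'
#' Converts a background-corrected photon-count trace into a molar
#' \eqn{[\mathrm{Ca}^{2+}]_{cyt}} time series. Per bin the fractional
#' consumption rate is estimated as
#' \deqn{\hat k_i = (L_i / \tau) / \sum_{j \ge i} L_j}
#' (counts per second over total counts remaining) and converted through
#' the calibration. Zero-count bins are assigned the rate floor and
#' flagged; they are excluded from downstream feature maxima. Baseline
#' statistics use exactly the 10 s window immediately preceding injection.
#'
#' @param trace a background-corrected [lum_trace()] spanning the full
#'   discharge window.
#' @param model an [aeq_calibration()].
#' @param inclusive remaining-total convention, see [lmax_remaining()].
#' @param saturation_threshold warn when this fraction of total counts is
#'   emitted before discharge (calibration unreliable near exhaustion).
#' @param baseline_bins number of pre-injection bins used for baseline
#'   statistics (10 bins = 10 s at the 1-s protocol).
#' @return object of class `ca_trace`: fields `time` (s, 0 = injection,
#'   bin-end convention), `ca` (molar), `khat` (s^-1), `baseline_mean`,
#'   `baseline_sd` (molar), per-bin `flagged`, markers and `warn`.
#' @export
calibrate_trace <- function(trace, model = aeq_calibration(),
                            inclusive = TRUE, saturation_threshold = 0.9,
                            baseline_bins = 10L) {
  stopifnot(inherits(trace, "lum_trace"))
  if (!trace$corrected)
    stop("trace must be background-corrected before calibration ",
         "(use background_correct(), possibly with rate 0)")
  n <- length(trace$counts)
  if (trace$injection < baseline_bins)
    stop(sprintf("need >= %d pre-injection bins for baseline statistics",
                 baseline_bins))
  rem <- lmax_remaining(trace, inclusive = inclusive)
  total <- rem[1L]
  warn <- trace$warn
  if (total <= 0)
    stop("trace has no counts; Lmax undefined")
  pre_frac <- sum(trace$counts[seq_len(trace$discharge)]) / total
  if (pre_frac > saturation_threshold)
    warn <- union(warn, "saturation")

  flagged <- trace$clamped | trace$counts <= 0 | rem <= 0
  khat <- ifelse(rem > 0, (trace$counts / trace$tau) / rem, model$rate_floor)
  khat <- pmax(khat, model$rate_floor)
  ca <- calcium_from_rate(khat, model)

  idx <- seq_len(n)
  time <- (idx - trace$injection) * trace$tau
  bl <- (trace$injection - baseline_bins + 1L):trace$injection
  baseline_mean <- mean(ca[bl])
  baseline_sd <- stats::sd(ca[bl])

  structure(list(time = time, ca = ca, khat = khat, tau = trace$tau,
                 injection = trace$injection, discharge = trace$discharge,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 flagged = flagged, warn = warn),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf(
    "ca_trace: %d bins x %g s; baseline %.3g M (sd %.2g); peak %.3g M%s\n",
    length(x$ca), x$tau, x$baseline_mean, x$baseline_sd,
    max(x$ca[(x$injection + 1L):x$discharge]),
    if (length(x$warn)) paste0("; warn: ", paste(x$warn, collapse = ",")) else ""))
  invisible(x)
}
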