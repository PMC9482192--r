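#' Baseline statistics of a calibrated trace
#'
#' Mean and standard deviation of calcium over exactly the `bins`
#' pre-injection bins (10 s at the 1-s protocol) immediately preceding
#' injection.
#'
#' @param trace a `ca_trace` from [calibrate_trace()].
#' @param bins number of baseline bins.
#' @return list with `mean` and `sd` (molar).
#' @export
baseline_stats <- function(trace, bins = 10L) {
  stopifnot(inherits(trace, "ca_trace"))
  if (trace$injection < bins)
    stop(sprintf("need >= %d pre-injection bins", bins))
  idx <- (trace$injection - bins + 1L):trace$injection
  list(mean = mean(trace$ca[idx]), sd = stats::sd(trace$ca[idx]))
}

# post-injection, pre-discharge analysis window (bin indices)
analysis_window <- function(trace) (trace$injection + 1L):trace$discharge

#' Maximal calcium elevation above baseline
#'
#' The signature amplitude: maximum calibrated calcium over the
#' post-injection, pre-discharge window (flagged bins excluded, earliest
#' bin wins ties) minus the 10-s baseline mean. Negative values (possible
#' in null wells through shot noise) are clamped to zero for reporting;
#' the raw value is kept in the `"raw"` attribute.
#'
#' @param trace a `ca_trace`.
#' @return Delta calcium (molar, >= 0) with attribute `raw`.
#' @export
delta_ca_max <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  win <- analysis_window(trace)
  ok <- win[!trace$flagged[win]]
  if (length(ok) == 0L) stop("all post-injection bins are flagged")
  raw <- max(trace$ca[ok]) - trace$baseline_mean
  structure(max(raw, 0), raw = raw)
}

#' Time to reach the calcium maximum
#'
#' Seconds between injection and the (earliest) maximal post-injection
#' bin, flagged bins excluded.
#'
#' @param trace a `ca_trace`.
#' @return time-to-peak in seconds after injection.
#' @export
time_to_peak <- function(trace) {
  stopifnot(inherits(trace, "ca_trace"))
  win <- analysis_window(trace)
  ok <- win[!trace$flagged[win]]
  if (length(ok) == 0L) stop("all post-injection bins are flagged")
  trace$time[ok[which.max(trace$ca[ok])]]
}

#' Onset delay of the calcium response
#'
#' Time of the first post-injection bin that starts `run_length`
#' consecutive bins above `baseline mean + threshold_sd * baseline SD`.
#' With a zero-noise baseline the SD is floored at `sd_floor` (1 nM).
#'
#' @param trace a `ca_trace`.
#' @param threshold_sd number of baseline SDs for the detection threshold.
#' @param run_length consecutive supra-threshold bins required.
#' @param sd_floor molar floor for the baseline SD.
#' @return onset time in seconds after injection, or `NA` if the trace
#'   never crosses the threshold.
#' @export
onset_delay <- function(trace, threshold_sd = 3, run_length = 3L,
                        sd_floor = 1e-9) {
  stopifnot(inherits(trace, "ca_trace"))
  thr <- trace$baseline_mean +
    threshold_sd * max(trace$baseline_sd, sd_floor, na.rm = TRUE)
  win <- analysis_window(trace)
  above <- trace$ca[win] > thr & !trace$flagged[win]
  if (run_length > 1L) {
    runs <- stats::filter(as.numeric(above), rep(1, run_length),
                          sides = 1)
    # runs[i] counts bins (i-run_length+1)..i; the run *starts* where the
    # window ending run_length-1 later is saturated
    start <- which(runs == run_length) - run_length + 1L
  } else {
    start <- which(above)
  }
  if (length(start) == 0L) return(NA_real_)
  trace$time[win[min(start)]]
}

#' Sustained calcium elevation
#'
#' Mean calcium over the final `window_s` seconds before discharge minus
#' the baseline mean; may be negative when the trace ends below baseline.
#'
#' @param trace a `ca_trace`.
#' @param window_s averaging window (s) ending at the discharge marker.
#' @return sustained elevation (molar).
#' @export
sustained_elevation <- function(trace, window_s = 60) {
  stopifnot(inherits(trace, "ca_trace"))
  nwin <- as.integer(round(window_s / trace$tau))
  lo <- trace$discharge - nwin + 1L
  if (lo <= trace$injection)
    stop("sustained window extends before injection")
  idx <- lo:trace$discharge
  idx <- idx[!trace$flagged[idx]]
  mean(trace$ca[idx]) - trace$baseline_mean
}

#' Boxcar-smooth a calibrated calcium trace
#'
#' Centered moving average of the calcium values (edges keep the raw
#' values); markers, flags and baseline statistics are unchanged. Used
#' before peak extraction to reduce the extreme-value bias that
#' single-bin shot noise adds to a maximum taken over hundreds of bins.
#'
#' @param trace a `ca_trace`.
#' @param width_s smoothing window (s); rounded to an odd bin count.
#' @return the smoothed `ca_trace`.
#' @export
smooth_ca_trace <- function(trace, width_s = 5) {
  stopifnot(inherits(trace, "ca_trace"), width_s >= 0)
  w <- as.integer(round(width_s / trace$tau))
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L) return(trace)
  # never mix discharge-phase bins (saturating, off-calibration calcium)
  # into the analysis window: smooth the pre-discharge segment only
  pre <- seq_len(trace$discharge)
  sm <- stats::filter(trace$ca[pre], rep(1 / w, w), sides = 2)
  out <- trace
  out$ca[pre] <- ifelse(is.na(sm), trace$ca[pre], as.numeric(sm))
  out
}

#' Extract all signature features from one calibrated trace
#'
#' The amplitude and time-to-peak are taken from a boxcar-smoothed copy
#' of the trace (`smooth_s`, default 5 s) to suppress shot-noise
#' extreme-value bias; onset detection and the sustained elevation use
#' the raw trace (the onset detector has its own run-length noise
#' control, and the sustained value is already an average).
#'
#' @param trace a `ca_trace`.
#' @param threshold_sd,run_length onset-detection parameters, see
#'   [onset_delay()].
#' @param smooth_s smoothing window for peak extraction (s); 0 disables.
#' @return object of class `signature_features`: `delta` (molar, clamped
#'   at 0), `delta_raw`, `ttp_s`, `onset_s`, `sustained` (molar),
#'   `baseline_mean`, `baseline_sd`, `warn`.
#' @export
extract_features <- function(trace, threshold_sd = 3, run_length = 3L,
                             smooth_s = 5) {
  sm <- if (smooth_s > 0) smooth_ca_trace(trace, smooth_s) else trace
  d <- delta_ca_max(sm)
  structure(list(delta = as.numeric(d), delta_raw = attr(d, "raw"),
                 ttp_s = time_to_peak(sm),
                 onset_s = onset_delay(trace, threshold_sd, run_length),
                 sustained = sustained_elevation(trace),
                 baseline_mean = trace$baseline_mean,
                 baseline_sd = trace$baseline_sd,
                 warn = trace$warn),
            class = "signature_features")
}

#' Quantify a single well record
#'
#' Background-corrects the raw counts, calibrates to calcium and extracts
#' the signature features.
#'
#' @param well a `well_record`.
#' @param background_rate empty-well background rate (counts/s).
#' @param model an [aeq_calibration()].
#' @param ... passed to [extract_features()].
#' @return a `signature_features` object.
#' @export
quantify_well <- function(well, background_rate, model = aeq_calibration(),
                          ...) {
  stopifnot(inherits(well, "well_record"))
  corrected <- background_correct(well$trace, background_rate,
                                  count_floor = model$count_floor)
  extract_features(calibrate_trace(corrected, model), ...)
}

#' Summarise a plate dataset into a feature table
#'
#' Runs the full inverse pipeline for every treatment well: background
#' estimation from the designated empty wells, background correction,
#' calibration and feature extraction. Calcium is reported in micromolar.
#'
#' @param dataset a `plate_dataset` (simulated or read from disk).
#' @param model an [aeq_calibration()].
#' @param ... passed to [extract_features()].
#' @return data.frame, one row per treatment well, in well order:
#'   metadata columns plus `delta_uM`, `ttp_s`, `onset_s`, `sustained_uM`,
#'   `baseline_uM`, `flags`.
#' @export
summarize_plate <- function(dataset, model = aeq_calibration(), ...) {
  stopifnot(inherits(dataset, "plate_dataset"))
  if (length(dataset$empty) == 0L)
    stop("dataset has no empty wells for background estimation")
  bg <- estimate_background(lapply(dataset$empty,
                                   function(w) w$trace$counts),
                            tau = dataset$config$tau)
  rows <- lapply(dataset$wells, function(w) {
    f <- quantify_well(w, bg, model, ...)
    data.frame(well_id = w$well_id, preset_id = w$preset_id,
               species = w$species, tissue = w$tissue,
               stimulus = w$stimulus, dose = w$dose,
               dose_units = w$dose_units, la3plus = w$la3plus,
               section_id = w$section_id, replicate = w$replicate,
               delta_uM = f$delta * 1e6, delta_raw_uM = f$delta_raw * 1e6,
               ttp_s = f$ttp_s, onset_s = f$onset_s,
               sustained_uM = f$sustained * 1e6,
               baseline_uM = f$baseline_mean * 1e6,
               flags = paste(f$warn, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "background_rate") <- bg
  out
}
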