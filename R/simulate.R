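#' Simulation protocol configuration
#'
#' Encodes the plate-luminometer protocol: a 90-s baseline at 1-s
#' integration, injection of the stimulus, a 600-s recording window
#' (1200 s for the slow flagellin-22 response), and a terminal 300-s
#' discharge with saturating CaCl2 that consumes the remaining aequorin.
#'
#' @param tau integration time (s).
#' @param baseline_s,post_s,discharge_s phase durations (s), positive
#'   multiples of `tau`.
#' @param A0 initial active-aequorin pool (units; one detected count per
#'   consumed unit, detector efficiency folded in).
#' @param background background count rate of an empty well (counts/s).
#' @param noise `"poisson"` for photon shot noise, `"none"` for the exact
#'   expected-value (noise-free) forward model.
#' @param discharge_rate fixed saturating consumption rate during the
#'   discharge window (s^-1); 0.05 s^-1 empties > 99.99 percent of the pool
#'   within 300 s. The empirical calibration is not extrapolated to molar
#'   calcium.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(tau = 1, baseline_s = 90, post_s = 600,
                       discharge_s = 300, A0 = 5e6, background = 20,
                       noise = c("poisson", "none"),
                       discharge_rate = 0.05) {
  noise <- match.arg(noise)
  stopifnot(tau > 0, baseline_s > 0, post_s > 0, discharge_s > 0,
            A0 > 0, background >= 0, discharge_rate > 0)
  for (d in c(baseline_s, post_s, discharge_s))
    if (abs(d / tau - round(d / tau)) > 1e-9)
      stop("phase durations must be positive multiples of tau")
  structure(list(tau = tau, baseline_s = baseline_s, post_s = post_s,
                 discharge_s = discharge_s, A0 = A0,
                 background = background, noise = noise,
                 discharge_rate = discharge_rate),
            class = "sim_config")
}

#' Protocol configuration appropriate for a preset
#'
#' flg22 responses are slow; the protocol records 1200 s post-injection
#' for them and 600 s for all other stimuli.
#'
#' @param preset a [signature_preset()].
#' @param ... overrides passed to [sim_config()].
#' @export
sim_config_for <- function(preset, ...) {
  args <- list(...)
  if (is.null(args$post_s))
    args$post_s <- if (preset$stimulus == "flg22") 1200 else 600
  do.call(sim_config, args)
}

phase_bins <- function(config) {
  list(n_base = as.integer(round(config$baseline_s / config$tau)),
       n_post = as.integer(round(config$post_s / config$tau)),
       n_dis = as.integer(round(config$discharge_s / config$tau)))
}

#' Ground-truth calcium kinetics for a preset
#'
#' Builds the noise-free cytosolic calcium concentration per bin over the
#' full protocol. The transient rises from the onset delay to the peak as
#' a saturating exponential (so the observable threshold-crossing onset
#' tracks the preset's onset parameter closely) and then decays
#' exponentially with the preset's half-time;
#' a saturating plateau term approaches the sustained elevation, and an
#' optional damped sine-squared train adds secondary elevations. The
#' maximum over post-injection bins minus baseline equals the preset
#' amplitude to within 1 percent by construction.
#'
#' @param preset a [signature_preset()].
#' @param config a [sim_config()]; the recording window must contain the
#'   peak.
#' @return numeric vector of molar calcium, one value per protocol bin
#'   (discharge bins hold the baseline value; consumption there is driven
#'   by the fixed discharge rate, not by this trace).
#' @export
build_ca_trace <- function(preset, config = sim_config_for(preset)) {
  stopifnot(inherits(preset, "signature_preset"),
            inherits(config, "sim_config"))
  nb <- phase_bins(config)
  if (preset$amplitude > 0 && preset$ttp >= config$post_s)
    stop(sprintf("preset '%s': peak (%g s) falls after the recording window",
                 preset$id, preset$ttp))
  n <- nb$n_base + nb$n_post + nb$n_dis
  t_rel <- (seq_len(n) - nb$n_base) * config$tau  # bin-end time, injection = 0
  ca <- rep(preset$baseline, n)
  if (preset$amplitude > 0) {
    d <- preset$onset; tp <- preset$ttp
    g <- numeric(n)
    rise <- t_rel > d & t_rel <= tp
    a <- 3  # rise shape: initial slope ~3x the mean rise rate
    g[rise] <- (1 - exp(-a * (t_rel[rise] - d) / (tp - d))) / (1 - exp(-a))
    fall <- t_rel > tp
    g[fall] <- exp(-(t_rel[fall] - tp) * log(2) / preset$decay_half)
    s_term <- numeric(n)
    if (preset$sustained > 0) {
      tau_s <- (tp - d) / 5
      on <- t_rel > d
      s_term[on] <- 1 - exp(-(t_rel[on] - d) / tau_s)
    }
    osc <- numeric(n)
    if (preset$osc_amp > 0 && preset$osc_count > 0) {
      t0 <- tp + preset$decay_half
      win <- t_rel > t0 & t_rel <= t0 + preset$osc_count * preset$osc_period
      osc[win] <- preset$osc_amp *
        exp(-(t_rel[win] - t0) / preset$osc_damp) *
        sin(pi * (t_rel[win] - t0) / preset$osc_period)^2
    }
    ca <- preset$baseline +
      (preset$amplitude - preset$sustained) * g +
      preset$sustained * s_term + osc
  }
  # discharge phase: ground truth reverts to baseline (pool consumption
  # there is modelled by the fixed discharge rate)
  ca[t_rel > config$post_s] <- preset$baseline
  ca
}

new_well_record <- function(trace, preset = NULL, replicate = NA_integer_,
                            seed = NA_integer_, is_empty = FALSE,
                            well_id = NA_character_) {
  meta <- if (is.null(preset)) {
    list(preset_id = NA_character_, species = NA_character_,
         tissue = NA_character_, stimulus = NA_character_,
         dose = NA_real_, dose_units = NA_character_,
         la3plus = FALSE, section_id = NA_character_)
  } else {
    stats::setNames(
      preset[c("id", "species", "tissue", "stimulus", "dose", "dose_units",
               "la3plus", "section_id")],
      c("preset_id", "species", "tissue", "stimulus",
        "dose", "dose_units", "la3plus", "section_id"))
  }
  structure(c(list(trace = trace, replicate = replicate, seed = seed,
                   is_empty = is_empty, well_id = well_id), meta),
            class = "well_record")
}

#' Simulate one well's photon-count record
#'
#' Pushes the preset's ground-truth calcium kinetics through the forward
#' photon model: per bin, the active pool emits
#' `pool * (1 - exp(-k(ca) tau))` expected counts (Poisson-distributed
#' under shot noise) and shrinks by the counts actually emitted; the
#' discharge phase consumes the remainder at the fixed saturating rate.
#' Poisson background counts are added to every bin. The expected total
#' signal equals the initial pool `A0`.
#'
#' @param preset a [signature_preset()].
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical records.
#' @param model an [aeq_calibration()].
#' @return a `well_record` whose `$trace` is the raw [lum_trace()].
#' @export
simulate_well <- function(preset, config = sim_config_for(preset),
                          seed = NULL, model = aeq_calibration()) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    set.seed(seed)
  }
  nb <- phase_bins(config)
  n <- nb$n_base + nb$n_post + nb$n_dis
  ca <- build_ca_trace(preset, config)
  k <- rate_from_calcium(ca, model)
  k[(nb$n_base + nb$n_post + 1L):n] <- config$discharge_rate
  p_emit <- 1 - exp(-k * config$tau)
  counts <- numeric(n)
  pool <- config$A0
  if (config$noise == "poisson") {
    for (i in seq_len(n)) {
      mu <- pool * p_emit[i]
      emitted <- if (mu > 0) stats::rpois(1L, mu) else 0
      emitted <- min(emitted, pool)
      counts[i] <- emitted
      pool <- pool - emitted
    }
    counts <- counts + stats::rpois(n, config$background * config$tau)
  } else {
    keep <- exp(-k * config$tau)
    pools <- config$A0 * cumprod(keep)
    counts <- c(config$A0, pools[-n]) - pools
    counts <- counts + config$background * config$tau
  }
  trace <- lum_trace(counts, tau = config$tau, injection = nb$n_base,
                     discharge = nb$n_base + nb$n_post)
  new_well_record(trace, preset = preset, seed = seed)
}

#' Simulate an empty (background-only) well
#'
#' @inheritParams simulate_well
#' @export
simulate_empty_well <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    set.seed(seed)
  }
  nb <- phase_bins(config)
  n <- nb$n_base + nb$n_post + nb$n_dis
  counts <- if (config$noise == "poisson") {
    stats::rpois(n, config$background * config$tau)
  } else {
    rep(config$background * config$tau, n)
  }
  trace <- lum_trace(counts, tau = config$tau, injection = nb$n_base,
                     discharge = nb$n_base + nb$n_post)
  new_well_record(trace, preset = NULL, seed = seed, is_empty = TRUE)
}

#' Simulate a plate of wells from a design
#'
#' Each design entry names a preset and optionally a dose (rescaled with
#' [dose_scale()]), a La3+ pre-treatment flag (applied with
#' [apply_blocker()]) and a replicate count. Per-well seeds are derived
#' from the master seed by a counter scheme: well `i` (empty wells
#' continue the counter) uses `seed * 10000 + i`, so plates with different
#' master seeds never share well seeds for master seeds below 2e5.
#'
#' @param design list of entries `list(preset=, dose=, la3plus=, replicates=)`
#'   (`preset` either a [signature_preset()] or an id into `library`).
#' @param config a [sim_config()] shared by all wells.
#' @param seed master seed.
#' @param n_empty number of background-only wells (>= 1, used for
#'   background estimation).
#' @param library preset library used to resolve ids.
#' @param model an [aeq_calibration()].
#' @return object of class `plate_dataset`: `$wells` (treatment
#'   `well_record`s), `$empty`, `$config`, `$seed`.
#' @export
simulate_plate <- function(design, config = sim_config(), seed = 1L,
                           n_empty = 3L, library = preset_library(),
                           model = aeq_calibration()) {
  stopifnot(length(design) > 0, n_empty >= 1L)
  seed <- as.integer(seed)
  wells <- list()
  counter <- 0L
  for (entry in design) {
    p <- entry$preset
    if (is.character(p)) {
      if (is.null(library[[p]])) stop(sprintf("unknown preset id '%s'", p))
      p <- library[[p]]
    }
    stopifnot(inherits(p, "signature_preset"))
    if (!is.null(entry$dose) && !is.na(entry$dose) && entry$dose != p$dose)
      p <- dose_scale(p, entry$dose)
    if (isTRUE(entry$la3plus)) p <- apply_blocker(p)
    reps <- if (is.null(entry$replicates)) 1L else as.integer(entry$replicates)
    for (r in seq_len(reps)) {
      counter <- counter + 1L
      w <- simulate_well(p, config, seed = seed * 10000L + counter,
                         model = model)
      w$replicate <- r
      w$well_id <- sprintf("W%03d", counter)
      wells[[length(wells) + 1L]] <- w
    }
  }
  empty <- lapply(seq_len(n_empty), function(j) {
    counter <<- counter + 1L
    w <- simulate_empty_well(config, seed = seed * 10000L + counter)
    w$well_id <- sprintf("E%03d", j)
    w
  })
  structure(list(wells = wells, empty = empty, config = config,
                 seed = seed),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("plate_dataset: %d treatment wells + %d empty wells (seed %s)\n",
              length(x$wells), length(x$empty), format(x$seed)))
  invisible(x)
}
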