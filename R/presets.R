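#' Construct a calcium-signature preset
#'
#' A preset is the ground truth for one stimulus x dose x tissue x species
#' combination: the kinetic parameters of the cytosolic calcium transient
#' that the synthetic-data generator reproduces. Amplitude-like fields are
#' molar; times are seconds after injection.
#'
#' @param id short identifier (e.g. `"hv_leaf_nacl_250"`).
#' @param species `"barley"` or `"arabidopsis"`.
#' @param tissue `"leaf"` or `"root"`.
#' @param stimulus one of `"NaCl"`, `"mannitol"`, `"H2O2"`, `"flg22"`.
#' @param dose reference dose in `dose_units`.
#' @param dose_units `"mM"` or `"nM"`.
#' @param baseline resting calcium (molar).
#' @param amplitude peak elevation above baseline, Delta (molar, >= 0).
#' @param onset delay between injection and the start of the rise (s).
#' @param ttp time-to-peak after injection (s, > onset when amplitude > 0).
#' @param decay_half half-time of the post-peak decay (s).
#' @param sustained long-lasting elevation above baseline approached after
#'   the transient (molar, <= amplitude).
#' @param osc_amp,osc_period,osc_damp,osc_count damped-sinusoid train of
#'   secondary elevations (molar amplitude, s period, s damping constant,
#'   bump count); all zero when absent.
#' @param dose_threshold largest non-responding dose (same units as `dose`).
#' @param dose_halfsat half-saturation of the Hill dose curve above the
#'   threshold.
#' @param dose_decline per-optimum-multiple attenuation factor above the
#'   reference dose (high-dose decline, `NA` when absent).
#' @param inhibition fraction of the response abolished by 1 mM LaCl3
#'   pre-treatment (0-1, `NA` when not measured).
#' @param la3plus logical: does this preset describe a blocked sample?
#' @param section_id leaf-blade section label (`NA` for whole-tip wells).
#' @return object of class `signature_preset`.
#' @export
signature_preset <- function(id, species, tissue, stimulus,
                             dose, dose_units = c("mM", "nM"),
                             baseline = 1e-7, amplitude,
                             onset = 0, ttp, decay_half,
                             sustained = 0,
                             osc_amp = 0, osc_period = 60,
                             osc_damp = 60, osc_count = 0,
                             dose_threshold = 0, dose_halfsat = dose / 2,
                             dose_decline = NA_real_,
                             inhibition = NA_real_,
                             la3plus = FALSE, section_id = NA_character_) {
  dose_units <- match.arg(dose_units)
  species <- match.arg(species, c("barley", "arabidopsis"))
  tissue <- match.arg(tissue, c("leaf", "root"))
  stimulus <- match.arg(stimulus, c("NaCl", "mannitol", "H2O2", "flg22"))
  p <- structure(list(id = id, species = species, tissue = tissue,
                      stimulus = stimulus, dose = dose,
                      dose_units = dose_units, baseline = baseline,
                      amplitude = amplitude, onset = onset, ttp = ttp,
                      decay_half = decay_half, sustained = sustained,
                      osc_amp = osc_amp, osc_period = osc_period,
                      osc_damp = osc_damp, osc_count = osc_count,
                      dose_threshold = dose_threshold,
                      dose_halfsat = dose_halfsat,
                      dose_decline = dose_decline,
                      inhibition = inhibition, la3plus = isTRUE(la3plus),
                      section_id = section_id),
                 class = "signature_preset")
  validate_preset(p)
}

validate_preset <- function(p) {
  with(p, {
    if (!is.numeric(amplitude) || amplitude < 0)
      stop(sprintf("preset '%s': amplitude must be >= 0", id))
    if (!is.numeric(baseline) || baseline <= 0)
      stop(sprintf("preset '%s': baseline must be > 0", id))
    if (onset < 0)
      stop(sprintf("preset '%s': onset delay must be >= 0", id))
    if (amplitude > 0 && ttp <= onset)
      stop(sprintf("preset '%s': time-to-peak must exceed onset delay", id))
    if (sustained > amplitude)
      stop(sprintf("preset '%s': sustained elevation exceeds amplitude", id))
    if (!is.na(inhibition) && (inhibition < 0 || inhibition > 1))
      stop(sprintf("preset '%s': inhibition fraction must lie in [0, 1]", id))
    if (dose < 0 || dose_threshold < 0)
      stop(sprintf("preset '%s': doses must be >= 0", id))
  })
  p
}

#' @export
print.signature_preset <- function(x, ...) {
  cat(sprintf(
    "signature_preset %s: %s %s + %g %s %s | Delta %.3g M, ttp %g s%s%s\n",
    x$id, x$species, x$tissue, x$dose, x$dose_units, x$stimulus,
    x$amplitude, x$ttp,
    if (x$onset > 0) sprintf(", onset %g s", x$onset) else "",
    if (x$la3plus) " [La3+]" else ""))
  invisible(x)
}

#' Rescale a preset to a different stimulus dose
#'
#' Amplitude-like parameters follow a Hill-type saturating dose curve
#' (coefficient 2) that is zero at and below the preset's threshold dose
#' and normalised to 1 at the reference dose. Above the reference optimum
#' an optional high-dose decline factor attenuates the response
#' (hydrogen-peroxide behaviour). Kinetic timings are unchanged.
#'
#' @param preset a [signature_preset()].
#' @param dose new dose (same units as the preset's reference dose, >= 0).
#' @param hill_n Hill coefficient of the dose curve.
#' @return a [signature_preset()] at the new dose.
#' @export
dose_scale <- function(preset, dose, hill_n = 2) {
  stopifnot(inherits(preset, "signature_preset"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("`dose` must be a single non-negative number")
  hill <- function(d) {
    x <- d - preset$dose_threshold
    if (x <= 0) return(0)
    x^hill_n / (x^hill_n + preset$dose_halfsat^hill_n)
  }
  decline <- function(d) {
    if (is.na(preset$dose_decline) || d <= preset$dose) return(1)
    preset$dose_decline^((d - preset$dose) / preset$dose)
  }
  ref <- hill(preset$dose)
  scale <- if (ref > 0) hill(dose) * decline(dose) / ref else 0
  out <- preset
  out$dose <- dose
  out$amplitude <- preset$amplitude * scale
  out$sustained <- preset$sustained * scale
  out$osc_amp <- preset$osc_amp * scale
  validate_preset(out)
}

#' Apply lanthanum channel-block inhibition to a preset
#'
#' Models 1 mM LaCl3 pre-treatment: every amplitude-like parameter is
#' multiplied by `1 - inhibition`, leaving kinetics untouched.
#'
#' @param preset a [signature_preset()] with its `inhibition` fraction set.
#' @return the blocked [signature_preset()] (flagged `la3plus`).
#' @export
apply_blocker <- function(preset) {
  stopifnot(inherits(preset, "signature_preset"))
  if (is.na(preset$inhibition))
    stop(sprintf("preset '%s' has no inhibition fraction", preset$id))
  keep <- 1 - preset$inhibition
  out <- preset
  out$amplitude <- preset$amplitude * keep
  out$sustained <- preset$sustained * keep
  out$osc_amp <- preset$osc_amp * keep
  out$la3plus <- TRUE
  out$id <- paste0(preset$id, "_la")
  validate_preset(out)
}

#' The shipped signature-preset library
#'
#' Loads the package's default library of stimulus x dose x tissue x
#' species presets (barley and Arabidopsis; NaCl, mannitol, H2O2, flg22 at
#' their reference doses).
#'
#' @return named list of [signature_preset()] objects.
#' @export
preset_library <- function() {
  load_presets(system.file("extdata", "signature_presets.json",
                           package = "aeqsig", mustWork = TRUE))
}

# Amplitude multipliers along the leaf blade (tip = S1), per stimulus and
# plant age. Values encode the observed developmental gradients: NaCl
# response grows towards the growing leaf base, H2O2 is tip-dominant in
# young leaves and U-shaped in older ones, flg22 is flat with a slight
# mid-blade elevation at 7 days.
section_gradients <- list(
  `5` = list(
    NaCl  = c(0.50, 0.625, 0.75, 0.875, 1.00),
    H2O2  = c(1.00, 0.85, 0.70, 0.55, 0.40),
    flg22 = rep(1, 5)),
  `7` = list(
    NaCl  = seq(0.40, 1.00, length.out = 10),
    H2O2  = c(1.00, 0.85, 0.70, 0.55, 0.40, 0.45, 0.55, 0.70, 0.85, 1.00),
    flg22 = c(1, 1, 1, 1, 1.15, 1.15, 1.15, 1, 1, 1))
)

#' Leaf-blade section presets along the developmental gradient
#'
#' Splits a barley leaf into consecutive 5-mm sections (tip = S1) and
#' returns one preset per section whose amplitude follows the stimulus- and
#' age-specific spatial profile: NaCl increasing tip-to-base, H2O2
#' decreasing (5-day) or U-shaped (7-day), flg22 flat (5-day) or slightly
#' elevated mid-blade (7-day).
#'
#' @param age_days leaf age, 5 (5 sections) or 7 (10 sections).
#' @param stimulus `"NaCl"`, `"H2O2"` or `"flg22"` (mannitol elicits no
#'   leaf response and is not profiled).
#' @param library preset library supplying the leaf-tip reference preset.
#' @return ordered list of [signature_preset()]s, one per section S1..Sn.
#' @export
section_profile_presets <- function(age_days, stimulus,
                                    library = preset_library()) {
  age <- as.character(age_days)
  if (!age %in% names(section_gradients))
    stop("`age_days` must be 5 or 7")
  stimulus <- match.arg(stimulus, c("NaCl", "H2O2", "flg22"))
  grad <- section_gradients[[age]][[stimulus]]
  base_id <- switch(stimulus, NaCl = "hv_leaf_nacl_250",
                    H2O2 = "hv_leaf_h2o2_10", flg22 = "hv_leaf_flg22_200")
  base <- library[[base_id]]
  lapply(seq_along(grad), function(i) {
    p <- base
    p$amplitude <- base$amplitude * grad[i]
    p$sustained <- base$sustained * grad[i]
    p$osc_amp <- base$osc_amp * grad[i]
    p$section_id <- sprintf("S%d", i)
    p$id <- sprintf("%s_%dd_S%d", base_id, age_days, i)
    validate_preset(p)
  })
}
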