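# shared fixtures, built in code

# short protocol for fast unit tests (baseline still >= 10 bins; the
# 120-s discharge leaves only exp(-6) ~ 0.25% of the pool undischarged)
short_config <- function(baseline_s = 30, post_s = 60, discharge_s = 120,
                         ...) {
  sim_config(baseline_s = baseline_s, post_s = post_s,
             discharge_s = discharge_s, ...)
}

# a constant-calcium "preset" (amplitude zero at an arbitrary baseline)
constant_preset <- function(ca = 1e-7) {
  signature_preset(id = sprintf("const_%g", ca), species = "barley",
                   tissue = "leaf", stimulus = "NaCl", dose = 250,
                   dose_units = "mM", baseline = ca, amplitude = 0,
                   ttp = 10, decay_half = 10)
}

# build a ca_trace container directly with prescribed values (white-box
# fixture for the feature extractors)
make_ca_trace <- function(ca, tau = 1, injection = 10L,
                          discharge = length(ca) - 5L,
                          baseline_sd = NULL, flagged = NULL) {
  n <- length(ca)
  bl <- (injection - 9L):injection
  structure(list(
    time = (seq_len(n) - injection) * tau, ca = ca, khat = rep(NA_real_, n),
    tau = tau, injection = as.integer(injection),
    discharge = as.integer(discharge),
    baseline_mean = mean(ca[bl]),
    baseline_sd = if (is.null(baseline_sd)) stats::sd(ca[bl]) else baseline_sd,
    flagged = if (is.null(flagged)) logical(n) else flagged,
    warn = character()), class = "ca_trace")
}

# simulate a preset and run the full inverse pipeline for given seeds;
# returns the per-well feature table
recover_features <- function(preset, seeds, config = sim_config_for(preset),
                             empty_seed_offset = 990L) {
  wells <- lapply(seq_along(seeds), function(i) {
    w <- simulate_well(preset, config, seed = seeds[i])
    w$replicate <- i
    w$well_id <- sprintf("W%03d", i)
    w
  })
  empty <- list(simulate_empty_well(config,
                                    seed = seeds[1] + empty_seed_offset))
  empty[[1]]$well_id <- "E001"
  plate <- structure(list(wells = wells, empty = empty, config = config,
                          seed = seeds[1]), class = "plate_dataset")
  summarize_plate(plate)
}
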