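# preset library, kinetics builder and the stochastic forward model

test_that("the shipped preset library loads and is internally valid", {
  lib <- preset_library()
  expect_length(lib, 16L)
  expect_named(lib)
  for (p in lib) {
    expect_s3_class(p, "signature_preset")
    expect_gte(p$amplitude, 0)
    expect_lte(p$sustained, p$amplitude)
    if (p$amplitude > 0) expect_gt(p$ttp, p$onset)
    if (!is.na(p$inhibition))
      expect_true(p$inhibition >= 0 && p$inhibition <= 1)
  }
  expect_match(attr(lib, "library_version"), ".")
})

test_that("preset invariants are enforced at construction", {
  ok <- function(...) signature_preset(id = "x", species = "barley",
                                       tissue = "leaf", stimulus = "NaCl",
                                       dose = 250, amplitude = 5e-7,
                                       ttp = 20, decay_half = 8, ...)
  expect_s3_class(ok(), "signature_preset")
  expect_error(ok(sustained = 6e-7), "sustained")
  expect_error(ok(inhibition = 1.2), "inhibition")
  expect_error(ok(onset = 25), "time-to-peak")
  expect_error(signature_preset(id = "x", species = "barley",
                                tissue = "leaf", stimulus = "NaCl",
                                dose = 250, amplitude = -1e-7,
                                ttp = 20, decay_half = 8), "amplitude")
})

test_that("dose_scale follows thresholded saturation with high-dose decline", {
  lib <- preset_library()
  flg <- lib$hv_leaf_flg22_200
  expect_equal(dose_scale(flg, 100)$amplitude, 0)   # at threshold: no signal
  expect_equal(dose_scale(flg, flg$dose)$amplitude, flg$amplitude)
  h2o2 <- lib$hv_leaf_h2o2_10
  expect_lt(dose_scale(h2o2, 20)$amplitude, dose_scale(h2o2, 10)$amplitude)
  nacl <- lib$hv_leaf_nacl_250
  amps <- vapply(c(50, 100, 150, 200, 250), function(d)
    dose_scale(nacl, d)$amplitude, numeric(1))
  expect_true(all(diff(amps) > 0))
  expect_error(dose_scale(nacl, -10), "non-negative")
  # sustained and oscillation amplitudes scale with the main amplitude
  man <- lib$hv_root_mannitol_250
  half <- dose_scale(man, 150)
  expect_equal(half$sustained / man$sustained,
               half$amplitude / man$amplitude)
})

test_that("apply_blocker scales amplitudes by 1 - inhibition", {
  lib <- preset_library()
  nacl <- lib$hv_leaf_nacl_250
  blocked <- apply_blocker(nacl)
  expect_equal(blocked$amplitude, nacl$amplitude * 0.2)
  expect_true(blocked$la3plus)
  man <- lib$hv_root_mannitol_250
  expect_equal(apply_blocker(man)$amplitude / man$amplitude, 0.02,
               tolerance = 1e-12)
  none <- nacl; none$inhibition <- 0
  expect_equal(apply_blocker(none)$amplitude, nacl$amplitude)
  expect_error(apply_blocker(lib$at_leaf_nacl_250), "inhibition")
})

test_that("build_ca_trace reproduces the preset kinetics", {
  lib <- preset_library()
  nacl <- lib$hv_leaf_nacl_250
  cfg <- sim_config_for(nacl)
  ca <- build_ca_trace(nacl, cfg)
  nb <- cfg$baseline_s
  post <- ca[(nb + 1):(nb + cfg$post_s)]
  t_post <- seq_len(cfg$post_s)
  expect_equal(max(post) - nacl$baseline, nacl$amplitude, tolerance = 0.01)
  expect_equal(t_post[which.max(post)], nacl$ttp, tolerance = 1)
  # back below 10% of the amplitude by 50 s
  expect_lt(post[50] - nacl$baseline, 0.1 * nacl$amplitude)
  expect_true(all(ca > 0))

  # zero-amplitude preset: constant baseline
  flat <- build_ca_trace(lib$hv_leaf_mannitol_250)
  expect_equal(flat, rep(1e-7, length(flat)))

  # flg22: rise starts at the 90-s onset, peak near 300 s
  flg <- lib$hv_leaf_flg22_200
  cfl <- sim_config_for(flg)
  ca_f <- build_ca_trace(flg, cfl)
  post_f <- ca_f[(cfl$baseline_s + 1):(cfl$baseline_s + cfl$post_s)]
  first_up <- which(post_f > flg$baseline * (1 + 1e-9))[1]
  expect_equal(first_up, 91, tolerance = 2)
  expect_equal(which.max(post_f), 300, tolerance = 2)

  # peak beyond the recording window is rejected
  expect_error(build_ca_trace(flg, sim_config(post_s = 200)), "window")
})

test_that("simulate_well is seed-deterministic and conserves counts", {
  p <- preset_library()$hv_leaf_nacl_250
  cfg <- short_config()
  a <- simulate_well(p, cfg, seed = 42)
  b <- simulate_well(p, cfg, seed = 42)
  expect_identical(a$trace$counts, b$trace$counts)
  expect_false(identical(simulate_well(p, cfg, seed = 43)$trace$counts,
                         a$trace$counts))
  nb <- with(cfg, (baseline_s + post_s + discharge_s) / tau)
  expect_length(a$trace$counts, nb)
  # noise-free total counts minus background = A0 (full 300-s discharge
  # leaves only an exp(-15) pool residual)
  cfg0 <- sim_config(noise = "none")
  nb0 <- with(cfg0, (baseline_s + post_s + discharge_s) / tau)
  w0 <- simulate_well(p, cfg0)
  expect_equal(sum(w0$trace$counts) - cfg0$background * nb0, cfg0$A0,
               tolerance = 1e-4)
})

test_that("Poisson totals match the pool over 100 seeds within 1%", {
  p <- constant_preset(1e-6)
  cfg <- short_config(background = 0)
  totals <- vapply(1:100, function(s)
    sum(simulate_well(p, cfg, seed = s)$trace$counts), numeric(1))
  expect_equal(mean(totals), cfg$A0, tolerance = 0.01)
})

test_that("simulate_plate bookkeeping, metadata and per-well seeds", {
  lib <- preset_library()
  cfg <- short_config()
  design <- list(
    list(preset = "hv_leaf_nacl_250", dose = 100, replicates = 3),
    list(preset = "hv_leaf_nacl_250", replicates = 3))
  plate <- simulate_plate(design, cfg, seed = 5, n_empty = 2, library = lib)
  expect_length(plate$wells, 6L)
  expect_length(plate$empty, 2L)
  expect_equal(vapply(plate$wells, function(w) w$dose, numeric(1)),
               c(100, 100, 100, 250, 250, 250))
  seeds <- vapply(c(plate$wells, plate$empty), function(w) w$seed,
                  integer(1))
  expect_false(anyDuplicated(seeds) > 0)
  # empty wells are background-only Poisson counts
  em <- plate$empty[[1]]$trace$counts
  expect_equal(mean(em), cfg$background * cfg$tau, tolerance = 0.15)
  expect_true(all(em == floor(em)))
})

test_that("section presets follow the stated spatial gradients", {
  amp <- function(ps) vapply(ps, function(p) p$amplitude, numeric(1))
  a5n <- amp(section_profile_presets(5, "NaCl"))
  expect_length(a5n, 5L)
  expect_true(all(diff(a5n) > 0))             # linear increase tip -> base
  a5h <- amp(section_profile_presets(5, "H2O2"))
  expect_true(all(diff(a5h) < 0))             # strongest at the tip
  a5f <- amp(section_profile_presets(5, "flg22"))
  expect_true(all(a5f == a5f[1]))             # flat
  a7h <- amp(section_profile_presets(7, "H2O2"))
  expect_length(a7h, 10L)
  expect_true(all(diff(a7h[1:5]) < 0) && all(diff(a7h[5:10]) > 0))  # U shape
  a7f <- amp(section_profile_presets(7, "flg22"))
  expect_gt(max(a7f[5:7]), a7f[1])            # slight mid-blade elevation
  expect_error(section_profile_presets(6, "NaCl"), "age")
  expect_error(section_profile_presets(5, "mannitol"), "arg")
})
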