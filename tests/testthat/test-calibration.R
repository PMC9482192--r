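# calibration mapping, emission model and trace calibration

test_that("rate/calcium calibration reproduces closed-form values", {
  cal <- aeq_calibration()
  # intercept case: pCa equal to c0 gives -log10 k = 0
  expect_equal(rate_from_calcium(10^(-cal$c0), cal), 1.0, tolerance = 1e-12)
  expect_equal(calcium_from_rate(1.0, cal), 10^(-cal$c0), tolerance = 1e-12)
  # frozen from direct evaluation of 10^(-(pCa - c0)/c1)
  expect_equal(rate_from_calcium(1e-6, cal), 4.73083e-2, tolerance = 1e-5)
  expect_equal(rate_from_calcium(1e-7, cal), 4.65816e-5, tolerance = 1e-5)
  # frozen from pCa = c1*4 + c0
  expect_equal(calcium_from_rate(1e-4, cal), 1.28928e-7, tolerance = 1e-5)
})

test_that("calibration is a strictly increasing inverse pair", {
  cal <- aeq_calibration()
  ca <- 10^seq(-9, -4, length.out = 41)
  k <- rate_from_calcium(ca, cal)
  expect_true(all(diff(k) > 0))
  expect_equal(calcium_from_rate(k, cal), ca, tolerance = 1e-12)
  k2 <- 10^seq(-8, 0, length.out = 33)
  expect_true(all(diff(calcium_from_rate(k2, cal)) > 0))
})

test_that("calibration domain errors and clamping", {
  cal <- aeq_calibration()
  expect_error(rate_from_calcium(0), "positive")
  expect_error(rate_from_calcium(-1e-7), "positive")
  expect_error(calcium_from_rate(0, cal, clamp = FALSE), "positive")
  # sub-floor rates are clamped to the floor value
  expect_equal(calcium_from_rate(1e-20, cal),
               calcium_from_rate(cal$rate_floor, cal))
})

test_that("emission_step conserves the pool and hits the closed form", {
  cal <- aeq_calibration()
  ca01 <- calcium_from_rate(0.01, cal)
  st <- emission_step(1e6, ca01, tau = 1, model = cal)
  expect_equal(st$emitted, 1e6 * (1 - exp(-0.01)), tolerance = 1e-10)
  expect_equal(st$emitted + st$remaining, 1e6)
  # saturation limit and empty pool
  sat <- emission_step(1e6, rate = 100, tau = 10)
  expect_equal(sat$emitted, 1e6)
  expect_equal(sat$remaining, 0, tolerance = 1e-6)
  z <- emission_step(0, ca01)
  expect_identical(c(z$emitted, z$remaining), c(0, 0))
  expect_error(emission_step(-1, ca01), "pool")
  # exact conservation along a sequence
  pool <- 5e6; emitted <- 0
  for (ca in c(1e-7, 5e-7, 1e-6, 2e-7)) {
    st <- emission_step(pool, ca)
    emitted <- emitted + st$emitted; pool <- st$remaining
  }
  expect_equal(emitted + pool, 5e6)
})

test_that("emission_step sequence matches brute-force fine-step integration", {
  # oracle: Euler integration of dA/dt = -k(ca) A at tau/1000 on a
  # piecewise-constant calcium trace
  cal <- aeq_calibration()
  ca_steps <- c(1e-7, 1e-6, 5e-7, 2e-6, 1e-7)
  tau <- 1; nsub <- 1000L
  pool_model <- 1e6; pool_oracle <- 1e6
  for (ca in ca_steps) {
    pool_model <- emission_step(pool_model, ca, tau, cal)$remaining
    k <- rate_from_calcium(ca, cal)
    for (s in seq_len(nsub))
      pool_oracle <- pool_oracle * (1 - k * tau / nsub)
  }
  expect_equal(pool_model, pool_oracle, tolerance = 1e-3)
  expect_equal((1e6 - pool_model) / (1e6 - pool_oracle), 1,
               tolerance = 1e-3)
})

test_that("lmax_remaining is the inclusive reverse cumulative sum", {
  expect_equal(lmax_remaining(c(5, 3, 2)), c(10, 5, 2))
  expect_equal(lmax_remaining(c(5, 3, 2), inclusive = FALSE), c(5, 2, 0))
  expect_equal(lmax_remaining(rep(0, 4)), rep(0, 4))
  set.seed(7)
  for (i in 1:20) {
    counts <- rpois(50, 30)
    rem <- lmax_remaining(counts)
    expect_true(all(diff(rem) <= 0))
    expect_equal(rem[1], sum(counts))
  }
})

test_that("background correction clamps, flags and is identity at zero", {
  tr <- lum_trace(c(25, 22, 20, 30, 40, 50, 80, 100, 20, 10, 5, 2),
                  injection = 3, discharge = 8)
  out <- background_correct(tr, 20)
  expect_equal(out$counts[1:3], c(5, 2, 0))
  expect_true(out$clamped[3])
  expect_false(any(out$clamped[1:2]))
  expect_true(out$corrected)
  id <- background_correct(tr, 0)
  expect_equal(id$counts, tr$counts)
  swamped <- background_correct(tr, 1000)
  expect_true("background_exceeds_signal" %in% swamped$warn)
})

test_that("background estimate from empty wells is unbiased (Monte Carlo)", {
  cfg <- short_config()
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 150L
    signal <- 200
    counts <- rpois(n, signal + cfg$background)
    empty <- rpois(n, cfg$background)
    bg_hat <- estimate_background(empty, tau = 1)
    mean(counts - bg_hat) - signal
  }, numeric(1))
  # mean residual error shrinks with replication: SE of the mean over 100
  # seeds is ~ sqrt((220+20/150)/150)/10 ~ 0.12 counts
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("noise-free constant-calcium round trip recovers calcium per bin", {
  # full 300-s discharge so the undischarged pool residual is negligible
  cfg <- sim_config(noise = "none", background = 0)
  for (spec in list(list(ca = 1e-6, tol = 0.03), list(ca = 1e-7, tol = 0.01))) {
    w <- simulate_well(constant_preset(spec$ca), cfg)
    tr <- calibrate_trace(background_correct(w$trace, 0))
    pre <- 1:tr$discharge
    expect_true(all(abs(tr$ca[pre] / spec$ca - 1) < spec$tol))
  }
})

test_that("calibration is invariant to scaling counts and pool by 10x", {
  cfg <- short_config(noise = "none", background = 0)
  w <- simulate_well(preset_library()$hv_leaf_nacl_250,
                     short_config(noise = "none", background = 0))
  t1 <- calibrate_trace(background_correct(w$trace, 0))
  scaled <- lum_trace(w$trace$counts * 10, tau = w$trace$tau,
                      injection = w$trace$injection,
                      discharge = w$trace$discharge)
  t2 <- calibrate_trace(background_correct(scaled, 0))
  expect_equal(t2$ca, t1$ca, tolerance = 1e-12)
})

test_that("calibrate_trace validates input and flags pathologies", {
  cfg <- short_config(noise = "none", background = 0)
  w <- simulate_well(constant_preset(1e-6), cfg)
  expect_error(calibrate_trace(w$trace), "background-corrected")
  corr <- background_correct(w$trace, 0)
  # too-short baseline
  expect_error(calibrate_trace(lum_trace(corr$counts[26:150], injection = 5,
                                         discharge = 65, corrected = TRUE)),
               "baseline")
  # zero-count bins are flagged and floored, not turned into -Inf
  counts <- corr$counts; counts[40] <- 0
  tr <- calibrate_trace(lum_trace(counts, injection = 30, discharge = 90,
                                  corrected = TRUE))
  expect_true(tr$flagged[40])
  expect_true(all(is.finite(tr$ca)) && all(tr$ca > 0))
  # saturation warning when >90% of counts precede discharge
  hot <- c(rep(1000, 99), rep(1, 21))
  sat <- calibrate_trace(lum_trace(hot, injection = 30, discharge = 99,
                                   corrected = TRUE))
  expect_true("saturation" %in% sat$warn)
})
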