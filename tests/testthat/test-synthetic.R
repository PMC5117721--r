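test_that("arc plans hit the requested geometry and determinism", {
  plan <- make_arc_plan(n_cp = 90, arc_span = 360, seed = 2)
  expect_equal(length(plan$mu), 90)
  expect_equal(diff(plan$gantry)[1], 4)  # 90 equi-spaced CPs over 360 deg
  expect_equal(sum(plan$mu), plan$total_mu, tolerance = 1e-9)
  # zero modulation: identical apertures, uniform MU
  p0 <- make_arc_plan(n_cp = 12, modulation = 0, seed = 5)
  expect_equal(max(apply(p0$leaves_a, 2, function(x) diff(range(x)))), 0)
  expect_lt(diff(range(p0$mu)), 1e-9)
  # determinism
  expect_identical(make_arc_plan(20, seed = 9), make_arc_plan(20, seed = 9))
  expect_false(identical(make_arc_plan(20, seed = 9)$mu,
                         make_arc_plan(20, seed = 10)$mu))
})

test_that("a zero error model replays the plan exactly", {
  # cadence and MU pulses aligned with plan CP boundaries: the coarse
  # discretization recovers the plan CP MUs exactly
  plan <- make_arc_plan(n_cp = 10, arc_span = 60, modulation = 0.4,
                        total_mu = 120, seed = 4)
  out <- emulate_delivery(plan, error_model = list(), gantry_speed = 6,
                          mu_pulse_hz = 1, seed = 4)
  expect_equal(out$log$total_mu, plan$total_mu, tolerance = 1e-9)
  arc <- discretize(out$log, "coarse")
  expect_equal(length(arc$mu), length(plan$mu))
  expect_equal(arc$mu, plan$mu, tolerance = 1e-9)
  expect_true(all(out$x_star_plan == 1))
})

test_that("MU drift defines bounded, seed-stable ground-truth weights", {
  plan <- make_arc_plan(n_cp = 30, seed = 6)
  out <- emulate_delivery(plan, error_model = list(mu_drift = 0.05),
                          seed = 6)
  # bounded by construction (5% nominal, small renormalization slack)
  expect_true(all(out$x_star_plan > 0.93 & out$x_star_plan < 1.07))
  # total MU conserved by the truth weights
  expect_equal(sum(plan$mu * out$x_star_plan), plan$total_mu,
               tolerance = 1e-9)
  out2 <- emulate_delivery(plan, error_model = list(mu_drift = 0.05),
                           seed = 7)
  expect_false(identical(out$x_star_plan, out2$x_star_plan))
  # marginal drift scale is stable across seeds
  sds <- vapply(1:30, function(s) {
    o <- emulate_delivery(plan, error_model = list(mu_drift = 0.05),
                          seed = s)
    sd(o$x_star_fn(seq(0, 1, length.out = 200)))
  }, numeric(1))
  expect_true(all(sds > 0.3 * median(sds) & sds < 2 * median(sds)))
})

test_that("scenarios are deterministic under a fixed seed", {
  a <- make_scenario("static-imrt", seed = 3)
  b <- make_scenario("static-imrt", seed = 3)
  expect_identical(a$films$inner$channels, b$films$inner$channels)
  expect_identical(a$chamber_gy, b$chamber_gy)
  c2 <- make_scenario("static-imrt", seed = 4)
  expect_false(identical(a$films$inner$channels, c2$films$inner$channels))
})

test_that("noiseless synthesis round-trips film dose and chamber reading", {
  sc <- make_scenario("static-imrt", seed = 2)  # noiseless preset
  expect_equal(sc$chamber_gy, sc$truth$iso_dose, tolerance = 1e-12)
  cal <- fit_calibration(sc$cal_doses, sc$cal_values)
  for (nm in names(sc$films)) {
    scan <- lateral_correction(sc$films[[nm]], sc$lateral_profiles[[nm]])
    inv <- multichannel_dose(scan, cal)
    truth_cgy <- sc$truth$maps[[nm]]$dose * 100
    err <- abs(inv$dose - truth_cgy)
    # 0.1 cGy on the bulk; 16-bit quantization admits isolated outliers
    expect_lt(stats::quantile(err, 0.99), 0.1)
    expect_lt(max(err), 0.3)
  }
})

test_that("the zero-noise pipeline closes on the injected ground truth", {
  sc <- make_scenario("prostate-like", seed = 5, film_dose_noise = 0,
                      scanner_noise = 0, misregistration = c(0, 0))
  res <- suppressWarnings(run_verification(sc, register = FALSE))
  expect_lt(max(abs(res$solution$x - res$x_true)), 0.01)
  expect_lt(res$rms_adjusted, res$rms_log)
  expect_lt(abs(sum(res$solution$mu_adjusted) - res$arc$total_mu), 1e-6)
})
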