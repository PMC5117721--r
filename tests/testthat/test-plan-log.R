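test_that("parsing accepts well-formed logs and totals cumulative MU", {
  f <- write_log_fixture(log_df(c(0, 1, 2), c(0, 1, 2), c(0, 10, 20)))
  log <- parse_delivery_log(f)
  expect_s3_class(log, "delivery_log")
  expect_equal(log$total_mu, 20)
  expect_equal(length(log$time), 3)

  # a 120 s beam-on log at 0.25 s cadence holds floor(120/0.25)+1 records
  t <- seq(0, 120, by = 0.25)
  f2 <- write_log_fixture(log_df(t, (t * 2.9) %% 360, seq(0, 240, length.out = length(t))))
  expect_equal(length(parse_delivery_log(f2)$time), 481)
})

test_that("parsing rejects integrity violations with informative errors", {
  expect_error(parse_delivery_log(
    write_log_fixture(log_df(c(0, 1, 2), c(0, 1, 2), c(0, 10, 8)))),
    "cumulative MU decreases")
  df <- log_df(c(0, 1), c(0, 1), c(0, 5))
  df$leaf_a_01 <- c(-10, 15)  # crosses leaf_b_01 = 10
  expect_error(parse_delivery_log(write_log_fixture(df)), "crossed leaves")
  df2 <- log_df(c(0, 1, 1), c(0, 1, 2), c(0, 5, 10))
  expect_error(parse_delivery_log(write_log_fixture(df2)),
               "not strictly increasing")
  df3 <- log_df(c(0, 1), c(0, 400), c(0, 5))
  expect_error(parse_delivery_log(write_log_fixture(df3)), "gantry")
})

test_that("write/parse round trip preserves every field", {
  log <- fx_log()
  f <- tempfile(fileext = ".csv")
  write_delivery_log(log, f)
  log2 <- parse_delivery_log(f)
  for (fld in c("time", "gantry", "mu_cum", "beam_on", "total_mu"))
    expect_equal(log2[[fld]], log[[fld]], tolerance = 1e-12)
  expect_equal(log2$leaves_a, log$leaves_a, tolerance = 1e-12)
  expect_equal(log2$leaves_b, log$leaves_b, tolerance = 1e-12)
})

test_that("coarse discretization keeps one CP per MU-bearing record", {
  f <- write_log_fixture(log_df(0:4, 0:4, c(0, 0, 5, 5, 10)))
  arc <- discretize(parse_delivery_log(f), "coarse")
  expect_equal(length(arc$mu), 2)
  expect_equal(arc$mu, c(5, 5))
  # zero-MU log is an empty arc
  fz <- write_log_fixture(log_df(0:2, 0:2, c(0, 0, 0)))
  expect_error(discretize(parse_delivery_log(fz), "coarse"), "empty arc")
})

test_that("discretization conserves total MU at both levels", {
  log <- fx_log()
  for (arc in list(discretize(log, "coarse"),
                   discretize(log, "fine", 2),
                   discretize(log, "fine", 3))) {
    expect_lt(abs(sum(arc$mu) - log$total_mu), 1e-9)
    expect_true(all(arc$mu > 0))
    expect_true(all(diff(arc$time) > 0))
  }
})

test_that("fine discretization hits the requested CP multiplier", {
  log <- fx_log()
  n_coarse <- length(discretize(log, "coarse")$mu)
  n_fine <- length(discretize(log, "fine", 3)$mu)
  expect_gt(n_fine / n_coarse, 3 * 0.85)
  expect_lt(n_fine / n_coarse, 3 * 1.15)
  expect_gte(length(discretize(log, "fine", 1)$mu), n_coarse)
})

test_that("constant dose rate and speed give uniform fine CP spacing", {
  plan <- make_arc_plan(n_cp = 20, arc_span = 120, modulation = 0,
                        total_mu = 200, seed = 3)
  log <- emulate_delivery(plan, error_model = list(), seed = 3,
                          mu_pulse_hz = 4)$log
  fine <- discretize(log, "fine", 3)
  spac <- diff(fine$gantry)
  spac <- spac[spac > 0]
  expect_lt(max(abs(spac - mean(spac))) / mean(spac), 0.10)
})

test_that("fine CP density follows the MU-per-degree rate", {
  # two sectors: 90% of MU in the first half of the arc
  t <- seq(0, 20, by = 0.25)
  mu <- ifelse(t <= 10, 18 * t, 180 + 2 * (t - 10))
  log <- parse_delivery_log(write_log_fixture(log_df(t, t * 6, mu)))
  fine <- discretize(log, "fine", 3)
  first_half <- sum(fine$gantry <= 60)
  second_half <- sum(fine$gantry > 60)
  expect_gt(first_half / second_half, 2.5)
})

test_that("angular MU distribution bins conserve and localize MU", {
  arc <- structure(list(gantry = c(10, 20, 30, 40), mu = rep(1, 4),
                        total_mu = 4), class = "discretized_arc")
  b <- angular_mu_distribution(arc, 20)
  expect_equal(b$mu, c(2, 2))
  expect_equal(b$angle_lo, c(0, 20))
  # conservation at arbitrary widths
  arc2 <- fx_arc()
  for (w in c(5, 10, 33)) {
    expect_equal(sum(angular_mu_distribution(arc2, w)$mu), arc2$total_mu,
                 tolerance = 1e-12)
  }
  expect_error(angular_mu_distribution(arc2, 0), "bin_width")
})

test_that("coarse and fine binned MU distributions agree", {
  # both levels partition the same cumulative-MU curve: binned totals can
  # differ only by CP intervals straddling a bin edge, bounded by 2% of
  # the treatment MU per 10-degree bin for a continuously sampled log
  plan <- make_arc_plan(n_cp = 25, arc_span = 180, modulation = 0.4,
                        total_mu = 300, seed = 8)
  log <- emulate_delivery(plan, error_model = list(), seed = 8,
                          mu_pulse_hz = 4)$log
  bc <- angular_mu_distribution(discretize(log, "coarse"), 10)
  bf <- angular_mu_distribution(discretize(log, "fine", 3), 10)
  m <- merge(bc, bf, by = c("angle_lo", "angle_hi"), all = TRUE)
  m[is.na(m)] <- 0
  expect_true(all(abs(m$mu.x - m$mu.y) < 0.02 * log$total_mu))
})

test_that("fine refinement reproduces the cumulative MU curve at least as well as coarse", {
  # continuous counter: the recorded curve is the delivery itself
  plan <- make_arc_plan(n_cp = 25, arc_span = 150, modulation = 0.5,
                        total_mu = 250, seed = 11)
  log <- emulate_delivery(plan, error_model = list(), seed = 11,
                          mu_pulse_hz = 4)$log
  gan <- unwrap_angles_for_test(log$gantry)
  curve_err <- function(arc) {
    ga <- unwrap_angles_for_test(arc$gantry)
    rec <- stats::approx(c(gan[1], ga), c(0, arc$mu_cum), xout = gan,
                         rule = 2)$y
    max(abs(rec - log$mu_cum))
  }
  e_coarse <- curve_err(discretize(log, "coarse"))
  e_fine <- curve_err(discretize(log, "fine", 3))
  expect_lte(e_fine, e_coarse + 1e-9)
})
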