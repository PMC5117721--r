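cal_points <- function() c(0, 10, 20, 35, 50, 70, 90, 115, 140, 170, 200,
                           240, 280, 320, 360, 400)

test_that("calibration fit recovers known response parameters", {
  doses <- cal_points()
  pars <- arcqa:::default_film_params()
  vals <- vapply(pars, function(p) film_response(doses, p),
                 numeric(length(doses)))
  cal <- fit_calibration(doses, vals)
  for (ch in c("R", "G", "B")) {
    p <- cal$channels[[ch]]
    expect_true(p$valid)
    for (nm in c("a", "b", "c"))
      expect_lt(abs(p[[nm]] / pars[[ch]][[nm]] - 1), 1e-4)
  }
  # the zero-dose point lies on the fitted curve: v(0) = a - b/c
  p <- cal$channels$G
  expect_equal(p$a - p$b / p$c, film_response(0, p), tolerance = 1e-12)
})

test_that("calibration requires enough points and monotone channels", {
  doses <- cal_points()
  pars <- arcqa:::default_film_params()
  vals <- vapply(pars, function(p) film_response(doses, p),
                 numeric(length(doses)))
  expect_error(fit_calibration(doses[1:10], vals[1:10, ]), ">= 13")
  bad <- vals
  set.seed(5); bad[, 1] <- runif(length(doses))  # scrambled: no monotone trend
  expect_warning(cal <- fit_calibration(doses, bad), "not monotone")
  expect_false(isTRUE(cal$channels$R$valid))
  expect_true(cal$channels$G$valid)
})

test_that("noisy calibration inverts doses within 2 cGy RMS", {
  doses <- cal_points()
  pars <- arcqa:::default_film_params()
  clean <- vapply(pars, function(p) film_response(doses, p),
                  numeric(length(doses)))
  test_doses <- seq(20, 380, by = 40)
  errs <- vapply(1:50, function(rep) {
    set.seed(rep)
    noisy <- clean * (1 + matrix(rnorm(length(clean), 0, 0.005), nrow(clean)))
    cal <- fit_calibration(doses, noisy)
    p <- cal$channels$G
    v <- film_response(test_doses, pars$G)
    inv <- p$c + p$b / (v - p$a)
    sqrt(mean((inv - test_doses)^2))
  }, numeric(1))
  expect_lt(mean(errs), 2)
})

test_that("multichannel inversion recovers a noiseless synthetic dose map", {
  doses <- cal_points()
  pars <- arcqa:::default_film_params()
  vals <- vapply(pars, function(p) film_response(doses, p),
                 numeric(length(doses)))
  cal <- fit_calibration(doses, vals)
  dose_map <- matrix(seq(5, 350, length.out = 15 * 12), 15, 12)
  scan <- film_from_dose(dose_map, pars, noise_sd = 0, quantize = FALSE)
  out <- multichannel_dose(scan, cal)
  expect_lt(max(abs(out$dose - dose_map)), 0.1)
  expect_lt(max(abs(out$disturbance)), 1e-3)
  # unexposed film reads zero dose up to the noise floor
  scan0 <- film_from_dose(matrix(0, 6, 6), pars, noise_sd = 0)
  out0 <- multichannel_dose(scan0, cal)
  expect_lt(max(abs(out0$dose)), 0.5)
})

test_that("a common-mode disturbance is absorbed without biasing dose", {
  doses <- cal_points()
  pars <- arcqa:::default_film_params()
  vals <- vapply(pars, function(p) film_response(doses, p),
                 numeric(length(doses)))
  cal <- fit_calibration(doses, vals)
  dose_map <- matrix(180, 8, 8)
  scan <- film_from_dose(dose_map, pars, noise_sd = 0, quantize = FALSE)
  scan$channels <- scan$channels * 1.02  # +2% on every channel
  out <- multichannel_dose(scan, cal)
  expect_lt(max(abs(out$dose - 180)), 0.5)
  expect_equal(mean(out$disturbance), 0.02, tolerance = 0.002)
})

test_that("disturbance-free mode reduces to green-channel inversion", {
  doses <- cal_points()
  pars <- arcqa:::default_film_params()
  vals <- vapply(pars, function(p) film_response(doses, p),
                 numeric(length(doses)))
  cal <- fit_calibration(doses, vals)
  dose_map <- matrix(c(40, 90, 160, 250), 2, 2)
  scan <- film_from_dose(dose_map, pars, noise_sd = 0, quantize = FALSE)
  out <- multichannel_dose(scan, cal, disturbance = FALSE)
  p <- cal$channels$G
  direct <- p$c + p$b / (scan$channels[, , 2] - p$a)
  expect_equal(out$dose, direct, tolerance = 1e-9)
})

test_that("lateral correction inverts the scanner profile", {
  pars <- arcqa:::default_film_params()
  scan <- film_from_dose(matrix(120, 10, 24), pars, noise_sd = 0,
                         quantize = FALSE)
  flat <- lateral_correction(scan, rep(1, 24))
  expect_equal(flat$channels, scan$channels, tolerance = 1e-15)
  prof <- 1 - 0.03 * seq(-1, 1, length.out = 24)^2
  warped <- scan
  for (k in 1:3) warped$channels[, , k] <-
    sweep(warped$channels[, , k], 2, prof, "*")
  fixed <- lateral_correction(warped, prof)
  expect_lt(max(abs(fixed$channels - scan$channels)), 1e-6)
  # a 3% edge falloff on a uniform film corrects to uniform within 0.2%
  expect_lt(diff(range(fixed$channels[, , 2])) /
              mean(fixed$channels[, , 2]), 0.002)
  expect_error(lateral_correction(scan, rep(1, 5)), "profile length")
  expect_error(lateral_correction(scan, rep(0, 24)), "> 0")
})

test_that("film scan TIFF round trip is lossless at 16 bits", {
  pars <- arcqa:::default_film_params()
  scan <- film_from_dose(matrix(seq(0, 300, length.out = 48), 8, 6), pars,
                         noise_sd = 0.003, seed = 2)
  f <- tempfile(fileext = ".tiff")
  write_film_scan(scan, f)
  scan2 <- read_film_scan(f)
  expect_equal(scan2$channels, scan$channels, tolerance = 1 / 65535)
})

test_that("mutual-information registration recovers known transforms", {
  img <- smooth_map(96, seed = 4)
  # identical images: identity transform
  tr0 <- register_rigid_mi(img, img, pixel_size = 1)
  expect_equal(tr0$shift_px, c(0, 0))
  expect_lt(abs(tr0$rotation_deg), 0.125)  # at most one refinement step
  # pure shift: moving = fixed shifted +2 px; recovery is -2 px
  mov <- apply_rigid(img, c(2, 0), 0)
  mov[is.na(mov)] <- 0
  tr <- register_rigid_mi(mov, img, pixel_size = 1)
  expect_lt(abs(tr$shift_px[1] + 2), 0.5)
  expect_lt(abs(tr$shift_px[2]), 0.5)
  # pure rotation 1.5 deg; recovery is -1.5 deg
  mvr <- apply_rigid(img, c(0, 0), 1.5)
  mvr[is.na(mvr)] <- 0
  tr2 <- register_rigid_mi(mvr, img, pixel_size = 1)
  expect_lt(abs(tr2$rotation_deg + 1.5), 0.25)
})

test_that("registration recovers random in-bound transforms (property)", {
  img <- smooth_map(96, seed = 9)
  for (s in 1:4) {
    set.seed(100 + s)
    sh <- runif(2, -1.5, 1.5); ro <- runif(1, -1.5, 1.5)
    mov <- apply_rigid(img, sh, ro)
    mov[is.na(mov)] <- 0
    tr <- register_rigid_mi(mov, img, pixel_size = 1)
    expect_lt(abs(tr$shift_px[1] + sh[1]), 0.5)
    expect_lt(abs(tr$shift_px[2] + sh[2]), 0.5)
    expect_lt(abs(tr$rotation_deg + ro), 0.35)
  }
})
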