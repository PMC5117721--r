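test_that("phantom setups have the specified geometry and density", {
  small <- fx_phantom()
  expect_equal(small$phantom$diameter, 200)
  expect_equal(small$phantom$length, 280)
  big <- build_phantom("big", voxel_size = c(5, 5, 5), z_extent = 30)
  expect_equal(big$phantom$diameter / 2, 150)
  # density: PMMA inside, air outside
  pts <- arcqa:::grid_points(small$grid)
  r2 <- pts[, 1]^2 + pts[, 2]^2
  inside <- r2 <= (99)^2
  outside <- r2 >= (103)^2
  expect_true(all(small$grid$density[inside] == 1.19))
  expect_true(all(small$grid$density[outside] < 0.01))
  # scroll depths: outer at 10 mm, inner at 60 mm
  expect_equal(small$phantom$scrolls$radius,
               c(90, 40))
})

test_that("scroll pixel width follows the radius and azimuthal step", {
  ph <- fx_phantom()
  g <- ph$grid
  g$values <- array(1, dim = g$shape)
  s <- extract_scroll(g, radius = 90, z_range = c(-40, 40), dtheta = 0.5)
  expect_equal(s$pixel_width, 90 * 0.5 * pi / 180, tolerance = 1e-12)
  expect_equal(round(s$pixel_width, 4), 0.7854)
  expect_equal(ncol(s$values), round(360 / 0.5))
  # unrolled width spans the full circumference within one pixel
  expect_lt(abs(s$pixel_width * ncol(s$values) - 2 * pi * 90),
            s$pixel_width + 1e-9)
  # uniform field unrolls to a uniform scroll
  expect_true(all(abs(s$values - 1) < 1e-12))
  expect_error(extract_scroll(g, radius = 500, z_range = c(-40, 40)),
               "geometry error")
})

test_that("scroll sampling reproduces a closed-form field", {
  # f(x, y, z) = x sampled on the cylinder gives r * sin(theta) with the
  # azimuth origin at the gantry-0 entrance (+y)
  g <- dose_grid(c(81, 81, 11), voxel_size = c(2.5, 2.5, 5))
  pts <- arcqa:::grid_points(g)
  g$values <- array(pts[, 1] - min(pts[, 1]), dim = g$shape)  # keep >= 0
  s <- extract_scroll(g, radius = 60, z_range = c(-10, 10), dtheta = 2)
  expected <- 60 * sin(s$thetas * pi / 180) - min(pts[, 1])
  for (i in seq_along(s$z))
    expect_equal(s$values[i, ], expected, tolerance = 1e-6)
})

test_that("rotating the dose field circularly shifts the scroll", {
  g <- dose_grid(c(81, 81, 5), voxel_size = c(2.5, 2.5, 5))
  pts <- arcqa:::grid_points(g)
  th <- atan2(pts[, 1], pts[, 2])
  g$values <- array(2 + sin(2 * th), dim = g$shape)
  s0 <- extract_scroll(g, 60, c(-5, 5), dtheta = 1)
  # rotate the field by 90 deg about z (x,y) -> values at rotated azimuth
  g2 <- g
  g2$values <- array(2 + sin(2 * (th - pi / 2)), dim = g$shape)
  s90 <- extract_scroll(g2, 60, c(-5, 5), dtheta = 1)
  shifted <- s0$values[, c(271:360, 1:270), drop = FALSE]
  expect_equal(s90$values, shifted, tolerance = 1e-9)
})

test_that("the five-shift ensemble is exact for constant and linear fields", {
  g <- dose_grid(c(61, 61, 9), voxel_size = c(2.5, 2.5, 5))
  g$values <- array(3, dim = g$shape)
  e <- scroll_ensemble(g, 50, c(-10, 10), dtheta = 2)
  expect_true(all(abs(e$values - 3) < 1e-12))
  expect_true(all(abs(e$envelope_max - e$envelope_min) < 1e-12))
  # linear field: +/- shifts cancel in the mean
  pts <- arcqa:::grid_points(g)
  g$values <- array(5 + 0.01 * pts[, 1] + 0.02 * pts[, 2], dim = g$shape)
  e2 <- scroll_ensemble(g, 40, c(-10, 10), dtheta = 2)
  s2 <- extract_scroll(g, 40, c(-10, 10), dtheta = 2)
  expect_equal(e2$values, s2$values, tolerance = 1e-9)
  # positional uncertainty equals the in-plane voxel pitch (1.25 mm at the
  # default grid)
  gd <- dose_grid(c(21, 21, 5))
  gd$values <- array(1, dim = gd$shape)
  ed <- scroll_ensemble(gd, 8, c(-2, 2), dtheta = 10)
  expect_equal(ed$position_uncertainty, 1.25)
})

test_that("scroll TIFF round trip preserves geometry and dose", {
  ph <- fx_phantom()
  g <- ph$grid
  pts <- arcqa:::grid_points(g)
  g$values <- array(1 + cos(atan2(pts[, 1], pts[, 2])), dim = g$shape)
  s <- extract_scroll(g, 90, c(-20, 20), dtheta = 2)
  f <- tempfile(fileext = ".tiff")
  write_scroll(s, f)
  s2 <- read_scroll(f)
  expect_equal(s2$radius, s$radius)
  expect_equal(s2$pixel_width, s$pixel_width)
  # 16-bit quantization bounds the round-trip error
  expect_lt(max(abs(s2$values - s$values)), max(s$values) / 65535 * 1.01)
})
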