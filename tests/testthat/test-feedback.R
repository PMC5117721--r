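mk_scroll <- function(values, radius = 90, dtheta = 10) {
  arcqa:::as_scroll(values, radius,
                    (seq_len(ncol(values)) - 1) * dtheta,
                    seq_len(nrow(values)) * 5, dtheta, 5)
}

test_that("measurement assembly counts rows as specified", {
  s1 <- mk_scroll(matrix(1, 10, 10))
  s2 <- mk_scroll(matrix(1, 10, 10), radius = 40)
  mv <- assemble_measurements(list(s1, s2), chamber_gy = 2, threshold = 0,
                              downsample = 1)
  expect_equal(length(mv$d), 201)  # 2 x 100 pixels + chamber
  expect_equal(as.character(tail(mv$source, 1)), "chamber")
  expect_equal(mv$weights[length(mv$weights)], 200 / 100)
  # threshold excluding one scroll keeps the other + chamber
  s_low <- mk_scroll(matrix(0.05, 10, 10))
  s_high <- mk_scroll(matrix(1, 10, 10), radius = 40)
  mv2 <- assemble_measurements(list(outer = s_low, inner = s_high),
                               chamber_gy = 2, threshold = 0.2)
  expect_equal(sort(unique(as.character(mv2$source))),
               c("chamber", "inner"))
  # downsampling by 2 keeps about a quarter of the pixels
  mv3 <- assemble_measurements(list(s1), chamber_gy = 2, threshold = 0,
                               downsample = 2)
  expect_equal(mv3$n_scroll_rows, 25)
  expect_error(assemble_measurements(list(s_low), chamber_gy = 2,
                                     threshold = 1.5), "above threshold")
  expect_error(assemble_measurements(list(s1), chamber_gy = 0), "> 0")
})

test_that("the adjustment recovers noiseless in-bound weights exactly", {
  C <- fx_contrib()
  arc <- fx_arc()
  set.seed(21)
  xs <- runif(length(arc$mu), 0.93, 1.07)
  xs <- xs * sum(arc$mu) / sum(arc$mu * xs)  # total-MU consistent truth
  d <- as.vector(C$entries %*% (xs * arc$mu))
  sol <- solve_mu_adjustment(C, d, constraint_set(arc))
  expect_lt(max(abs(sol$x - xs)), 1e-6)
  expect_lt(abs(sum(sol$mu_adjusted) - arc$total_mu), 1e-6)
})

test_that("measurements equal to the log prediction leave MU unchanged", {
  C <- fx_contrib()
  arc <- fx_arc()
  d <- as.vector(C$entries %*% arc$mu)
  sol <- solve_mu_adjustment(C, d, constraint_set(arc))
  expect_lt(max(abs(sol$x - 1)), 1e-7)
  expect_lt(max(abs(sol$change_pct)), 1e-5)
})

test_that("degenerate bounds pin the solution to the log file", {
  C <- fx_contrib()
  arc <- fx_arc()
  set.seed(3)
  d <- as.vector(C$entries %*% arc$mu) * runif(nrow(C$entries), 0.8, 1.2)
  sol <- solve_mu_adjustment(C, d,
                             constraint_set(arc, lower = 1, upper = 1,
                                            use_tolerance = FALSE))
  expect_equal(sol$x, rep(1, length(arc$mu)), tolerance = 1e-9)
})

test_that("the adjusted objective never exceeds the feasible starting point", {
  C <- fx_contrib()
  arc <- fx_arc()
  set.seed(31)
  xs <- runif(length(arc$mu), 0.95, 1.05)
  xs <- xs * sum(arc$mu) / sum(arc$mu * xs)
  d <- as.vector(C$entries %*% (xs * arc$mu)) *
    (1 + rnorm(nrow(C$entries), 0, 0.01))
  sol <- suppressWarnings(solve_mu_adjustment(C, d, constraint_set(arc)))
  expect_lte(sol$objective, sol$objective_log + 1e-12)
  # total-MU equality in every solution
  expect_lt(abs(sum(sol$mu_adjusted) - arc$total_mu), 1e-6)
  expect_true(all(sol$x >= 0.9 - 1e-9 & sol$x <= 1.1 + 1e-9))
})

test_that("dimension mismatches and invalid bounds are rejected", {
  C <- fx_contrib()
  arc <- fx_arc()
  expect_error(solve_mu_adjustment(C, rep(1, 5), constraint_set(arc)),
               "dimension mismatch")
  expect_error(constraint_set(arc, lower = 1.05), "bounds")
})

test_that("MU change reports localize and conserve the adjustment", {
  C <- fx_contrib()
  arc <- fx_arc()
  d0 <- as.vector(C$entries %*% arc$mu)
  sol0 <- solve_mu_adjustment(C, d0, constraint_set(arc))
  rep0 <- mu_change_report(sol0, arc)
  expect_true(all(abs(rep0$per_cp$change_pct) < 1e-5))
  expect_lt(abs(rep0$total_difference), 1e-6)
  # perturb the measurements in one azimuthal sector upward: the largest
  # positive MU changes must sit on CPs whose columns support that sector
  sector <- which(atan2(C$points[, 1], C$points[, 2]) * 180 / pi %% 360 < 60)
  d1 <- d0
  d1[sector] <- d1[sector] * 1.06
  sol1 <- suppressWarnings(
    solve_mu_adjustment(C, d1, constraint_set(arc, use_tolerance = FALSE)))
  rep1 <- mu_change_report(sol1, arc, bin_width = 10)
  expect_lt(abs(sum(rep1$binned$dmu)), 1e-6)
  support <- colSums(C$entries[sector, , drop = FALSE])
  top_changed <- order(sol1$change_pct, decreasing = TRUE)[1:5]
  top_support <- order(support, decreasing = TRUE)[1:20]
  expect_true(all(top_changed %in% top_support))
})

test_that("infeasible tolerances relax progressively with warnings", {
  C <- fx_contrib()
  arc <- fx_arc()
  set.seed(4)
  d <- as.vector(C$entries %*% arc$mu) * 1.3  # 30% off: outside 10% bounds
  w <- capture_warnings(
    sol <- solve_mu_adjustment(C, d,
                               constraint_set(arc, tol_pct = 1,
                                              tol_floor_gy = 0.001,
                                              max_relax = 12)))
  expect_true(any(grepl("relaxing", w)))
  expect_gt(sol$relaxations, 0)
})
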