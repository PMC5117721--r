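# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# small phantom grid (coarse voxels for speed)
fx_phantom <- function() fixture("phantom", function()
  build_phantom("small", voxel_size = c(2.5, 2.5, 2.5), z_extent = 70))

# a modulated delivery log + discretizations
fx_log <- function() fixture("log", function() {
  plan <- make_arc_plan(n_cp = 30, arc_span = 180, modulation = 0.4,
                        total_mu = 300, seed = 7)
  emulate_delivery(plan, error_model = list(mu_drift = 0.04,
                                            leaf_jitter = 0.3,
                                            angle_jitter = 0.1),
                   seed = 7)$log
})

fx_arc <- function() fixture("arc", function() discretize(fx_log(), "coarse"))

# small contribution matrix over scroll-like sample points
fx_contrib <- function() fixture("contrib", function() {
  ph <- fx_phantom()
  pts <- scroll_points(90, seq(0, 354, by = 6), seq(-40, 40, by = 10))
  build_contribution_matrix(fx_arc(), ph$grid, model = beam_model(),
                            points = pts)
})

# tiny grid with density for engine tests
fx_engine_grid <- function() fixture("engine_grid", function() {
  g <- dose_grid(c(41, 41, 21), voxel_size = c(2.5, 2.5, 2.5))
  g$density <- array(1.0, dim = g$shape)
  g
})

# an open rectangular aperture
open_cp <- function(gantry = 0, half_width = 25, n_pairs = 20) {
  list(gantry = gantry, leaves_a = rep(-half_width, n_pairs),
       leaves_b = rep(half_width, n_pairs))
}

# dose-like random test map: an irregular field with a steep penumbra and
# internal modulation, so both translations and rotations are identifiable
smooth_map <- function(n = 64, seed = 1, peak = 2) {
  set.seed(seed)
  x <- seq(-1, 1, length.out = n)
  cx <- runif(1, -0.15, 0.15); cy <- runif(1, -0.15, 0.15)
  ph <- runif(4, 0, 2 * pi)
  m <- outer(x, x, function(u, v) {
    r <- sqrt((u - cx)^2 + (v - cy)^2)
    ang <- atan2(v - cy, u - cx)
    edge <- 0.55 + 0.12 * sin(2 * ang + ph[1]) + 0.08 * sin(3 * ang + ph[2])
    plateau <- 1 / (1 + exp((r - edge) / 0.06))
    plateau * (1 + 0.12 * sin(4 * u + ph[3]) * sin(3 * v + ph[4]))
  })
  peak * (m - min(m))
}

unwrap_angles_for_test <- function(a) {
  d <- diff(a)
  d <- ((d + 180) %% 360) - 180
  cumsum(c(a[1], d))
}

write_log_fixture <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

# minimal well-formed log data frame with n leaf pairs
log_df <- function(time, gantry, mu, beam = TRUE, n_pairs = 2) {
  df <- data.frame(time_s = time, gantry_deg = gantry, mu_cum = mu,
                   beam_on = beam)
  for (p in seq_len(n_pairs)) {
    df[[sprintf("leaf_a_%02d", p)]] <- -10
    df[[sprintf("leaf_b_%02d", p)]] <- 10
  }
  df
}
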