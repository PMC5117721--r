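#' Synthetic arc plan generator
#'
#' Generates a VMAT-like arc plan: control points equi-spaced over the arc
#' span with smoothly varying random apertures and MU. Aperture centres and
#' widths per leaf pair follow low-order random Fourier series along the
#' arc so that neighbouring CPs overlap laterally, which is what the
#' experimental MU adjustment exploits. `modulation = 0` yields identical
#' apertures and uniform MU.
#'
#' @param n_cp number of control points (>= 2).
#' @param arc_span arc span in degrees.
#' @param modulation complexity knob in `[0, 1]`.
#' @param total_mu total monitor units (default 250).
#' @param start_angle first CP gantry angle (degrees, default 0).
#' @param n_pairs MLC leaf pairs (default 20, 5 mm pitch).
#' @param field_half_width base aperture half-width (mm, default 30).
#' @param seed RNG seed.
#' @return an `arc_plan`: list with `gantry`, `mu`, `leaves_a`, `leaves_b`,
#'   `total_mu`, `arc_span`, `n_pairs`.
#' @export
make_arc_plan <- function(n_cp, arc_span = 120, modulation = 0.3,
                          total_mu = 250, start_angle = 0, n_pairs = 20,
                          field_half_width = 30, seed = 1) {
  stopifnot(n_cp >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gantry <- (start_angle + (seq_len(n_cp) - 1) * arc_span / n_cp) %% 360
  s <- seq(0, 1, length.out = n_cp)
  fourier <- function(amp, n_terms = 3) {
    y <- rep(0, n_cp)
    for (k in seq_len(n_terms))
      y <- y + rnorm(1, 0, amp / k) * sin(2 * pi * k * s + runif(1, 0, 2 * pi))
    y
  }
  mu <- rep(1, n_cp) * (1 + modulation * fourier(0.5))
  mu <- pmax(mu, 0.1)
  mu <- mu / sum(mu) * total_mu
  half_z <- n_pairs * 5 / 2
  pair_v <- -half_z + 5 * (seq_len(n_pairs) - 0.5)
  la <- matrix(0, n_cp, n_pairs); lb <- matrix(0, n_cp, n_pairs)
  for (p in seq_len(n_pairs)) {
    taper <- sqrt(pmax(1 - (pair_v[p] / (half_z + 5))^2, 0.1))
    centre <- modulation * fourier(12)
    width <- field_half_width * taper * (1 + modulation * fourier(0.4))
    width <- pmax(width, 1)
    la[, p] <- pmax(centre - width, -95)
    lb[, p] <- pmin(centre + width, 95)
  }
  plan <- list(gantry = gantry, mu = mu, leaves_a = la, leaves_b = lb,
               total_mu = total_mu, arc_span = arc_span, n_pairs = n_pairs,
               start_angle = start_angle, modulation = modulation,
               seed = seed)
  class(plan) <- "arc_plan"
  plan
}

# smooth multiplicative MU drift over the arc: sum of <= 3 sinusoids with
# random phase, scaled to the requested amplitude; evaluated at arc
# fraction s in [0, 1]
drift_function <- function(amplitude, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 211)
  amps <- rnorm(3, 0, c(1, 0.6, 0.35))
  phases <- runif(3, 0, 2 * pi)
  freqs <- c(1, 2, 3)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  raw <- function(s) {
    y <- rep(0, length(s))
    for (k in 1:3) y <- y + amps[k] * sin(2 * pi * freqs[k] * s + phases[k])
    y
  }
  # normalize peak to the requested amplitude
  sg <- seq(0, 1, length.out = 512)
  peak <- max(abs(raw(sg)), 1e-9)
  list(fn = function(s) 1 + amplitude * raw(s) / peak,
       amplitude = amplitude)
}

#' Emulate an arc delivery, producing a log and ground-truth MU weights
#'
#' Interpolates the plan at the log recording cadence (0.25 s while beam
#' on) assuming constant gantry speed, and injects delivery errors: a
#' smooth multiplicative MU drift (the ground truth `x*` the verification
#' pipeline must recover), plus leaf and gantry jitter written into the
#' recorded positions. The log's cumulative MU records the *reported*
#' (plan-consistent) values: the drift affects what is actually delivered
#' (and hence measured on film), not the machine's own counter, and is
#' normalized to conserve total MU, consistent with the total-MU equality
#' of the adjustment. A zero error model replays the plan exactly and has
#' `x*(s) = 1`.
#'
#' @param plan an `arc_plan`.
#' @param error_model list with `mu_drift` (fractional amplitude, default
#'   0.05), `leaf_jitter` (mm SD, default 0.5), `angle_jitter` (degrees SD,
#'   default 0.2).
#' @param gantry_speed degrees per second (default 6).
#' @param cadence recording interval in seconds (default 0.25).
#' @param mu_pulse_hz update rate of the machine's MU counter (default 1).
#'   The dose servo reports MU in discrete steps, so at a 4 Hz recording
#'   rate most records repeat the previous cumulative MU; records without
#'   MU variation are excluded by the coarse discretization, which is what
#'   keeps coarse CP counts near the plan's CP count for a realistic arc.
#'   Set equal to `1 / cadence` for a continuously updating counter.
#' @param seed RNG seed.
#' @return list with `log` (a `delivery_log`), `x_star_fn` (function of
#'   arc fraction giving the true MU weight), `x_star_plan` (weights at the
#'   plan CPs, total-MU-normalized).
#' @export
emulate_delivery <- function(plan,
                             error_model = list(mu_drift = 0.05,
                                                leaf_jitter = 0.5,
                                                angle_jitter = 0.2),
                             gantry_speed = 6, cadence = 0.25,
                             mu_pulse_hz = 1, seed = 1) {
  em <- utils::modifyList(list(mu_drift = 0, leaf_jitter = 0,
                               angle_jitter = 0), error_model)
  stopifnot(em$mu_drift >= 0, em$leaf_jitter >= 0, em$angle_jitter >= 0)
  duration <- plan$arc_span / gantry_speed
  times <- seq(0, duration, by = cadence)
  if (abs(times[length(times)] - duration) > 1e-9)
    times <- c(times, duration)
  n_cp <- length(plan$mu)
  # plan CP i spans arc fraction ((i-1)/n, i/n]; cumulative MU piecewise
  # linear in arc fraction
  s_plan <- seq_len(n_cp) / n_cp
  cum_plan <- cumsum(plan$mu)
  # MU counter updates at mu_pulse_hz; recorded cumulative MU holds the
  # last reported value between updates
  pulses <- seq(0, duration, by = 1 / mu_pulse_hz)
  if (abs(pulses[length(pulses)] - duration) > 1e-9)
    pulses <- c(pulses, duration)
  mu_at_pulse <- stats::approx(c(0, s_plan), c(0, cum_plan),
                               xout = pulses / duration)$y
  mu_at_pulse[length(mu_at_pulse)] <- plan$total_mu
  s_t <- times / duration
  mu_cum <- mu_at_pulse[findInterval(times + 1e-9, pulses)]
  gantry_unwrapped <- plan$start_angle + s_t * plan$arc_span
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gantry <- gantry_unwrapped +
    if (em$angle_jitter > 0) rnorm(length(times), 0, em$angle_jitter) else 0
  gantry <- pmin(pmax(gantry, 0), 359.999)
  # leaves: linear interpolation of plan apertures in arc fraction + jitter
  interp_leaves <- function(m) {
    out <- apply(m, 2, function(col)
      stats::approx(seq(0, 1, length.out = n_cp), col, xout = s_t)$y)
    matrix(out, nrow = length(s_t))
  }
  la <- interp_leaves(plan$leaves_a)
  lb <- interp_leaves(plan$leaves_b)
  if (em$leaf_jitter > 0) {
    la <- la + matrix(rnorm(length(la), 0, em$leaf_jitter), nrow(la))
    lb <- lb + matrix(rnorm(length(lb), 0, em$leaf_jitter), nrow(lb))
    cross <- la > lb
    mid <- (la + lb) / 2
    la[cross] <- mid[cross] - 0.1; lb[cross] <- mid[cross] + 0.1
  }
  la <- pmax(pmin(la, 100), -100); lb <- pmax(pmin(lb, 100), -100)
  log <- list(time = times, gantry = gantry, mu_cum = mu_cum,
              beam_on = rep(TRUE, length(times)),
              leaves_a = la, leaves_b = lb, n_pairs = plan$n_pairs,
              total_mu = mu_cum[length(mu_cum)],
              arc_span = sum(diff(unwrap_angles(gantry))))
  class(log) <- "delivery_log"
  if (em$mu_drift > 0) {
    dr <- drift_function(em$mu_drift, seed)
    x_raw <- dr$fn
  } else {
    x_raw <- function(s) rep(1, length(s))
  }
  # normalize so the true total MU equals the reported total MU
  s_mid <- (c(0, s_plan[-n_cp]) + s_plan) / 2
  scale <- sum(plan$mu) / sum(plan$mu * x_raw(s_mid))
  x_star_fn <- function(s) x_raw(s) * scale
  list(log = log, x_star_fn = x_star_fn,
       x_star_plan = x_star_fn(s_mid))
}

#' Ground-truth MU weights at the CPs of a discretized arc
#'
#' Evaluates a scenario's smooth drift at the arc fraction of each CP and
#' renormalizes so that total MU is conserved on that discretization.
#'
#' @param scenario a `vmat_scenario` (or the list from
#'   [emulate_delivery()]).
#' @param arc a `discretized_arc` of the scenario's log.
#' @export
true_weights <- function(scenario, arc) {
  s <- arc$mu_cum / arc$total_mu  # arc fraction at CP end
  s_mid <- (c(0, head(s, -1)) + s) / 2
  x <- scenario$x_star_fn(s_mid)
  x * sum(arc$mu) / sum(arc$mu * x)
}

#' Generate an end-to-end verification scenario with known ground truth
#'
#' Builds a complete seeded scenario: arc plan, emulated delivery log,
#' cylindrical phantom, beam model, film calibration, synthetic film scans
#' (outer scroll split into two films, inner scroll one film) and an
#' isocenter chamber reading. The true delivered dose applies the smooth
#' MU drift `x*`; films and chamber measure that truth through the film
#' forward model (calibration response, lateral scanner profile, scanner
#' noise, 16-bit quantization, small rigid misregistration).
#'
#' Presets: `prostate-like` (87-CP plan, full 360 deg arc, moderate
#' modulation, ~60 coarse CPs at the default cadences), `hn-like` (93-CP
#' plan, 360 deg, high modulation, slower gantry, ~80 coarse CPs),
#' `static-imrt` (34-CP plan over 200 deg with a zero error model: the
#' static control case).
#'
#' @param preset scenario preset.
#' @param seed integer seed controlling every random element.
#' @param n_cp,arc_span,modulation,total_mu plan overrides.
#' @param mu_drift,leaf_jitter,angle_jitter delivery error overrides.
#' @param mc_noise relative statistical noise applied to calculated doses
#'   (default 0 here; the pipeline adds its own, see [run_verification()]).
#' @param film_dose_noise multiplicative film dose noise SD (default 0.02
#'   for the VMAT presets, 0 for `static-imrt`); set 0 for a noiseless
#'   scenario.
#' @param scanner_noise film scanner additive noise fraction (default
#'   0.003).
#' @param misregistration max |shift| in mm and |rotation| in degrees for
#'   the random film offset, as `c(mm, deg)` (default `c(1, 0.3)`).
#' @param dtheta_film azimuthal film sampling (degrees, default 2).
#' @param z_step_film axial film sampling (mm, default 2.5).
#' @param z_half_film axial film half-extent (mm, default 50).
#' @param voxel_size phantom grid voxel (default `c(2.5, 2.5, 2.5)` mm for
#'   desk-scale runtimes).
#' @return a `vmat_scenario` list.
#' @export
make_scenario <- function(preset = c("prostate-like", "hn-like",
                                     "static-imrt"),
                          seed = 1, n_cp = NULL, arc_span = NULL,
                          modulation = NULL, total_mu = 500,
                          mu_drift = NULL, leaf_jitter = NULL,
                          angle_jitter = NULL, gantry_speed = NULL,
                          mu_pulse_hz = 1,
                          mc_noise = 0, film_dose_noise = NULL,
                          scanner_noise = 0.003,
                          misregistration = c(1, 0.3),
                          dtheta_film = 2, z_step_film = 2.5,
                          z_half_film = 50,
                          voxel_size = c(2.5, 2.5, 2.5)) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    "prostate-like" = list(n_cp = 87, arc_span = 360, modulation = 0.3,
                           mu_drift = 0.05, leaf_jitter = 0.5,
                           angle_jitter = 0.2, gantry_speed = 6),
    "hn-like" = list(n_cp = 93, arc_span = 360, modulation = 0.5,
                     mu_drift = 0.05, leaf_jitter = 0.5,
                     angle_jitter = 0.2, gantry_speed = 4.5),
    "static-imrt" = list(n_cp = 34, arc_span = 200, modulation = 0.3,
                         mu_drift = 0, leaf_jitter = 0, angle_jitter = 0,
                         gantry_speed = 6))
  if (is.null(n_cp)) n_cp <- defaults$n_cp
  if (is.null(arc_span)) arc_span <- defaults$arc_span
  if (is.null(modulation)) modulation <- defaults$modulation
  if (is.null(mu_drift)) mu_drift <- defaults$mu_drift
  if (is.null(leaf_jitter)) leaf_jitter <- defaults$leaf_jitter
  if (is.null(angle_jitter)) angle_jitter <- defaults$angle_jitter
  if (is.null(gantry_speed)) gantry_speed <- defaults$gantry_speed
  # the static control emulates an exactly reproduced delivery: noiseless
  # measurements unless noise is requested explicitly
  if (is.null(film_dose_noise))
    film_dose_noise <- if (preset == "static-imrt") 0 else 0.02
  plan <- make_arc_plan(n_cp, arc_span, modulation, total_mu, seed = seed)
  deliv <- emulate_delivery(plan,
                            error_model = list(mu_drift = mu_drift,
                                               leaf_jitter = leaf_jitter,
                                               angle_jitter = angle_jitter),
                            gantry_speed = gantry_speed,
                            mu_pulse_hz = mu_pulse_hz, seed = seed)
  ph <- build_phantom("small", voxel_size = voxel_size,
                      z_extent = z_half_film + 20)
  model <- beam_model()
  scen <- list(preset = preset, seed = seed, plan = plan,
               log = deliv$log, x_star_fn = deliv$x_star_fn,
               phantom = ph$phantom, grid = ph$grid, model = model,
               film_params = default_film_params(),
               mc_noise = mc_noise, film_dose_noise = film_dose_noise,
               scanner_noise = scanner_noise,
               misregistration = misregistration,
               dtheta_film = dtheta_film, z_step_film = z_step_film,
               z_half_film = z_half_film)
  class(scen) <- "vmat_scenario"
  scen <- synthesize_measurements(scen)
  scen
}

# film sampling geometry for one scroll radius
film_geometry <- function(scenario, radius, z_lo, z_hi) {
  thetas <- seq(0, 360 - scenario$dtheta_film, by = scenario$dtheta_film)
  zs <- seq(z_lo, z_hi, by = scenario$z_step_film)
  list(radius = radius, thetas = thetas, zs = zs,
       points = scroll_points(radius, thetas, zs),
       pixel_width = radius * scenario$dtheta_film * pi / 180)
}

#' Synthesize film scans and chamber reading for a scenario
#'
#' Computes the true delivered dose (drift-weighted per-CP contributions)
#' at the film sample locations and the isocenter, then pushes the scroll
#' dose maps through the film forward model: calibration response, lateral
#' scanner profile, scanner noise, 16-bit quantization and a small random
#' rigid offset per film. The outer scroll is split into two films (upper
#' and lower axial halves); the inner scroll is one film. Chamber reading
#' adds 0.5% noise (zeroed when `film_dose_noise` is 0).
#'
#' @param scenario a `vmat_scenario`.
#' @return the scenario, augmented with `films`, `chamber_gy`,
#'   `lateral_profiles`, `true_offsets`, `cal_doses`, `cal_values`,
#'   `truth` (true dose maps and weights at the coarse discretization).
#' @export
synthesize_measurements <- function(scenario) {
  arc <- discretize(scenario$log, "coarse")
  x_star <- true_weights(scenario, arc)
  ph <- scenario$phantom
  r_out <- ph$scrolls$radius[ph$scrolls$label == "outer"]
  r_in <- ph$scrolls$radius[ph$scrolls$label == "inner"]
  zh <- scenario$z_half_film
  geoms <- list(
    outer_upper = c(radius = r_out, z_lo = 0, z_hi = zh),
    outer_lower = c(radius = r_out, z_lo = -zh, z_hi = -scenario$z_step_film),
    inner = c(radius = r_in, z_lo = -zh, z_hi = zh)
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed + 677)
  films <- list(); true_maps <- list(); offsets <- list(); lat <- list()
  noisy <- scenario$film_dose_noise > 0
  for (nm in names(geoms)) {
    gsp <- geoms[[nm]]
    fg <- film_geometry(scenario, gsp[["radius"]], gsp[["z_lo"]], gsp[["z_hi"]])
    Cf <- build_contribution_matrix(arc, scenario$grid, model = scenario$model,
                                    points = fg$points)
    dose_gy <- matrix(as.vector(Cf$entries %*% (x_star * arc$mu)),
                      nrow = length(fg$zs), ncol = length(fg$thetas),
                      byrow = TRUE)
    true_maps[[nm]] <- list(dose = dose_gy, geom = fg)
    d_meas <- dose_gy
    if (noisy)
      d_meas <- d_meas * (1 + matrix(rnorm(length(d_meas), 0,
                                           scenario$film_dose_noise),
                                     nrow(d_meas)))
    # rigid misregistration: the film as scanned is offset from the frame
    off <- if (noisy || any(scenario$misregistration > 0)) {
      c(runif(1, -1, 1) * scenario$misregistration[1] / scenario$z_step_film,
        runif(1, -1, 1) * scenario$misregistration[1] / fg$pixel_width,
        runif(1, -1, 1) * scenario$misregistration[2])
    } else c(0, 0, 0)
    if (scenario$preset == "static-imrt" && !noisy) off <- c(0, 0, 0)
    # films wrap the full cylinder: an azimuthal offset is a rotation of
    # the roll, so the column axis is periodic
    d_offset <- apply_rigid(d_meas, off[1:2], off[3], wrap_cols = TRUE)
    d_offset[is.na(d_offset)] <- 0
    offsets[[nm]] <- off
    # lateral scanner profile along the scan width (azimuthal axis)
    w <- ncol(d_offset)
    prof <- 1 - 0.03 * ((seq_len(w) - (w + 1) / 2) / ((w - 1) / 2))^2
    lat[[nm]] <- prof
    films[[nm]] <- film_from_dose(d_offset * 100, scenario$film_params,
                                  lateral_profile = prof,
                                  noise_sd = if (noisy) scenario$scanner_noise else 0,
                                  seed = scenario$seed + 31 + match(nm, names(geoms)))
  }
  C_iso <- build_contribution_matrix(arc, scenario$grid, model = scenario$model,
                                     points = matrix(ph$chamber_point, 1))
  iso_true <- as.vector(C_iso$entries %*% (x_star * arc$mu))
  chamber <- iso_true * (1 + if (noisy) rnorm(1, 0, 0.005) else 0)
  scenario$films <- films
  scenario$lateral_profiles <- lat
  scenario$true_offsets <- offsets
  scenario$chamber_gy <- chamber
  scenario$truth <- list(arc = arc, x_star = x_star, maps = true_maps,
                         iso_dose = iso_true)
  # film calibration data set (16 pieces, 0-400 cGy)
  cal_doses <- c(0, 10, 20, 35, 50, 70, 90, 115, 140, 170, 200, 240, 280,
                 320, 360, 400)
  vals <- vapply(scenario$film_params, function(p)
    film_response(cal_doses, p), numeric(length(cal_doses)))
  if (noisy)
    vals <- vals * (1 + matrix(rnorm(length(vals), 0, 0.005), nrow(vals)))
  scenario$cal_doses <- cal_doses
  scenario$cal_values <- vals
  scenario
}

#' @export
print.vmat_scenario <- function(x, ...) {
  cat("<vmat_scenario> ", x$preset, " | seed ", x$seed, " | ",
      length(x$plan$mu), " plan CPs over ", x$plan$arc_span, " deg | ",
      length(x$truth$arc$mu), " coarse CPs | chamber ",
      sprintf("%.3f", x$chamber_gy), " Gy\n", sep = "")
  invisible(x)
}
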