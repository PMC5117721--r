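# End-to-end verification pipeline: film processing, registration,
# measurement assembly, constrained MU adjustment, reporting.

# wrap a dose matrix into a scroll_image with a given film geometry
as_scroll <- function(values, radius, thetas, zs, dtheta, z_spacing) {
  s <- list(values = values, radius = radius, dtheta = dtheta,
            theta_start = thetas[1], thetas = thetas, z = zs,
            z_spacing = z_spacing, pixel_width = radius * dtheta * pi / 180)
  class(s) <- "scroll_image"
  s
}

#' Synthetic patient model
#'
#' Desk-scale stand-in for a patient CT: a water-density cylinder with a
#' cylindrical planning target volume (PTV) around the isocenter and an
#' adjacent organ-at-risk (OAR) shell, on a configurable grid.
#'
#' @param radius patient cylinder radius (mm, default 100).
#' @param voxel_size grid voxel size (mm), default `c(4, 4, 4)`.
#' @param z_extent axial half-extent of the grid (mm, default 60).
#' @param ptv_radius,ptv_half_length PTV cylinder dimensions (mm).
#' @param oar_offset transverse centre offset of the OAR cylinder (mm).
#' @param oar_radius OAR cylinder radius (mm).
#' @return list with `grid` (a `dose_grid` with density) and `structures`
#'   (named list of logical masks).
#' @export
make_patient <- function(radius = 100, voxel_size = c(4, 4, 4),
                         z_extent = 60, ptv_radius = 25,
                         ptv_half_length = 25, oar_offset = c(0, -45),
                         oar_radius = 15) {
  n <- 2 * ceiling((radius + 5) / voxel_size[1]) + 1
  nz <- 2 * ceiling(z_extent / voxel_size[3]) + 1
  grid <- dose_grid(c(n, n, nz), voxel_size)
  pts <- grid_points(grid)
  r2 <- pts[, 1]^2 + pts[, 2]^2
  body <- r2 <= radius^2
  dens <- array(0.0012, dim = grid$shape)
  dens[body] <- 1.0
  grid$density <- dens
  ptv <- r2 <= ptv_radius^2 & abs(pts[, 3]) <= ptv_half_length
  oar <- (pts[, 1] - oar_offset[1])^2 + (pts[, 2] - oar_offset[2])^2 <=
    oar_radius^2 & abs(pts[, 3]) <= ptv_half_length
  structures <- list(
    body = array(body, dim = grid$shape),
    ptv = array(ptv, dim = grid$shape),
    oar = array(oar & !ptv, dim = grid$shape)
  )
  list(grid = grid, structures = structures)
}

#' Run the full verification pipeline on a scenario
#'
#' Discretizes the scenario's delivery log, converts the synthetic film
#' scans to dose (lateral correction + multichannel inversion), registers
#' each film to the calculated prediction by mutual information, assembles
#' the measurement vector, builds the per-CP contribution matrix at the
#' measurement locations (optionally with Monte-Carlo-like statistical
#' noise), solves the constrained MU adjustment, and reports film-vs-
#' calculation comparisons before and after adjustment plus the absolute
#' chamber check.
#'
#' @param scenario a `vmat_scenario` from [make_scenario()].
#' @param level discretization level (`"coarse"` or `"fine"`).
#' @param target_multiplier fine-level CP multiplier (default 3).
#' @param lower,upper per-CP MU weight bounds (default 0.90 / 1.10).
#' @param tol_pct,tol_floor_gy dose-tolerance inequality parameters.
#' @param use_tolerance include the tolerance inequalities (default TRUE).
#' @param threshold measurement dose threshold (fraction of max).
#' @param downsample measurement downsampling factor (default 2).
#' @param mc_noise relative statistical noise added to the contribution
#'   matrix (default: the scenario's `mc_noise`).
#' @param register run mutual-information registration (default TRUE;
#'   FALSE trusts the film frame, for noiseless closure checks).
#' @param ridge stabilizer passed to [solve_mu_adjustment()].
#' @param compare produce comparison reports per film (default TRUE).
#' @return a `verification_result`: list with `arc`, `solution`,
#'   `measurements`, `x_true` (truth at this discretization),
#'   `film_doses`, `registrations`, `reports_log`, `reports_adjusted`,
#'   `chamber`, `rms_log`, `rms_adjusted` (RMS vs the noiseless truth at
#'   the measurement rows).
#' @export
run_verification <- function(scenario, level = "coarse",
                             target_multiplier = 3,
                             lower = 0.90, upper = 1.10,
                             tol_pct = 3, tol_floor_gy = 0.02,
                             use_tolerance = TRUE,
                             threshold = 0.2, downsample = 2,
                             mc_noise = NULL, register = TRUE,
                             compare = TRUE, ridge = 1e-8) {
  if (is.null(mc_noise)) mc_noise <- scenario$mc_noise
  arc <- discretize(scenario$log, level, target_multiplier)
  cal <- fit_calibration(scenario$cal_doses, scenario$cal_values)
  films <- scenario$films
  scrolls <- list(); regs <- list(); film_doses <- list()
  geoms <- list()
  for (nm in names(films)) {
    tm <- scenario$truth$maps[[nm]]
    fg <- tm$geom
    geoms[[nm]] <- fg
    scan <- lateral_correction(films[[nm]], scenario$lateral_profiles[[nm]])
    inv <- multichannel_dose(scan, cal)
    dmap <- inv$dose / 100  # Gy
    dmap[inv$invalid] <- NA
    film_doses[[nm]] <- dmap
    if (register) {
      # predicted (log-file) dose at the film grid for registration
      Cf <- build_contribution_matrix(arc, scenario$grid,
                                      model = scenario$model,
                                      points = fg$points)
      pred <- matrix(as.vector(Cf$entries %*% arc$mu),
                     nrow = length(fg$zs), byrow = TRUE)
      mov <- dmap; mov[is.na(mov)] <- 0
      tr <- suppressWarnings(
        register_rigid_mi(mov, pred,
                          pixel_size = c(scenario$z_step_film,
                                         fg$pixel_width),
                          wrap_cols = TRUE))
      regs[[nm]] <- tr
      aligned <- apply_rigid(dmap, tr$shift_px, tr$rotation_deg,
                             wrap_cols = TRUE)
    } else {
      regs[[nm]] <- NULL
      aligned <- dmap
    }
    scrolls[[nm]] <- as_scroll(aligned, fg$radius, fg$thetas, fg$zs,
                               scenario$dtheta_film, scenario$z_step_film)
  }
  mv <- assemble_measurements(scrolls, scenario$chamber_gy,
                              scenario$phantom$chamber_point,
                              threshold = threshold,
                              downsample = downsample)
  C <- build_contribution_matrix(arc, scenario$grid, model = scenario$model,
                                 points = mv$points)
  if (mc_noise > 0)
    C$entries <- add_statistical_noise(C$entries, mc_noise,
                                       seed = scenario$seed + 4099)
  cons <- constraint_set(arc, lower, upper, tol_pct, tol_floor_gy,
                         use_tolerance = use_tolerance)
  sol <- solve_mu_adjustment(C, mv, cons, ridge = ridge)
  x_true <- true_weights(scenario, arc)
  # RMS against the noiseless truth at the measurement rows
  C_true <- if (mc_noise > 0)
    build_contribution_matrix(arc, scenario$grid, model = scenario$model,
                              points = mv$points)
  else C
  d_true <- as.vector(C_true$entries %*% (x_true * arc$mu))
  rms <- function(x) sqrt(mean(x^2))
  rms_log <- rms(as.vector(C_true$entries %*% arc$mu) - d_true)
  rms_adj <- rms(as.vector(C_true$entries %*% sol$mu_adjusted) - d_true)
  reports_log <- list(); reports_adj <- list(); chamber <- NULL
  if (compare) {
    for (nm in names(films)) {
      fg <- geoms[[nm]]
      Cf <- build_contribution_matrix(arc, scenario$grid,
                                      model = scenario$model,
                                      points = fg$points)
      mk <- function(w) matrix(as.vector(Cf$entries %*% w),
                               nrow = length(fg$zs), byrow = TRUE)
      film_ref <- scrolls[[nm]]$values
      film_ref[is.na(film_ref)] <- 0
      sp <- c(scenario$z_step_film, fg$pixel_width)
      reports_log[[nm]] <- comparison_report(mk(arc$mu), film_ref, sp)
      reports_adj[[nm]] <- comparison_report(mk(sol$mu_adjusted), film_ref, sp)
    }
  }
  iso_log <- as.vector(
    build_contribution_matrix(arc, scenario$grid, model = scenario$model,
                              points = matrix(scenario$phantom$chamber_point,
                                              1))$entries %*% arc$mu)
  chamber <- list(
    chamber_gy = scenario$chamber_gy,
    log_gy = iso_log,
    log_deviation_pct = point_dose_deviation(iso_log, scenario$chamber_gy))
  res <- list(arc = arc, solution = sol, measurements = mv,
              x_true = x_true, film_doses = film_doses,
              registrations = regs, calibration = cal,
              reports_log = reports_log, reports_adjusted = reports_adj,
              chamber = chamber, rms_log = rms_log, rms_adjusted = rms_adj)
  class(res) <- "verification_result"
  res
}

#' @export
print.verification_result <- function(x, ...) {
  cat("<verification_result> ", length(x$arc$mu), " CPs (", x$arc$level,
      ") | max |MU change| ", sprintf("%.2f", max(abs(x$solution$change_pct))),
      "% | RMS vs truth: log ", sprintf("%.4g", x$rms_log), " Gy -> adjusted ",
      sprintf("%.4g", x$rms_adjusted), " Gy\n", sep = "")
  invisible(x)
}
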