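#' Simplified divergent-beam dose engine
#'
#' A deterministic stand-in for per-control-point Monte Carlo dose
#' calculation, preserving the linear-algebra structure the monitor-unit
#' adjustment consumes: dose is strictly linear in MU, each control point
#' (CP) contributes independently, and the pattern rotates rigidly with the
#' gantry. Per unit MU the engine computes
#' `fluence(u, v) * mu_to_gy * exp(-attenuation_coeff * radiological_depth)`
#' where `(u, v)` are the point's divergent beam's-eye-view coordinates at
#' the isocenter plane, fluence is 1 inside the MLC aperture and
#' `leaf_transmission` under closed leaves with a Gaussian penumbra of
#' width `kernel_sigma` across the leaf-travel direction, and radiological
#' depth is ray-marched through the density grid from the source.
#' Inverse-square falloff is deliberately not modelled, so attenuation along
#' any ray is exactly exponential.
#'
#' @param source_distance source-axis distance (mm), default 1000.
#' @param kernel_sigma lateral penumbra sigma at the isocenter plane (mm).
#' @param mu_to_gy Gy per MU for an open ray at zero depth.
#' @param attenuation_coeff effective linear attenuation (1/mm of
#'   water-equivalent depth); default 0.005 is representative of 6 MV.
#' @param leaf_transmission MLC transmission fraction (default 0.015).
#' @param leaf_width leaf width at the isocenter plane (mm).
#' @param depth_step ray-marching step (mm).
#' @return a `beam_model` object.
#' @export
beam_model <- function(source_distance = 1000, kernel_sigma = 3,
                       mu_to_gy = 0.01, attenuation_coeff = 0.005,
                       leaf_transmission = 0.015, leaf_width = 5,
                       depth_step = 1) {
  stopifnot(source_distance > 0, kernel_sigma > 0, mu_to_gy > 0,
            attenuation_coeff > 0, leaf_transmission >= 0,
            leaf_transmission < 1, leaf_width > 0, depth_step > 0)
  m <- list(source_distance = source_distance, kernel_sigma = kernel_sigma,
            mu_to_gy = mu_to_gy, attenuation_coeff = attenuation_coeff,
            leaf_transmission = leaf_transmission, leaf_width = leaf_width,
            depth_step = depth_step)
  class(m) <- "beam_model"
  m
}

# Gantry angle convention (IEC 61217): at angle g the source sits at
# SAD * (sin g, cos g, 0); the beam axis points to the isocenter. Leaf
# travel (u) is the in-plane direction perpendicular to the beam axis;
# leaf pairs are stacked along z (v).
source_position <- function(gantry_deg, sad) {
  g <- gantry_deg * pi / 180
  c(sad * sin(g), sad * cos(g), 0)
}

# Per-MU dose of one control point at arbitrary points.
# cp: list(gantry, leaves_a (vector, mm), leaves_b) — one aperture.
# density_grid: dose_grid carrying the density array (phantom/patient).
cp_dose_points <- function(points, cp, model, density_grid) {
  points <- rbind(points)
  sad <- model$source_distance
  g <- cp$gantry * pi / 180
  sx <- sad * sin(g); sy <- sad * cos(g)
  # beam frame: t = distance from source along beam axis; u = leaf travel
  t <- sad - (points[, 1] * sin(g) + points[, 2] * cos(g))
  up <- points[, 1] * cos(g) - points[, 2] * sin(g)
  scale <- sad / t
  u <- up * scale
  v <- points[, 3] * scale
  # leaf pair index from v (pairs centred on v = 0)
  np <- length(cp$leaves_a)
  half <- np * model$leaf_width / 2
  pair <- floor((v + half) / model$leaf_width) + 1
  inside <- pair >= 1 & pair <= np
  pair[!inside] <- 1L
  A <- cp$leaves_a[pair]; B <- cp$leaves_b[pair]
  open_frac <- pnorm((u - A) / model$kernel_sigma) -
    pnorm((u - B) / model$kernel_sigma)
  open_frac[!inside] <- 0
  fl <- model$leaf_transmission + (1 - model$leaf_transmission) * open_frac
  if (is.null(density_grid$density))
    stop("density_grid must carry a density field")
  depth <- .ray_depth_cpp(points[, 1], points[, 2], points[, 3],
                          sx, sy, 0,
                          density_grid$density, dim(density_grid$density),
                          density_grid$origin, density_grid$voxel_size,
                          model$depth_step)
  model$mu_to_gy * fl * exp(-model$attenuation_coeff * depth)
}

#' Per-MU dose grid for one control point
#'
#' Evaluates the divergent-beam engine at every voxel centre of `grid`
#' (which must carry a density field). Returns a per-MU `dose_grid`.
#'
#' @param grid a `dose_grid` with a density field.
#' @param cp a single control point: list with `gantry` (degrees) and leaf
#'   vectors `leaves_a`, `leaves_b` (mm at isocenter, A <= B).
#' @param model a `beam_model`.
#' @export
cp_dose <- function(grid, cp, model) {
  if (any(cp$leaves_a > cp$leaves_b + 1e-9)) stop("crossed leaves in aperture")
  pts <- grid_points(grid)
  vals <- cp_dose_points(pts, cp, model, grid)
  dose_grid(grid$shape, grid$voxel_size, grid$origin,
            values = array(vals, dim = grid$shape),
            density = grid$density, per_mu = TRUE)
}

# extract aperture j of an arc as a single-CP list
arc_cp <- function(arc, j) {
  list(gantry = arc$gantry[j],
       leaves_a = arc$leaves_a[j, ], leaves_b = arc$leaves_b[j, ])
}

#' Assemble the per-CP contribution matrix
#'
#' Column j holds the per-MU dose of control point j at the sampled
#' locations, so that the total dose for MU weights `x` is
#' `entries %*% (x * mu)`. Rows may be selected voxels of a grid
#' (`sample_rows` = integer voxel indices in array order) or arbitrary
#' sample points (`points` = n x 3 matrix), e.g. film-scroll samples.
#'
#' @param arc a `discretized_arc`.
#' @param grid a `dose_grid` with density (the transport medium).
#' @param sample_rows integer voxel indices (array order) or NULL.
#' @param model a `beam_model`.
#' @param points optional n x 3 coordinate matrix overriding `sample_rows`.
#' @return a `contribution_matrix`: list with `entries` (rows x CPs, Gy/MU),
#'   `points` (row coordinates), `voxel_index` (or NULL), `mu` (log MU per
#'   CP), `gantry`.
#' @export
build_contribution_matrix <- function(arc, grid, sample_rows = NULL,
                                      model = beam_model(), points = NULL) {
  if (is.null(points)) {
    if (is.null(sample_rows) || length(sample_rows) == 0)
      stop("empty sample_rows")
    pts <- grid_points(grid)[sample_rows, , drop = FALSE]
  } else {
    if (nrow(points) == 0) stop("empty sample points")
    pts <- points
    sample_rows <- NULL
  }
  n_cp <- length(arc$mu)
  entries <- matrix(0, nrow = nrow(pts), ncol = n_cp)
  for (j in seq_len(n_cp))
    entries[, j] <- cp_dose_points(pts, arc_cp(arc, j), model, grid)
  cm <- list(entries = entries, points = pts, voxel_index = sample_rows,
             mu = arc$mu, gantry = arc$gantry, grid_shape = grid$shape,
             grid_origin = grid$origin, grid_voxel = grid$voxel_size)
  class(cm) <- "contribution_matrix"
  cm
}

#' Add Monte-Carlo-like statistical noise to a dose field
#'
#' Independent zero-mean Gaussian perturbation with standard deviation
#' `rel_sigma` times the local dose; negative results are clipped to zero.
#' Reproducible under a fixed seed.
#'
#' @param dose a `dose_grid`, matrix or numeric vector.
#' @param rel_sigma relative sigma (0 <= rel_sigma < 0.1).
#' @param seed integer RNG seed.
#' @export
add_statistical_noise <- function(dose, rel_sigma, seed) {
  stopifnot(rel_sigma >= 0, rel_sigma < 0.1)
  if (rel_sigma == 0) return(dose)
  vals <- if (inherits(dose, "dose_grid")) dose$values else dose
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noisy <- pmax(vals + rnorm(length(vals), 0, rel_sigma * abs(vals)), 0)
  if (inherits(dose, "dose_grid")) {
    dose$values <- array(noisy, dim = dim(vals))
    dose
  } else if (is.matrix(vals)) {
    matrix(noisy, nrow = nrow(vals))
  } else noisy
}

#' @export
print.contribution_matrix <- function(x, ...) {
  cat("<contribution_matrix> ", nrow(x$entries), " samples x ",
      ncol(x$entries), " CPs\n", sep = "")
  invisible(x)
}
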