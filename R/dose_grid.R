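#' Dose grids
#'
#' A `dose_grid` is a 3-D scalar field (Gy, or Gy/MU when flagged per-MU) on
#' a regular voxel grid, optionally paired with a mass-density field
#' (g/cm^3) used for radiological-depth calculations. Axis order is
#' `[x, y, z]` (mm); `origin` is the centre of voxel `[1, 1, 1]`.
#'
#' @param shape integer voxel counts per axis.
#' @param voxel_size voxel size in mm per axis (default `c(1.25, 1.25, 1)`).
#' @param origin centre of the first voxel (mm); default centres the grid
#'   on the isocenter (0, 0, 0).
#' @param values optional 3-D array of dose values (Gy); default zeros.
#' @param density optional 3-D array of densities (g/cm^3); default NULL.
#' @param per_mu logical: values are Gy per MU.
#' @return a `dose_grid` object.
#' @export
dose_grid <- function(shape, voxel_size = c(1.25, 1.25, 1), origin = NULL,
                      values = NULL, density = NULL, per_mu = FALSE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), all(voxel_size > 0))
  if (is.null(origin))
    origin <- -(shape - 1) * voxel_size / 2
  if (is.null(values)) values <- array(0, dim = shape)
  stopifnot(all(dim(values) == shape))
  if (!is.null(density)) stopifnot(all(dim(density) == shape))
  if (any(values < 0)) stop("dose values must be >= 0")
  g <- list(origin = origin, voxel_size = voxel_size, shape = shape,
            values = values, density = density, per_mu = per_mu)
  class(g) <- "dose_grid"
  g
}

# voxel-centre coordinates of every voxel, as an n x 3 matrix in array order
grid_points <- function(grid) {
  d <- grid$shape
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$voxel_size[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$voxel_size[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$voxel_size[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Sample a dose grid at arbitrary points (trilinear)
#'
#' @param grid a `dose_grid`.
#' @param points n x 3 matrix of coordinates (mm).
#' @return numeric vector of interpolated values.
#' @export
sample_grid <- function(grid, points) {
  points <- rbind(points)
  trilinear_interp(grid$values, grid$origin, grid$voxel_size,
                   points[, 1], points[, 2], points[, 3])
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(x$shape, collapse = " x "), " voxels @ ",
      paste(sprintf("%.3g", x$voxel_size), collapse = " x "), " mm",
      if (x$per_mu) " (Gy/MU)" else " (Gy)",
      if (!is.null(x$density)) ", with density" else "", "\n", sep = "")
  invisible(x)
}
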