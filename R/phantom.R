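#' Cylindrical film phantom
#'
#' Builds the PMMA verification phantom: two concentric cylinders hosting
#' rolled radiochromic film at two radial depths (outer scroll at 10 mm
#' depth, inner scroll at 60 mm depth) plus an ionization-chamber point at
#' the isocenter. Two setups exist: `big` (300 mm diameter, 300 mm length)
#' and `small` (200 mm diameter, 280 mm length). Voxels inside the cylinder
#' take PMMA density 1.19 g/cm^3, outside air density 0.0012.
#'
#' @param setup `"big"` or `"small"`.
#' @param voxel_size grid voxel size (mm), default `c(1.25, 1.25, 1)`.
#' @param z_extent optional axial half-extent (mm) of the voxelized grid;
#'   defaults to the full phantom length. Trimming it keeps desk-scale
#'   grids small while covering the film region.
#' @param margin transverse margin (mm) added around the cylinder.
#' @return list with `phantom` (geometry description) and `grid` (a
#'   `dose_grid` whose `density` field holds the voxelized phantom).
#' @export
build_phantom <- function(setup = c("small", "big"),
                          voxel_size = c(1.25, 1.25, 1),
                          z_extent = NULL, margin = 5) {
  setup <- match.arg(setup)
  dims <- if (setup == "big") c(diameter = 300, length = 300)
          else c(diameter = 200, length = 280)
  radius <- dims[["diameter"]] / 2
  scrolls <- data.frame(
    label = c("outer", "inner"),
    depth = c(10, 60),
    radius = radius - c(10, 60)
  )
  if (is.null(z_extent)) z_extent <- dims[["length"]] / 2
  nx <- 2 * ceiling((radius + margin) / voxel_size[1]) + 1
  ny <- 2 * ceiling((radius + margin) / voxel_size[2]) + 1
  nz <- 2 * ceiling(z_extent / voxel_size[3]) + 1
  grid <- dose_grid(c(nx, ny, nz), voxel_size)
  pts <- grid_points(grid)
  r2 <- pts[, 1]^2 + pts[, 2]^2
  inside <- r2 <= radius^2 & abs(pts[, 3]) <= dims[["length"]] / 2
  dens <- array(0.0012, dim = grid$shape)
  dens[inside] <- 1.19
  grid$density <- dens
  phantom <- list(setup = setup, diameter = dims[["diameter"]],
                  length = dims[["length"]], density = 1.19,
                  scrolls = scrolls, chamber_point = c(0, 0, 0))
  class(phantom) <- "phantom_model"
  list(phantom = phantom, grid = grid)
}

#' Cylinder-surface sample coordinates of an unrolled scroll
#'
#' 3-D coordinates (mm) of scroll samples at the given azimuths and axial
#' positions; azimuth 0 is the gantry-0 beam entrance direction (+y),
#' increasing with gantry angle. Points are ordered azimuth-fastest
#' (matching the column-major layout of a `scroll_image` row).
#'
#' @param radius cylinder radius (mm).
#' @param thetas_deg azimuth samples (degrees).
#' @param zs axial samples (mm).
#' @export
scroll_points <- function(radius, thetas_deg, zs) {
  th <- thetas_deg * pi / 180
  cbind(rep(radius * sin(th), times = length(zs)),
        rep(radius * cos(th), times = length(zs)),
        rep(zs, each = length(th)))
}

#' Extract an unrolled film-scroll dose image from a 3-D dose grid
#'
#' Samples the grid on a cylinder of the given radius by trilinear
#' interpolation (optionally nearest-neighbour) every `dtheta` degrees of
#' azimuth and at the grid's axial spacing, producing a planar z-vs-azimuth
#' image matching the geometry of a rolled film. The azimuthal pixel width
#' is `radius * dtheta * pi / 180` mm.
#'
#' @param grid a `dose_grid`.
#' @param radius cylinder radius (mm); must lie inside the grid.
#' @param z_range axial range `c(zmin, zmax)` (mm).
#' @param dtheta azimuthal sampling step in degrees (default 0.5).
#' @param theta_start first azimuth sample (degrees, default 0).
#' @param arc_span azimuthal span to cover (degrees, default 360).
#' @param method `"trilinear"` (default) or `"nearest"`.
#' @return a `scroll_image`: list with `values` (z rows x azimuth columns,
#'   Gy), `radius`, `dtheta`, `theta_start`, `thetas`, `z`, `pixel_width`.
#' @export
extract_scroll <- function(grid, radius, z_range, dtheta = 0.5,
                           theta_start = 0, arc_span = 360,
                           method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  ext_x <- grid$origin[1] + c(0, (grid$shape[1] - 1) * grid$voxel_size[1])
  ext_y <- grid$origin[2] + c(0, (grid$shape[2] - 1) * grid$voxel_size[2])
  if (radius > min(abs(c(ext_x, ext_y))))
    stop("geometry error: cylinder radius ", radius, " outside grid")
  n_az <- round(arc_span / dtheta)
  thetas <- theta_start + (seq_len(n_az) - 1) * dtheta
  zs <- seq(max(z_range[1], grid$origin[3]),
            min(z_range[2], grid$origin[3] + (grid$shape[3] - 1) * grid$voxel_size[3]),
            by = grid$voxel_size[3])
  pts <- scroll_points(radius, thetas, zs)
  vals <- if (method == "trilinear") {
    sample_grid(grid, pts)
  } else {
    idx <- round(sweep(pts, 2, grid$origin) %*% diag(1 / grid$voxel_size))
    idx <- pmin(pmax(idx, 0), matrix(rep(grid$shape - 1, each = nrow(idx)), ncol = 3))
    grid$values[idx + 1]
  }
  scroll <- list(values = matrix(vals, nrow = length(zs), ncol = n_az,
                                 byrow = TRUE),
                 radius = radius, dtheta = dtheta, theta_start = theta_start,
                 thetas = thetas, z = zs,
                 z_spacing = grid$voxel_size[3],
                 pixel_width = radius * dtheta * pi / 180)
  class(scroll) <- "scroll_image"
  scroll
}

#' Shift-ensemble scroll extraction
#'
#' Averages five scroll extractions: unshifted plus the isocenter shifted
#' by plus/minus one in-plane voxel along each transverse axis. This folds
#' the one-voxel positional uncertainty between the calculated grid and the
#' physically rolled film into the reconstructed scroll; the declared
#' positional uncertainty is one in-plane voxel pitch (1.25 mm on the
#' default grid). Min/max envelopes are retained for uncertainty reporting.
#'
#' @inheritParams extract_scroll
#' @return a `scroll_image` with extra fields `envelope_min`,
#'   `envelope_max` and `position_uncertainty` (mm).
#' @export
scroll_ensemble <- function(grid, radius, z_range, dtheta = 0.5,
                            theta_start = 0, arc_span = 360) {
  shifts <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  acc <- NULL
  for (k in seq_len(nrow(shifts))) {
    g <- grid
    g$origin <- grid$origin + c(shifts[k, ] * grid$voxel_size[1:2], 0)
    s <- extract_scroll(g, radius, z_range, dtheta, theta_start, arc_span)
    if (is.null(acc)) {
      acc <- s
      stack <- array(NA_real_, dim = c(dim(s$values), nrow(shifts)))
    }
    stack[, , k] <- s$values
  }
  acc$values <- apply(stack, c(1, 2), mean)
  acc$envelope_min <- apply(stack, c(1, 2), min)
  acc$envelope_max <- apply(stack, c(1, 2), max)
  acc$position_uncertainty <- max(grid$voxel_size[1:2])
  acc
}

#' Write / read a scroll image (16-bit TIFF + JSON header)
#'
#' Dose is linearly scaled to the 16-bit range; the scale and geometry go
#' to a JSON sidecar `<file>.json`.
#'
#' @param scroll a `scroll_image`.
#' @param file output TIFF path.
#' @export
write_scroll <- function(scroll, file) {
  dmax <- max(scroll$values, 1e-12)
  tiff::writeTIFF(scroll$values / dmax, file, bits.per.sample = 16)
  hdr <- list(radius = scroll$radius, dtheta = scroll$dtheta,
              theta_start = scroll$theta_start, z = scroll$z,
              z_spacing = scroll$z_spacing, dose_max = dmax,
              pixel_width = scroll$pixel_width)
  jsonlite::write_json(hdr, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_scroll
#' @export
read_scroll <- function(file) {
  hdr <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(file)
  s <- list(values = img * hdr$dose_max, radius = hdr$radius,
            dtheta = hdr$dtheta, theta_start = hdr$theta_start,
            thetas = hdr$theta_start + (seq_len(ncol(img)) - 1) * hdr$dtheta,
            z = hdr$z, z_spacing = hdr$z_spacing,
            pixel_width = hdr$pixel_width)
  class(s) <- "scroll_image"
  s
}

#' @export
print.scroll_image <- function(x, ...) {
  cat("<scroll_image> r = ", x$radius, " mm, ", nrow(x$values), " z x ",
      ncol(x$values), " az (", x$dtheta, " deg), pixel width ",
      sprintf("%.4f", x$pixel_width), " mm\n", sep = "")
  invisible(x)
}
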