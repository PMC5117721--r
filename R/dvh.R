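#' Reconstruct dose from adjusted MU weights
#'
#' Applies per-CP MU weights to a contribution matrix over the patient (or
#' phantom) grid: `dose = entries %*% (x * mu_log)`. Linear in `x`. When
#' the contribution matrix covers a full grid (built from voxel indices or
#' all voxels), a `dose_grid` is returned; otherwise the bare vector of
#' doses at the sampled points.
#'
#' @param C_patient a `contribution_matrix` over the patient grid.
#' @param x a `mu_solution`, or a bare numeric weight vector (1 = log MU).
#' @param mu_log per-CP log MU; defaults to `C_patient$mu`.
#' @export
reconstruct_dose <- function(C_patient, x, mu_log = NULL) {
  entries <- C_patient$entries
  if (inherits(x, "mu_solution")) {
    mu_log <- x$mu_log
    x <- x$x
  }
  if (is.null(mu_log)) mu_log <- C_patient$mu
  if (ncol(entries) != length(x))
    stop("dimension mismatch: ", ncol(entries), " CP columns vs ",
         length(x), " weights")
  vals <- as.vector(entries %*% (x * mu_log))
  shape <- C_patient$grid_shape
  if (!is.null(shape) && is.null(C_patient$voxel_index) &&
      nrow(entries) == prod(shape)) {
    return(dose_grid(shape, C_patient$grid_voxel, C_patient$grid_origin,
                     values = array(vals, dim = shape)))
  }
  vals
}

#' Cumulative dose-volume histogram
#'
#' Voxel-counting cumulative DVH of a structure: the volume fraction (%)
#' receiving at least each dose level. Voxels belong to the structure by
#' centre inclusion; partial volumes are ignored.
#'
#' @param dose a `dose_grid`, array, or numeric vector of voxel doses.
#' @param mask logical array/vector selecting the structure voxels.
#' @param bin_width dose bin width in Gy (default 0.01).
#' @return a `dvh_curve`: list with `dose` (bin edges, Gy), `volume`
#'   (cumulative %, monotone non-increasing, 100% at dose 0), `n_voxels`.
#' @export
compute_dvh <- function(dose, mask = NULL, bin_width = 0.01) {
  vals <- if (inherits(dose, "dose_grid")) as.vector(dose$values) else
    as.vector(dose)
  if (!is.null(mask)) {
    mask <- as.vector(mask)
    stopifnot(length(mask) == length(vals))
    vals <- vals[mask]
  }
  if (length(vals) == 0) stop("empty structure mask")
  edges <- seq(0, max(vals) + bin_width, by = bin_width)
  # V(d) = % of voxels with dose >= d
  cnt <- length(vals) - findInterval(edges - 1e-12, sort(vals))
  curve <- list(dose = edges, volume = 100 * cnt / length(vals),
                n_voxels = length(vals), bin_width = bin_width)
  class(curve) <- "dvh_curve"
  curve
}

#' DVH metrics
#'
#' `Dmean`, `D<q>` (dose received by at least q% of the volume, e.g. D95,
#' D2) and `V<d>` (volume % receiving at least d Gy) read off a
#' [compute_dvh()] curve by linear interpolation.
#'
#' @param dvh a `dvh_curve`.
#' @param metric e.g. `"Dmean"`, `"D95"`, `"D2"`, `"V2"` (V argument Gy).
#' @export
dvh_metric <- function(dvh, metric) {
  if (metric == "Dmean") {
    # mean dose from the cumulative curve: integral of V(d)/100 over d
    v <- dvh$volume / 100
    return(sum((v[-1] + v[-length(v)]) / 2 * diff(dvh$dose)))
  }
  type <- substr(metric, 1, 1)
  val <- as.numeric(substring(metric, 2))
  if (is.na(val)) stop("unrecognized metric ", metric)
  if (type == "D") {
    # largest dose with V(dose) >= val
    ok <- dvh$volume >= val
    if (!any(ok)) return(0)
    i <- max(which(ok))
    if (i == length(dvh$dose)) return(dvh$dose[i])
    # interpolate between bins i and i+1
    v1 <- dvh$volume[i]; v2 <- dvh$volume[i + 1]
    if (v1 == v2) return(dvh$dose[i])
    dvh$dose[i] + (v1 - val) / (v1 - v2) * (dvh$dose[i + 1] - dvh$dose[i])
  } else if (type == "V") {
    stats::approx(dvh$dose, dvh$volume, xout = val, rule = 2)$y
  } else stop("unrecognized metric ", metric)
}

#' Absolute point-dose check against the chamber reading
#'
#' Percent deviation of the calculated dose at a point from the measured
#' chamber dose: `100 * (dose(point) - chamber) / chamber`, the calculated
#' value taken by trilinear interpolation (optionally averaged over a
#' chamber-sized sphere).
#'
#' @param dose a `dose_grid`.
#' @param point 3-vector (mm).
#' @param chamber_gy measured chamber dose (Gy, > 0).
#' @param average_mm diameter (mm) of a sphere to average over; 0 (default)
#'   compares the point value.
#' @return list with `dose_gy`, `chamber_gy`, `deviation_pct`.
#' @export
point_dose_check <- function(dose, point, chamber_gy, average_mm = 0) {
  if (chamber_gy <= 0) stop("chamber dose must be > 0")
  if (average_mm > 0) {
    r <- average_mm / 2
    offs <- expand.grid(x = seq(-r, r, length.out = 5),
                        y = seq(-r, r, length.out = 5),
                        z = seq(-r, r, length.out = 5))
    offs <- offs[rowSums(offs^2) <= r^2, ]
    pts <- sweep(as.matrix(offs), 2, as.numeric(point), "+")
    dval <- mean(sample_grid(dose, pts))
  } else {
    dval <- sample_grid(dose, matrix(point, nrow = 1))
  }
  list(dose_gy = dval, chamber_gy = chamber_gy,
       deviation_pct = 100 * (dval - chamber_gy) / chamber_gy)
}

#' Percent deviation between a calculated and a measured point dose
#'
#' Scalar helper for absolute-dosimetry tables:
#' `100 * (calculated - measured) / measured`.
#'
#' @param calculated_gy calculated dose (Gy).
#' @param measured_gy measured chamber dose (Gy, > 0).
#' @export
point_dose_deviation <- function(calculated_gy, measured_gy) {
  if (any(measured_gy <= 0)) stop("measured dose must be > 0")
  100 * (calculated_gy - measured_gy) / measured_gy
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, 0-%.2f Gy, Dmean %.3f Gy\n",
              x$n_voxels, max(x$dose), dvh_metric(x, "Dmean")))
  invisible(x)
}
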