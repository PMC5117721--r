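#' Percent dose-difference map and passing rate
#'
#' Per-pixel difference `100 * (eval - ref) / normalization`, evaluated
#' over pixels whose reference dose is at or above `threshold` percent of
#' the reference maximum. The passing rate is the percentage of evaluated
#' pixels with |difference| below `pass_limit` percent (default 3).
#'
#' @param eval,ref co-registered dose maps (same shape).
#' @param normalization normalization dose in Gy (default: max of `ref`,
#'   i.e. global).
#' @param threshold low-dose exclusion threshold, % of reference max
#'   (default 20).
#' @param pass_limit passing criterion in percent (default 3).
#' @return list with `diff_map` (%; NA outside the evaluated region),
#'   `passing_rate` (%), `n_evaluated`.
#' @export
percent_dose_difference <- function(eval, ref, normalization = NULL,
                                    threshold = 20, pass_limit = 3) {
  if (!all(dim(eval) == dim(ref))) stop("shape mismatch between maps")
  if (is.null(normalization)) normalization <- max(ref)
  if (normalization <= 0) stop("normalization must be > 0")
  mask <- ref >= threshold / 100 * max(ref)
  if (!any(mask)) stop("no pixels above threshold")
  dmap <- 100 * (eval - ref) / normalization
  dmap[!mask] <- NA
  list(diff_map = dmap,
       passing_rate = 100 * mean(abs(dmap[mask]) < pass_limit),
       n_evaluated = sum(mask))
}

#' Gamma parameter set
#'
#' @param dose_diff dose-difference criterion, % of the normalization dose.
#' @param dta distance-to-agreement criterion (mm).
#' @param threshold low-dose exclusion, % of reference maximum (default 20).
#' @param normalization `"global"` (% of reference max) or `"local"`.
#' @param search_cap distance-search cap as a multiple of `dta` (default 3).
#' @param upsample reference upsampling factor (default 4).
#' @export
gamma_params <- function(dose_diff = 2, dta = 2, threshold = 20,
                         normalization = c("global", "local"),
                         search_cap = 3, upsample = 4) {
  normalization <- match.arg(normalization)
  stopifnot(dose_diff > 0, dta > 0, threshold >= 0, threshold < 100,
            search_cap >= 1, upsample >= 1)
  p <- list(dose_diff = dose_diff, dta = dta, threshold = threshold,
            normalization = normalization, search_cap = search_cap,
            upsample = as.integer(upsample))
  class(p) <- "gamma_params"
  p
}

# bilinear upsampling of a matrix by an integer factor: output grid places
# sample k at position (k-1)/f in original pixel units (size f*(n-1)+1)
upsample_bilinear <- function(m, f) {
  nr <- nrow(m); nc <- ncol(m)
  ur <- if (nr > 1) seq(1, nr, by = 1 / f) else 1
  uc <- if (nc > 1) seq(1, nc, by = 1 / f) else 1
  matrix(bilinear_interp(m, rep(ur, times = length(uc)),
                         rep(uc, each = length(ur)), fill = NA),
         length(ur), length(uc))
}

#' Gamma-index map
#'
#' Global (or local) gamma analysis of an evaluated against a reference
#' dose distribution:
#' `gamma(r) = min over r' of sqrt(|r - r'|^2 / dta^2 +
#'  (D_eval(r) - D_ref(r'))^2 / (dd * D_norm)^2)`.
#' The reference is upsampled bilinearly before the search; the search is
#' restricted to `search_cap * dta`, and any pixel whose capped minimum
#' exceeds the cap's distance-only bound is re-searched exhaustively, so
#' the result equals the full exhaustive minimum everywhere. Pixels whose
#' reference dose is below threshold are excluded (NA). Gamma <= 1 counts
#' as passing.
#'
#' @param eval,ref dose maps on the same grid.
#' @param params a [gamma_params()] object.
#' @param spacing pixel spacing in mm, scalar or `c(row, col)`.
#' @return list with `gamma_map`, `passing_rate` (%), `n_evaluated`.
#' @export
gamma_map <- function(eval, ref, params = gamma_params(), spacing = 1) {
  if (!all(dim(eval) == dim(ref))) stop("shape mismatch between maps")
  spacing <- rep(spacing, length.out = 2)
  if (any(spacing > params$dta))
    warning("pixel spacing coarser than DTA; gamma may be undersampled")
  dnorm_global <- max(ref)
  mask <- ref >= params$threshold / 100 * max(ref)
  if (!any(mask)) stop("no pixels above threshold")
  f <- params$upsample
  refu <- upsample_bilinear(ref, f)
  spu <- spacing / f
  dd_abs <- params$dose_diff / 100 *
    if (params$normalization == "global") dnorm_global else 1
  cap_mm <- params$search_cap * params$dta
  # offsets on the upsampled grid within the cap
  max_or <- floor(cap_mm / spu[1]); max_oc <- floor(cap_mm / spu[2])
  orv <- -max_or:max_or; ocv <- -max_oc:max_oc
  og <- expand.grid(dr = orv, dc = ocv)
  dist2 <- (og$dr * spu[1])^2 + (og$dc * spu[2])^2
  keep <- dist2 <= cap_mm^2
  og <- og[keep, ]; dist2 <- dist2[keep]
  ord <- order(dist2)
  og <- og[ord, ]; dist2 <- dist2[ord]
  nr <- nrow(eval); nc <- ncol(eval)
  # evaluated pixel (i,j) sits at upsampled index (f*(i-1)+1, f*(j-1)+1)
  g2 <- matrix(Inf, nr, nc)
  dta2 <- params$dta^2
  localnorm <- params$normalization == "local"
  for (k in seq_len(nrow(og))) {
    dr <- og$dr[k]; dc <- og$dc[k]
    # evaluated rows i where shifted upsampled index is in range
    ui <- f * (seq_len(nr) - 1) + 1 + dr
    uj <- f * (seq_len(nc) - 1) + 1 + dc
    iok <- which(ui >= 1 & ui <= nrow(refu))
    jok <- which(uj >= 1 & uj <= ncol(refu))
    if (length(iok) == 0 || length(jok) == 0) next
    sub <- refu[ui[iok], uj[jok], drop = FALSE]
    dd2 <- if (localnorm) {
      ((eval[iok, jok, drop = FALSE] - sub) /
         (params$dose_diff / 100 * pmax(sub, 1e-12)))^2
    } else {
      ((eval[iok, jok, drop = FALSE] - sub) / dd_abs)^2
    }
    cand <- dist2[k] / dta2 + dd2
    cur <- g2[iok, jok, drop = FALSE]
    upd <- cand < cur
    cur[upd] <- cand[upd]
    g2[iok, jok] <- cur
  }
  gmap <- sqrt(g2)
  # pixels whose capped minimum exceeds the cap's pure-distance bound may
  # have their true optimum outside the cap: fall back to exhaustive search
  need <- which(mask & gmap > params$search_cap)
  if (length(need) > 0 && !localnorm) {
    ii <- (need - 1) %% nr + 1; jj <- (need - 1) %/% nr + 1
    gex <- .gamma_exhaustive_cpp(eval[need], c(length(need), 1L),
                                 refu, dim(refu),
                                 f * (ii - 1), f * (jj - 1),
                                 spu[1], spu[2], dd_abs, params$dta,
                                 rep(1L, length(need)))
    gmap[need] <- pmin(gmap[need], gex)
  }
  gmap[!mask] <- NA
  list(gamma_map = gmap,
       passing_rate = 100 * mean(gmap[mask] <= 1 + 1e-9),
       n_evaluated = sum(mask))
}

#' Exhaustive brute-force gamma (oracle)
#'
#' Reference implementation that minimizes over every point of the
#' upsampled reference grid with no search cap, used to validate the
#' optimized [gamma_map()]. Global normalization only.
#'
#' @inheritParams gamma_map
#' @export
gamma_map_exhaustive <- function(eval, ref, params = gamma_params(),
                                 spacing = 1) {
  if (!all(dim(eval) == dim(ref))) stop("shape mismatch between maps")
  spacing <- rep(spacing, length.out = 2)
  mask <- ref >= params$threshold / 100 * max(ref)
  f <- params$upsample
  refu <- upsample_bilinear(ref, f)
  spu <- spacing / f
  dd_abs <- params$dose_diff / 100 * max(ref)
  nr <- nrow(eval); nc <- ncol(eval)
  ii <- rep(seq_len(nr), nc); jj <- rep(seq_len(nc), each = nr)
  g <- .gamma_exhaustive_cpp(as.vector(eval), dim(eval), refu, dim(refu),
                             f * (ii - 1), f * (jj - 1),
                             spu[1], spu[2], dd_abs, params$dta,
                             as.integer(as.vector(mask)))
  gmap <- matrix(g, nr, nc)
  list(gamma_map = gmap,
       passing_rate = 100 * mean(gmap[mask] <= 1 + 1e-9),
       n_evaluated = sum(mask))
}

#' Gamma analysis of 3-D dose grids
#'
#' Same gamma definition on a 3-D grid with (possibly anisotropic) voxel
#' spacing folded into the distance term. The reference is not upsampled;
#' the search visits voxel offsets within the cap. Intended for
#' grid-to-grid comparisons where both distributions share a grid.
#'
#' @param eval,ref 3-D arrays.
#' @param params a [gamma_params()] object.
#' @param spacing voxel spacing `c(dx, dy, dz)` mm.
#' @export
gamma_map_3d <- function(eval, ref, params = gamma_params(), spacing) {
  stopifnot(all(dim(eval) == dim(ref)), length(spacing) == 3)
  mask <- ref >= params$threshold / 100 * max(ref)
  if (!any(mask)) stop("no voxels above threshold")
  dd_abs <- params$dose_diff / 100 * max(ref)
  cap_mm <- params$search_cap * params$dta
  mo <- floor(cap_mm / spacing)
  og <- expand.grid(dx = -mo[1]:mo[1], dy = -mo[2]:mo[2], dz = -mo[3]:mo[3])
  dist2 <- (og$dx * spacing[1])^2 + (og$dy * spacing[2])^2 +
    (og$dz * spacing[3])^2
  keep <- dist2 <= cap_mm^2
  og <- og[keep, ]; dist2 <- dist2[keep]
  d <- dim(eval)
  g2 <- array(Inf, dim = d)
  dta2 <- params$dta^2
  for (k in seq_len(nrow(og))) {
    sx <- og$dx[k]; sy <- og$dy[k]; sz <- og$dz[k]
    xe <- max(1, 1 - sx):min(d[1], d[1] - sx)
    ye <- max(1, 1 - sy):min(d[2], d[2] - sy)
    ze <- max(1, 1 - sz):min(d[3], d[3] - sz)
    if (length(xe) == 0 || length(ye) == 0 || length(ze) == 0) next
    cand <- dist2[k] / dta2 +
      ((eval[xe, ye, ze, drop = FALSE] -
          ref[xe + sx, ye + sy, ze + sz, drop = FALSE]) / dd_abs)^2
    cur <- g2[xe, ye, ze, drop = FALSE]
    upd <- cand < cur
    cur[upd] <- cand[upd]
    g2[xe, ye, ze] <- cur
  }
  gmap <- sqrt(g2)
  gmap[!mask] <- NA
  list(gamma_map = gmap, passing_rate = 100 * mean(gmap[mask] <= 1 + 1e-9),
       n_evaluated = sum(mask))
}

#' Bundled comparison report
#'
#' Percent-difference (<3%) and gamma passing rates at 2%/2mm and 3%/3mm,
#' the standard acceptance summary for film-vs-calculation scroll
#' comparisons.
#'
#' @param eval,ref dose maps on the same grid.
#' @param spacing pixel spacing in mm.
#' @param threshold low-dose exclusion, % of reference max.
#' @return a `comparison_report` list; serializable with
#'   [jsonlite::toJSON()].
#' @export
comparison_report <- function(eval, ref, spacing = 1, threshold = 20) {
  dd <- percent_dose_difference(eval, ref, threshold = threshold)
  g22 <- gamma_map(eval, ref, gamma_params(2, 2, threshold), spacing)
  g33 <- gamma_map(eval, ref, gamma_params(3, 3, threshold), spacing)
  rep <- list(
    diff_map = dd$diff_map,
    gamma_map = g22$gamma_map,
    dose_diff_passing = dd$passing_rate,
    gamma_passing_2_2 = g22$passing_rate,
    gamma_passing_3_3 = g33$passing_rate,
    n_evaluated = dd$n_evaluated
  )
  class(rep) <- "comparison_report"
  rep
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("<comparison_report> %d px evaluated | dose-diff <3%%: ",
                     "%.2f%% | gamma 2%%/2mm: %.2f%% | 3%%/3mm: %.2f%%\n"),
              x$n_evaluated, x$dose_diff_passing, x$gamma_passing_2_2,
              x$gamma_passing_3_3))
  invisible(x)
}
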