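#' Rigid 2-D registration by mutual information
#'
#' Finds the in-plane shift and rotation that maximize the mutual
#' information of the joint intensity histogram (64 x 64 bins) between a
#' moving and a fixed dose map. The optimizer is a deterministic
#' coarse-to-fine grid search: 0.5 px / 0.25 deg steps over the search
#' bounds, then a 5 x 5 x 5 refinement at 0.125 px / 0.0625 deg around the
#' optimum. No random restarts, so results are reproducible.
#'
#' @param moving,fixed dose maps (matrices, same pixel size).
#' @param pixel_size pixel size in mm (scalar or `c(row, col)`), used to
#'   express the shift bounds in px.
#' @param max_shift_mm search bound on |shift| per axis (default 3 mm).
#' @param max_rot_deg search bound on |rotation| (default 3 deg).
#' @param n_bins histogram bins per image (default 64).
#' @param wrap_cols treat the column axis as periodic (full-turn scroll
#'   images); forwarded to [apply_rigid()].
#' @return a `rigid_transform`: list with `shift_px` (row, col),
#'   `shift_mm`, `rotation_deg`, `mi`, `at_bound` (logical warning flag).
#'   Applying the transform to `moving` (see [apply_rigid()]) aligns it to
#'   `fixed`.
#' @export
register_rigid_mi <- function(moving, fixed, pixel_size = 1,
                              max_shift_mm = 3, max_rot_deg = 3,
                              n_bins = 64, wrap_cols = FALSE) {
  stopifnot(all(dim(moving) == dim(fixed)))
  pixel_size <- rep(pixel_size, length.out = 2)
  max_px <- max_shift_mm / pixel_size
  sr <- seq(-floor(max_px[1] / 0.5) * 0.5, floor(max_px[1] / 0.5) * 0.5, by = 0.5)
  sc <- seq(-floor(max_px[2] / 0.5) * 0.5, floor(max_px[2] / 0.5) * 0.5, by = 0.5)
  ro <- seq(-floor(max_rot_deg / 0.25) * 0.25, floor(max_rot_deg / 0.25) * 0.25,
            by = 0.25)
  rng <- range(c(moving, fixed))
  if (diff(rng) <= 0) rng <- rng + c(0, 1e-9)
  bin_fixed <- pmin(pmax(floor((fixed - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                    n_bins)
  # MI is compared over a fixed interior region so every candidate uses the
  # same sample count: sparse-histogram MI estimates are biased upward,
  # which would otherwise favour large transforms with small overlap
  nr <- nrow(fixed); nc <- ncol(fixed)
  arm <- sin(max(abs(ro)) * pi / 180) / 2
  marg_r <- ceiling(max(abs(sr)) + arm * nc) + 1
  marg_c <- if (wrap_cols) 0 else ceiling(max(abs(sc)) + arm * nr) + 1
  interior <- matrix(FALSE, nr, nc)
  interior[min(marg_r + 1, nr):max(nr - marg_r, 1),
           min(marg_c + 1, nc):max(nc - marg_c, 1)] <- TRUE
  eval_mi <- function(dr, dc, rot) {
    w <- apply_rigid(moving, c(dr, dc), rot, wrap_cols = wrap_cols)
    ok <- interior & !is.na(w)
    if (sum(ok) < 16) return(-Inf)
    bw <- pmin(pmax(floor((w[ok] - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
               n_bins)
    bf <- bin_fixed[ok]
    joint <- tabulate(bw + n_bins * (bf - 1L), nbins = n_bins * n_bins)
    p <- joint / sum(joint)
    px <- tabulate(bw, nbins = n_bins) / length(bw)
    py <- tabulate(bf, nbins = n_bins) / length(bf)
    hx <- -sum(px[px > 0] * log(px[px > 0]))
    hy <- -sum(py[py > 0] * log(py[py > 0]))
    hxy <- -sum(p[p > 0] * log(p[p > 0]))
    hx + hy - hxy
  }
  best <- list(mi = -Inf)
  # candidates visited in order of increasing transform magnitude so that
  # exact ties resolve to the smallest transform (identity first)
  scan_candidates <- function(cand) {
    cand <- cand[order(cand$dr^2 + cand$dc^2 + cand$rot^2), ]
    for (i in seq_len(nrow(cand))) {
      mi <- eval_mi(cand$dr[i], cand$dc[i], cand$rot[i])
      if (mi > best$mi)
        best <<- list(dr = cand$dr[i], dc = cand$dc[i], rot = cand$rot[i],
                      mi = mi)
    }
  }
  scan_candidates(expand.grid(dr = sr, dc = sc, rot = ro))
  # refinement
  for (step in c(0.25, 0.125)) {
    astep <- step / 2
    scan_candidates(expand.grid(dr = best$dr + step * (-2:2),
                                dc = best$dc + step * (-2:2),
                                rot = best$rot + astep * (-2:2)))
  }
  at_bound <- abs(best$dr) >= max(abs(sr)) - 1e-9 ||
    abs(best$dc) >= max(abs(sc)) - 1e-9 ||
    abs(best$rot) >= max(abs(ro)) - 1e-9
  if (at_bound)
    warning("registration optimum at search bound; larger misalignment possible")
  tr <- list(shift_px = c(best$dr, best$dc),
             shift_mm = c(best$dr, best$dc) * pixel_size,
             rotation_deg = best$rot, mi = best$mi, at_bound = at_bound)
  class(tr) <- "rigid_transform"
  tr
}

#' Apply a rigid 2-D transform to an image
#'
#' Rotates by `rot_deg` about the image centre, then shifts by `shift_px`
#' (rows, cols), resampling bilinearly. Pixels mapped from outside the
#' source are NA.
#'
#' @param img matrix.
#' @param shift_px shift in pixels `c(rows, cols)`.
#' @param rot_deg rotation in degrees (counter-clockwise in row/col space).
#' @param wrap_cols treat the column axis as periodic (TRUE for unrolled
#'   film-scroll images covering a full turn, where a column shift is a
#'   rotation of the cylinder).
#' @export
apply_rigid <- function(img, shift_px = c(0, 0), rot_deg = 0,
                        wrap_cols = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  gr <- matrix(rep(seq_len(nr), nc), nr, nc)
  gc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  th <- rot_deg * pi / 180
  # inverse mapping: output (r,c) pulls from input coordinates
  r0 <- gr - shift_px[1] - cr
  c0 <- gc - shift_px[2] - cc
  rs <- cos(th) * r0 + sin(th) * c0 + cr
  cs <- -sin(th) * r0 + cos(th) * c0 + cc
  if (wrap_cols) {
    cs <- ((cs - 1) %% nc) + 1
    img <- cbind(img, img[, 1])
  }
  matrix(bilinear_interp(img, as.vector(rs), as.vector(cs), fill = NA_real_),
         nr, nc)
}
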