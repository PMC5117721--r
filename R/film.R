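#' Radiochromic film model
#'
#' Sensitometric response of EBT-family film per colour channel is modelled
#' with the rational form `v(D) = a + b / (D - c)` mapping dose D (cGy) to
#' normalized pixel value v (0..1, 16 bits per channel). With `b > 0` and
#' `c < 0` the response is monotone decreasing and pole-free over the
#' calibrated range 0-400 cGy, and the inverse `D(v) = c + b / (v - a)` is
#' closed-form and well conditioned.
#'
#' `film_response()` evaluates the forward model; `fit_calibration()` fits
#' per-channel parameters to measured calibration points by nonlinear least
#' squares.
#'
#' @param dose_cgy dose values in cGy.
#' @param par named vector/list with `a`, `b`, `c`.
#' @export
film_response <- function(dose_cgy, par) {
  par$a + par$b / (dose_cgy - par$c)
}

# canonical channel parameters used by the synthetic scenario generator
# (representative of a 6 MV / EBT3-like response; red most sensitive)
default_film_params <- function() {
  list(R = list(a = 0.18, b = 45, c = -120),
       G = list(a = 0.14, b = 80, c = -180),
       B = list(a = 0.30, b = 60, c = -250))
}

#' Fit a per-channel calibration curve
#'
#' Fits `v(D) = a + b/(D - c)` independently per channel by Levenberg-
#' Marquardt least squares. Requires at least 13 distinct dose points
#' including 0 (the protocol uses 16 pieces spanning 0-400 cGy). Channels
#' whose values are not monotone in dose are rejected with a warning.
#'
#' @param doses calibration doses (cGy), including 0.
#' @param values matrix (points x 3, columns R/G/B) of normalized pixel
#'   values (0..1).
#' @return a `calibration_curve`: per-channel parameter list with fit RMS,
#'   valid-channel flags and the calibrated dose range.
#' @export
fit_calibration <- function(doses, values) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 3, length(doses) == nrow(values))
  if (length(unique(doses)) < 13)
    stop("calibration needs >= 13 distinct dose points")
  if (min(doses) > 0) stop("calibration must include the 0-dose point")
  ord <- order(doses)
  doses <- doses[ord]; values <- values[ord, , drop = FALSE]
  chan <- c("R", "G", "B")
  out <- list()
  for (k in 1:3) {
    v <- values[, k]
    # tolerate noise-level local inversions but reject channels without a
    # clear monotone trend
    if (abs(stats::cor(doses, v, method = "spearman")) < 0.9) {
      warning("channel ", chan[k], " not monotone in dose; rejected")
      out[[chan[k]]] <- list(valid = FALSE)
      next
    }
    # starting values: scan candidate c, solve (a, b) linearly
    best <- NULL
    for (c0 in -c(30, 60, 120, 180, 250, 400, 800)) {
      x <- 1 / (doses - c0)
      fit0 <- stats::lm(v ~ x)
      rss <- sum(stats::resid(fit0)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(a = coef(fit0)[1], b = coef(fit0)[2], c = c0, rss = rss)
    }
    df <- data.frame(D = doses, v = v)
    fit <- minpack.lm::nlsLM(v ~ a + b / (D - c), data = df,
                             start = list(a = best$a, b = best$b, c = best$c),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- as.list(coef(fit))
    out[[chan[k]]] <- list(a = p$a, b = p$b, c = p$c, valid = TRUE,
                           residual_rms = sqrt(mean(stats::resid(fit)^2)))
  }
  cal <- list(channels = out, dose_range = c(0, max(doses)),
              doses = doses)
  class(cal) <- "calibration_curve"
  cal
}

#' Convert a film scan to dose with the multichannel method
#'
#' Per pixel, solves for dose `D` and a common multiplicative thickness
#' disturbance `delta` minimizing
#' `sum_ch (v_ch - vhat_ch(D) * (1 + delta))^2`, where `vhat_ch` is the
#' fitted channel response. The scalar disturbance absorbs common-mode
#' perturbations (film thickness, scanner gain) that act equally on all
#' channels. For fixed D the optimal `1 + delta` is closed-form, so the
#' problem reduces to a 1-D minimization in D solved on a coarse dose grid
#' followed by a fine local grid. With `disturbance = FALSE` the method
#' reduces to single-channel (green) inversion.
#'
#' @param scan a `film_scan` (see [film_from_dose()]).
#' @param cal a `calibration_curve`.
#' @param disturbance solve for the common-mode disturbance (default TRUE).
#' @param dose_max upper end of the inversion search (cGy); defaults to the
#'   calibrated range plus 12.5%.
#' @return list with `dose` (matrix, cGy), `disturbance` (matrix),
#'   `invalid` (logical matrix: pixels outside the calibrated value range).
#' @export
multichannel_dose <- function(scan, cal, disturbance = TRUE,
                              dose_max = NULL) {
  if (is.null(dose_max)) dose_max <- cal$dose_range[2] * 1.125
  ch <- cal$channels
  valid_ch <- vapply(ch, function(p) isTRUE(p$valid), logical(1))
  if (!valid_ch["G"] && !disturbance)
    stop("green channel invalid; single-channel inversion unavailable")
  v <- scan$channels  # nz x ny x 3, normalized 0..1
  d <- dim(v)
  npix <- d[1] * d[2]
  V <- matrix(v, nrow = npix, ncol = 3)
  if (!disturbance) {
    p <- ch$G
    D <- p$c + p$b / (V[, 2] - p$a)
    D[V[, 2] <= p$a] <- NA
    invalid <- is.na(D) | D < -2 | D > dose_max
    D <- pmin(pmax(D, 0), dose_max)
    return(list(dose = matrix(D, d[1], d[2]),
                disturbance = matrix(0, d[1], d[2]),
                invalid = matrix(invalid, d[1], d[2])))
  }
  use <- which(valid_ch)
  Vu <- V[, use, drop = FALSE]
  response_mat <- function(Dg) {
    m <- vapply(use, function(k) {
      p <- ch[[k]]
      p$a + p$b / (Dg - p$c)
    }, numeric(length(Dg)))
    matrix(m, nrow = length(Dg))
  }
  reduced_obj <- function(Dg) {
    # g(D) per pixel: ||v||^2 - (v . vhat)^2 / ||vhat||^2, pixels x doses
    Vh <- response_mat(Dg)                    # nD x nch
    num <- Vu %*% t(Vh)                       # npix x nD
    den <- rowSums(Vh^2)                      # nD
    sweep(-num^2, 2, den, "/")                # + ||v||^2 (constant/pixel)
  }
  Dg <- seq(0, dose_max, by = 2)
  g <- reduced_obj(Dg)
  best <- max.col(-g, ties.method = "first")
  Dc <- Dg[best]
  # fine local grid +/- 2 cGy at 0.05 cGy
  offs <- seq(-2, 2, by = 0.05)
  gf <- matrix(Inf, npix, length(offs))
  Df <- pmin(pmax(outer(Dc, offs, "+"), 0), dose_max)
  # evaluate per offset column (distinct doses per pixel)
  for (j in seq_along(offs)) {
    Dj <- Df[, j]
    Vh <- response_mat(Dj)                    # npix x nch
    num <- rowSums(Vu * Vh)
    den <- rowSums(Vh^2)
    gf[, j] <- -num^2 / den
  }
  jb <- max.col(-gf, ties.method = "first")
  D <- Df[cbind(seq_len(npix), jb)]
  Vh <- response_mat(D)
  delta <- rowSums(Vu * Vh) / rowSums(Vh^2) - 1
  # flag pixels whose values sit outside the calibrated response range
  v0 <- response_mat(0); vmaxd <- response_mat(cal$dose_range[2])
  lo <- pmin(v0[1, ], vmaxd[1, ]); hi <- pmax(v0[1, ], vmaxd[1, ])
  slack <- 0.05 * (hi - lo)
  invalid <- rowSums(sweep(Vu, 2, hi + slack, ">") |
                     sweep(Vu, 2, lo - slack, "<")) > 0
  list(dose = matrix(D, d[1], d[2]),
       disturbance = matrix(delta, d[1], d[2]),
       invalid = matrix(invalid, d[1], d[2]))
}

#' Lateral scanner-response correction
#'
#' Divides each image column by its lateral correction factor (flatbed
#' scanners respond non-uniformly across the lateral axis; the longitudinal
#' direction is left untouched, its effect being negligible).
#'
#' @param scan a `film_scan`.
#' @param profile per-column correction factors (length = scan width).
#' @export
lateral_correction <- function(scan, profile) {
  d <- dim(scan$channels)
  if (length(profile) != d[2])
    stop("profile length ", length(profile), " != scan width ", d[2])
  if (any(profile <= 0)) stop("correction factors must be > 0")
  for (k in 1:3)
    scan$channels[, , k] <- sweep(scan$channels[, , k], 2, profile, "/")
  scan
}

#' Synthesize a film scan from a dose map (forward model)
#'
#' Applies the per-channel response, multiplies by the lateral scanner
#' profile, adds per-channel Gaussian scanner noise and quantizes to 16
#' bits per channel. This is the generator counterpart of
#' [multichannel_dose()].
#'
#' @param dose_map matrix of dose in cGy (z rows x lateral columns).
#' @param params per-channel response parameters (default
#'   representative EBT3-like values used across the synthetic module).
#' @param lateral_profile per-column sensitivity factors (default flat).
#' @param noise_sd Gaussian scanner noise, fraction of signal (default
#'   0.003).
#' @param seed RNG seed (required when noise_sd > 0).
#' @param quantize quantize to 16-bit integers (default TRUE).
#' @param resolution_dpi scan resolution metadata (default 75).
#' @return a `film_scan`: list with `channels` (nz x ny x 3, normalized
#'   0..1), `resolution_dpi`, `portrait`.
#' @export
film_from_dose <- function(dose_map, params = default_film_params(),
                           lateral_profile = NULL, noise_sd = 0.003,
                           seed = NULL, quantize = TRUE,
                           resolution_dpi = 75) {
  d <- dim(dose_map)
  if (is.null(lateral_profile)) lateral_profile <- rep(1, d[2])
  ch <- array(0, dim = c(d, 3))
  for (k in 1:3) {
    p <- params[[k]]
    m <- film_response(dose_map, p)
    m <- sweep(m, 2, lateral_profile, "*")
    ch[, , k] <- m
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required for noisy synthesis")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    ch <- ch * (1 + array(rnorm(length(ch), 0, noise_sd), dim = dim(ch)))
  }
  ch <- pmin(pmax(ch, 0), 1)
  if (quantize) ch <- round(ch * 65535) / 65535
  scan <- list(channels = ch, resolution_dpi = resolution_dpi,
               portrait = TRUE)
  class(scan) <- "film_scan"
  scan
}

#' Write / read a film scan as 48-bit RGB TIFF
#'
#' @param scan a `film_scan`.
#' @param file TIFF path.
#' @export
write_film_scan <- function(scan, file) {
  tiff::writeTIFF(scan$channels, file, bits.per.sample = 16)
  invisible(file)
}

#' @rdname write_film_scan
#' @export
read_film_scan <- function(file, resolution_dpi = 75) {
  img <- tiff::readTIFF(file)
  scan <- list(channels = img, resolution_dpi = resolution_dpi,
               portrait = TRUE)
  class(scan) <- "film_scan"
  scan
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$channels)
  cat("<film_scan> ", d[1], " x ", d[2], " px, 48-bit RGB, ",
      x$resolution_dpi, " dpi\n", sep = "")
  invisible(x)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve> 0-", x$dose_range[2], " cGy\n", sep = "")
  for (nm in names(x$channels)) {
    p <- x$channels[[nm]]
    if (isTRUE(p$valid))
      cat(sprintf("  %s: a=%.4f b=%.2f c=%.1f (rms %.2e)\n", nm,
                  p$a, p$b, p$c, p$residual_rms))
    else cat("  ", nm, ": rejected\n", sep = "")
  }
  invisible(x)
}
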