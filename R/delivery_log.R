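#' Delivery logs: parsing, validation and control-point discretization
#'
#' A delivery log is a time-stamped record of linac machine state during an
#' arc delivery: gantry angle, MLC leaf positions, cumulative monitor units
#' (MU) and beam state. The on-disk dialect is CSV with header columns
#' `time_s, gantry_deg, mu_cum, beam_on, leaf_a_01..leaf_a_NN,
#' leaf_b_01..leaf_b_NN`, leaf positions in mm at the isocenter plane
#' (bank A = lower edge, bank B = upper edge, A <= B per pair).
#'
#' @param path path to a CSV log file, or a connection/character vector of
#'   lines as accepted by [utils::read.csv()].
#' @return `parse_delivery_log()` returns a `delivery_log` object: a list
#'   with vectors `time`, `gantry`, `mu_cum`, `beam_on`, leaf matrices
#'   `leaves_a`, `leaves_b` (records x pairs), and scalars `total_mu`,
#'   `arc_span` (signed unwrapped degrees).
#' @examples
#' log <- with_seed_log_example()
#' arc <- discretize(log, "coarse")
#' sum(arc$mu) - log$total_mu   # MU conservation
#' @export
parse_delivery_log <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "gantry_deg", "mu_cum", "beam_on")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed log: missing column(s) ", paste(miss, collapse = ", "))
  la_cols <- grep("^leaf_a_", names(df), value = TRUE)
  lb_cols <- grep("^leaf_b_", names(df), value = TRUE)
  if (length(la_cols) == 0 || length(la_cols) != length(lb_cols))
    stop("malformed log: leaf_a_* / leaf_b_* columns absent or unpaired")
  la_cols <- la_cols[order(la_cols)]
  lb_cols <- lb_cols[order(lb_cols)]
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad) > 0)
    stop("malformed log row at line ", bad[1] + 1L, " (header = line 1)")
  time <- as.numeric(df$time_s)
  if (any(diff(time) <= 0))
    stop("integrity error: timestamps not strictly increasing at record ",
         which(diff(time) <= 0)[1] + 1L)
  mu_cum <- as.numeric(df$mu_cum)
  if (any(diff(mu_cum) < -1e-9))
    stop("integrity error: cumulative MU decreases at record ",
         which(diff(mu_cum) < -1e-9)[1] + 1L)
  gantry <- as.numeric(df$gantry_deg)
  if (any(gantry < 0 | gantry >= 360))
    stop("integrity error: gantry angle outside [0, 360) at record ",
         which(gantry < 0 | gantry >= 360)[1])
  la <- as.matrix(df[la_cols]); lb <- as.matrix(df[lb_cols])
  if (any(la > lb + 1e-9))
    stop("integrity error: crossed leaves (A > B) at record ",
         which(apply(la > lb + 1e-9, 1, any))[1])
  log <- list(
    time = time, gantry = gantry, mu_cum = mu_cum,
    beam_on = as.logical(df$beam_on),
    leaves_a = unname(la), leaves_b = unname(lb),
    n_pairs = length(la_cols),
    total_mu = mu_cum[length(mu_cum)],
    arc_span = sum(diff(unwrap_angles(gantry)))
  )
  class(log) <- "delivery_log"
  log
}

#' @rdname parse_delivery_log
#' @param log a `delivery_log`.
#' @param file output path.
#' @export
write_delivery_log <- function(log, file) {
  np <- log$n_pairs
  df <- data.frame(time_s = log$time, gantry_deg = log$gantry,
                   mu_cum = log$mu_cum, beam_on = log$beam_on)
  la <- as.data.frame(log$leaves_a)
  lb <- as.data.frame(log$leaves_b)
  names(la) <- sprintf("leaf_a_%02d", seq_len(np))
  names(lb) <- sprintf("leaf_b_%02d", seq_len(np))
  utils::write.csv(cbind(df, la, lb), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# Unwrap a sequence of angles in [0, 360) into a continuous signed track
# (IEC 61217 convention; arcs may cross 0/360).
unwrap_angles <- function(a) {
  d <- diff(a)
  d <- ((d + 180) %% 360) - 180
  cumsum(c(a[1], d))
}

#' Discretize a delivery log into a control-point sequence
#'
#' Coarse level keeps one control point (CP) per log record with positive MU
#' increment, carrying that record's gantry angle and leaf positions. Fine
#' level places non-equispaced CP boundaries at equal increments of
#' cumulative MU (inverse-transform sampling of the |dMU| density over the
#' arc), so CP density per arc sector is proportional to the local
#' MU-per-degree rate; a floor guarantees at least one fine CP per coarse
#' CP. Gantry angle and leaves at an off-record boundary are linearly
#' interpolated in time. Total MU is conserved exactly at both levels.
#'
#' @param log a `delivery_log`.
#' @param level `"coarse"` or `"fine"`.
#' @param target_multiplier fine level: requested CP count as a multiple of
#'   the coarse count (default 3).
#' @return a `discretized_arc`: list with `gantry`, `mu`, `mu_cum`,
#'   `leaves_a`, `leaves_b`, `time`, `level`, `total_mu`.
#' @export
discretize <- function(log, level = c("coarse", "fine"),
                       target_multiplier = 3) {
  level <- match.arg(level)
  if (log$total_mu <= 0) stop("empty arc: log delivers zero MU")
  dmu <- diff(c(0, log$mu_cum))
  keep <- which(dmu > 0)
  if (level == "coarse") {
    arc <- list(
      index = seq_along(keep),
      gantry = log$gantry[keep] %% 360,
      mu = dmu[keep],
      mu_cum = log$mu_cum[keep],
      leaves_a = log$leaves_a[keep, , drop = FALSE],
      leaves_b = log$leaves_b[keep, , drop = FALSE],
      time = log$time[keep],
      level = "coarse", total_mu = log$total_mu,
      n_pairs = log$n_pairs
    )
    class(arc) <- "discretized_arc"
    return(arc)
  }
  if (target_multiplier < 1) stop("target_multiplier must be >= 1")
  n_coarse <- length(keep)
  # Each coarse CP interval is subdivided into equal-MU sub-CPs, the
  # sub-CP count proportional to the interval's share of the total MU
  # (inverse-transform sampling of the |dMU| density over the arc, with a
  # floor of one sub-CP per coarse CP). Coarse boundaries are retained, so
  # the fine arc refines the coarse one. The recorded counter may update
  # in discrete steps (flat stretches between updates) while delivery is
  # continuous: the cumulative curve is linearized through the update
  # records before inverting, so fine CPs land between counter updates
  # with equal MU increments.
  ti <- log$time; mi <- log$mu_cum
  inc <- c(TRUE, diff(mi) > 0)
  mu_lin_inv <- function(mq) stats::approx(mi[inc], ti[inc], xout = mq,
                                           ties = "ordered", rule = 2)$y
  mu_lin <- function(tq) stats::approx(ti[inc], mi[inc], xout = tq,
                                       rule = 2)$y
  mu_target <- log$total_mu / (target_multiplier * n_coarse)
  dmu_keep <- dmu[keep]
  mu_hi <- log$mu_cum[keep]
  tau <- unlist(lapply(seq_len(n_coarse), function(j) {
    k <- max(1L, round(dmu_keep[j] / mu_target))
    levels <- mu_hi[j] - dmu_keep[j] + seq_len(k) * dmu_keep[j] / k
    tt <- mu_lin_inv(levels)
    tt[k] <- log$time[keep[j]]  # interval end lands on the record exactly
    tt
  }))
  tau <- sort(tau)
  tau <- tau[c(TRUE, diff(tau) > 1e-9)]
  mu_cum_tau <- mu_lin(tau)
  mu <- diff(c(0, mu_cum_tau))
  pos <- mu > 1e-12
  tau <- tau[pos]; mu_cum_tau <- mu_cum_tau[pos]
  mu <- diff(c(0, mu_cum_tau))
  gan_unwrap <- unwrap_angles(log$gantry)
  g_tau <- stats::approx(ti, gan_unwrap, xout = tau, rule = 2)$y
  interp_rows <- function(m) {
    apply(m, 2, function(col) stats::approx(ti, col, xout = tau, rule = 2)$y)
  }
  la <- interp_rows(log$leaves_a)
  lb <- interp_rows(log$leaves_b)
  if (is.null(dim(la))) { la <- matrix(la, nrow = 1); lb <- matrix(lb, nrow = 1) }
  arc <- list(
    index = seq_along(tau),
    gantry = g_tau %% 360,
    mu = mu,
    mu_cum = mu_cum_tau,
    leaves_a = la, leaves_b = lb,
    time = tau,
    level = "fine", total_mu = log$total_mu,
    n_pairs = log$n_pairs
  )
  class(arc) <- "discretized_arc"
  arc
}

#' Angular MU distribution of a discretized arc
#'
#' Sums control-point MU into angular bins over the arc span. Bin sums
#' conserve total MU exactly.
#'
#' @param arc a `discretized_arc`.
#' @param bin_width bin width in degrees (> 0).
#' @return data.frame with `angle_lo`, `angle_hi`, `mu`.
#' @export
angular_mu_distribution <- function(arc, bin_width = 10) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  a <- arc$gantry %% 360
  # bins are right-closed, (lo, hi]: a CP records the machine state at the
  # end of its interval, so MU delivered up to an angle belongs at or
  # below it
  lo <- floor((min(a) - 1e-9) / bin_width) * bin_width
  hi <- ceiling(max(a) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  idx <- findInterval(a, edges, left.open = TRUE)
  mu <- vapply(seq_len(length(edges) - 1),
               function(k) sum(arc$mu[idx == k]), numeric(1))
  data.frame(angle_lo = edges[-length(edges)], angle_hi = edges[-1], mu = mu)
}

#' @export
print.delivery_log <- function(x, ...) {
  cat("<delivery_log> ", length(x$time), " records, ",
      sprintf("%.2f", x$total_mu), " MU, arc span ",
      sprintf("%.1f", x$arc_span), " deg, ", x$n_pairs, " leaf pairs\n",
      sep = "")
  invisible(x)
}

#' @export
print.discretized_arc <- function(x, ...) {
  cat("<discretized_arc> ", length(x$mu), " CPs (", x$level, "), ",
      sprintf("%.2f", x$total_mu), " MU\n", sep = "")
  invisible(x)
}

# small deterministic example log used in documentation
with_seed_log_example <- function() {
  plan <- make_arc_plan(n_cp = 10, arc_span = 60, modulation = 0.2,
                        total_mu = 100, seed = 1)
  emulate_delivery(plan, seed = 1)$log
}
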