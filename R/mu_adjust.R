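#' Assemble the measurement vector for the MU adjustment
#'
#' Stacks film-scroll dose samples and the isocenter chamber dose into the
#' measurement vector `d` of the constrained least-squares adjustment,
#' keeping per-row provenance (source scroll and 3-D position). Scroll
#' pixels below the dose threshold are excluded; the remaining pixels may
#' be downsampled by an integer factor along both scroll axes. The chamber
#' row carries a configurable weight so a single point is not drowned out
#' by thousands of film pixels (default: number of scroll rows / 100).
#'
#' @param scrolls list of `scroll_image` objects (e.g. outer, inner),
#'   registered to the calculation frame.
#' @param chamber_gy isocenter chamber dose (Gy, > 0).
#' @param chamber_point chamber position (mm), default isocenter.
#' @param threshold exclusion threshold as a fraction of the maximum scroll
#'   dose (default 0.2).
#' @param downsample integer subsampling factor per scroll axis (default 1).
#' @param chamber_weight weight of the chamber row (default n_rows / 100).
#' @return a `measurement_vector`: list with `d` (Gy), `points` (n x 3 mm),
#'   `weights`, `source` (factor), `n_scroll_rows`.
#' @export
assemble_measurements <- function(scrolls, chamber_gy,
                                  chamber_point = c(0, 0, 0),
                                  threshold = 0.2, downsample = 1,
                                  chamber_weight = NULL) {
  if (chamber_gy <= 0) stop("chamber dose must be > 0")
  if (inherits(scrolls, "scroll_image")) scrolls <- list(scrolls)
  dmax <- max(vapply(scrolls, function(s) max(s$values, na.rm = TRUE),
                     numeric(1)))
  d <- numeric(0); pts <- NULL; src <- character(0)
  for (k in seq_along(scrolls)) {
    s <- scrolls[[k]]
    iz <- seq(1, length(s$z), by = downsample)
    ith <- seq(1, length(s$thetas), by = downsample)
    vals <- s$values[iz, ith, drop = FALSE]
    p <- scroll_points(s$radius, s$thetas[ith], s$z[iz])
    v <- as.vector(t(vals))  # theta fastest, matching scroll_points order
    keep <- !is.na(v) & v >= threshold * dmax
    d <- c(d, v[keep])
    pts <- rbind(pts, p[keep, , drop = FALSE])
    lab <- if (!is.null(names(scrolls)) && nzchar(names(scrolls)[k]))
      names(scrolls)[k] else paste0("scroll", k)
    src <- c(src, rep(lab, sum(keep)))
  }
  n_scroll <- length(d)
  if (n_scroll == 0) stop("no scroll samples above threshold")
  if (is.null(chamber_weight)) chamber_weight <- n_scroll / 100
  d <- c(d, chamber_gy)
  pts <- rbind(pts, chamber_point)
  src <- c(src, "chamber")
  mv <- list(d = d, points = unname(pts),
             weights = c(rep(1, n_scroll), chamber_weight),
             source = factor(src), n_scroll_rows = n_scroll)
  class(mv) <- "measurement_vector"
  mv
}

#' Constraint set for the MU adjustment
#'
#' Encodes the constraints of the adjustment problem: per-row dose
#' tolerance `|C x - d| <= tol` (both signs), the total-MU equality
#' `sum(mu_log * x) = total MU`, and per-CP bounds on the multiplicative
#' weight `x` (1 = log-file value). The tolerance per row is
#' `max(tol_pct% of the local measured dose, tol_floor_gy)`.
#'
#' @param arc a `discretized_arc` (supplies `mu_log` and total MU).
#' @param lower,upper per-CP bounds as fractions of the log MU (defaults
#'   0.90 / 1.10); scalars are recycled.
#' @param tol_pct dose tolerance, % of local dose (default 3).
#' @param tol_floor_gy absolute tolerance floor in Gy (default 0.02).
#' @param use_tolerance include the inequality rows (default TRUE).
#' @param max_relax maximum number of 1.5x tolerance relaxations attempted
#'   on infeasibility (default 8).
#' @export
constraint_set <- function(arc, lower = 0.90, upper = 1.10, tol_pct = 3,
                           tol_floor_gy = 0.02, use_tolerance = TRUE,
                           max_relax = 8) {
  n <- length(arc$mu)
  lb <- rep(lower, length.out = n); ub <- rep(upper, length.out = n)
  if (any(lb > 1 + 1e-12) || any(ub < 1 - 1e-12))
    stop("bounds must satisfy lb <= 1 <= ub per CP")
  cs <- list(lb = lb, ub = ub, mu_log = arc$mu, total_mu = arc$total_mu,
             tol_pct = tol_pct, tol_floor_gy = tol_floor_gy,
             use_tolerance = use_tolerance, max_relax = max_relax)
  class(cs) <- "constraint_set"
  cs
}

#' Solve the experimentally constrained MU adjustment
#'
#' Minimizes `0.5 * ||W^(1/2) (C x - d)||^2` over per-CP MU weights `x`
#' subject to the total-MU equality, per-CP bounds, and (optionally) the
#' per-row dose-tolerance inequalities, via a dual active-set quadratic
#' program. `x = 1` reproduces the log file; the solution is deterministic
#' and its objective never exceeds the log-file starting point when that
#' point is feasible. If the tolerance inequalities make the problem
#' infeasible, the tolerance is relaxed by factors of 1.5 (up to
#' `max_relax` times), each relaxation raised as a warning; a structured
#' infeasibility report is returned if relaxation is exhausted.
#'
#' @param C a `contribution_matrix` (rows must match `d`).
#' @param d a `measurement_vector` (or bare numeric vector).
#' @param cons a `constraint_set`.
#' @param ridge Tikhonov stabilizer added to the normal matrix, as a
#'   fraction of its mean diagonal (default 1e-8); reported as a degeneracy
#'   warning when the normal matrix is numerically rank deficient.
#' @return a `mu_solution`: list with `x`, `mu_adjusted`, `objective`,
#'   `objective_log` (at x = 1), `change_pct`, `feasible`, `relaxations`,
#'   `tol` (final per-row tolerance), `binding_rows`.
#' @export
solve_mu_adjustment <- function(C, d, cons, ridge = 1e-8) {
  entries <- if (inherits(C, "contribution_matrix")) C$entries else C
  mv <- if (inherits(d, "measurement_vector")) d else
    list(d = d, weights = rep(1, length(d)))
  if (nrow(entries) != length(mv$d))
    stop("dimension mismatch: C has ", nrow(entries), " rows, d has ",
         length(mv$d))
  n <- ncol(entries)
  stopifnot(length(cons$mu_log) == n)
  mu <- cons$mu_log
  # solve in delivered-MU contribution terms: columns scaled by mu so the
  # model is entries %*% diag(mu) %*% x
  Cm <- entries * rep(mu, each = nrow(entries))
  w <- sqrt(mv$weights)
  Cw <- Cm * w
  dw <- mv$d * w
  H <- crossprod(Cw)
  diag_mean <- mean(diag(H))
  if (diag_mean <= 0) stop("contribution matrix is all zero")
  rk <- qr(H)$rank
  if (rk < n)
    warning("contribution matrix rank deficient (", rk, " < ", n,
            "); solution regularized")
  # stabilizer biased toward the log-file solution x = 1: among
  # near-optimal solutions of an ill-conditioned fit, prefer the smallest
  # MU change
  lam <- ridge * diag_mean
  Hr <- H + diag(lam, n)
  f <- crossprod(Cw, dw) + lam
  tol_row <- pmax(cons$tol_pct / 100 * abs(mv$d), cons$tol_floor_gy)
  relax <- 0
  if (all(cons$ub - cons$lb < 1e-12)) {
    # degenerate feasible set: the bounds pin the solution
    x <- cons$lb
    resid <- Cw %*% x - dw
    resid1 <- Cw %*% rep(1, n) - dw
    out <- list(x = x, mu_log = mu, mu_adjusted = x * mu,
                objective = 0.5 * sum(resid^2),
                objective_log = 0.5 * sum(resid1^2),
                change_pct = 100 * (x - 1), feasible = TRUE,
                relaxations = 0, tol = tol_row, binding_rows = integer(0),
                gantry = if (inherits(C, "contribution_matrix")) C$gantry else NULL)
    class(out) <- "mu_solution"
    return(out)
  }
  repeat {
    # quadprog convention: min 0.5 x'Hx - f'x s.t. A'x >= b, first meq equality
    Amat <- cbind(mu,
                  diag(n), -diag(n))
    bvec <- c(cons$total_mu, cons$lb, -cons$ub)
    if (isTRUE(cons$use_tolerance)) {
      Amat <- cbind(Amat, t(Cm), -t(Cm))
      bvec <- c(bvec, mv$d - tol_row, -(mv$d + tol_row))
    }
    sol <- try(quadprog::solve.QP(Hr, f, Amat, bvec, meq = 1), silent = TRUE)
    if (!inherits(sol, "try-error")) break
    if (!isTRUE(cons$use_tolerance) || relax >= cons$max_relax) {
      # structured infeasibility report: which rows cannot be met at x = 1
      res0 <- Cm %*% rep(1, n) - mv$d
      viol <- which(abs(res0) > tol_row)
      stop("infeasible constraint set after ", relax,
           " tolerance relaxations; ", length(viol),
           " measurement rows violate the tolerance at x = 1")
    }
    relax <- relax + 1
    tol_row <- tol_row * 1.5
    warning("tolerance constraints infeasible; relaxing by 1.5x (step ",
            relax, ")")
  }
  x <- sol$solution
  # clip numerical bound violations
  x <- pmin(pmax(x, cons$lb), cons$ub)
  resid <- Cw %*% x - dw
  obj <- 0.5 * sum(resid^2)
  resid1 <- Cw %*% rep(1, n) - dw
  obj1 <- 0.5 * sum(resid1^2)
  res_un <- as.vector(Cm %*% x - mv$d)
  binding <- which(abs(abs(res_un) - tol_row) < 1e-6 * pmax(tol_row, 1e-12))
  out <- list(x = x, mu_log = mu, mu_adjusted = x * mu,
              objective = obj, objective_log = obj1,
              change_pct = 100 * (x - 1),
              feasible = TRUE, relaxations = relax, tol = tol_row,
              binding_rows = binding, gantry = if (inherits(C, "contribution_matrix")) C$gantry else NULL)
  class(out) <- "mu_solution"
  out
}

#' Per-CP and angular MU change report
#'
#' Differences between adjusted and log MU per control point and summed
#' into angular bins. The binned differences sum to zero by the total-MU
#' equality constraint (reported as a check).
#'
#' @param sol a `mu_solution`.
#' @param arc the matching `discretized_arc`.
#' @param bin_width angular bin width in degrees (default 10).
#' @return list with `per_cp` (data.frame: gantry, mu_log, mu_adjusted,
#'   change_pct), `binned` (data.frame: angle_lo, angle_hi, dmu),
#'   `total_difference`.
#' @export
mu_change_report <- function(sol, arc, bin_width = 10) {
  stopifnot(length(sol$x) == length(arc$mu))
  per_cp <- data.frame(gantry = arc$gantry, mu_log = arc$mu,
                       mu_adjusted = sol$mu_adjusted,
                       change_pct = sol$change_pct)
  adj <- arc; adj$mu <- sol$mu_adjusted - arc$mu
  binned <- angular_mu_distribution(adj, bin_width)
  names(binned)[names(binned) == "mu"] <- "dmu"
  list(per_cp = per_cp, binned = binned,
       total_difference = sum(sol$mu_adjusted) - sum(arc$mu))
}

#' @export
print.mu_solution <- function(x, ...) {
  cat(sprintf(paste0("<mu_solution> %d CPs | objective %.4g (log: %.4g) | ",
                     "max |change| %.2f%% | relaxations %d\n"),
              length(x$x), x$objective, x$objective_log,
              max(abs(x$change_pct)), x$relaxations))
  invisible(x)
}
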