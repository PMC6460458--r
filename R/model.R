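#' Kinetic rate parameters for skin-to-lymph-node trafficking
#'
#' Bundles the rates of the trafficking model.  Photoconverted cells leave
#' the skin with a per-cell hazard \eqn{\mu(t)}: constant \eqn{\mu_0} under
#' saline, and \eqn{\mu_0 + \alpha t e^{-mt}} under alum/LPS (an
#' inflammation-driven pulse of extra migration peaking at \eqn{t = 1/m}).
#' Cells take a fixed transit time \eqn{\tau} through the lymphatics and are
#' then lost from the draining lymph node at a condition-specific first-order
#' rate \eqn{\delta} (death and egress are not distinguished).
#'
#' @param mu0 basal migration rate, per hour (> 0).
#' @param alpha inflammatory migration amplitude, per hour^2 (>= 0;
#'   `alpha = 0` reduces the alum law to the saline law).
#' @param m inflammatory decay constant, per hour (>= 0; must be > 0 when
#'   `alpha > 0`).
#' @param tau transit delay between skin egress and lymph-node arrival,
#'   hours (>= 0).
#' @param delta_alum,delta_saline lymph-node loss rates per hour (> 0).
#' @return An object of class `rate_parameters`.
#' @seealso [canonical_parameters()] for the set assembled from published
#'   point estimates.
#' @examples
#' p <- rate_parameters(mu0 = 0.01, alpha = 0.005, m = 1/24, tau = 2,
#'                      delta_alum = 0.07, delta_saline = 0.18)
#' migration_rate(24, p, "alum")
#' @export
rate_parameters <- function(mu0, alpha = 0, m = 0, tau, delta_alum,
                            delta_saline) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(m), length(m) == 1L, is.finite(m),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(delta_alum), length(delta_alum) == 1L,
            is.numeric(delta_saline), length(delta_saline) == 1L)
  if (mu0 <= 0) stop("mu0 must be > 0")
  if (alpha < 0) stop("alpha must be >= 0")
  if (m < 0) stop("m must be >= 0")
  if (alpha > 0 && m <= 0) stop("m must be > 0 when alpha > 0")
  if (tau < 0) stop("tau must be >= 0")
  if (delta_alum <= 0 || delta_saline <= 0) stop("loss rates must be > 0")
  structure(list(mu0 = mu0, alpha = alpha, m = m, tau = tau,
                 delta_alum = delta_alum, delta_saline = delta_saline),
            class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Trafficking rate parameters\n")
  cat(sprintf("  basal migration   mu0   = %.5g /h  (skin residence %.3g d)\n",
              x$mu0, 1 / x$mu0 / 24))
  if (x$alpha > 0) {
    cat(sprintf("  migration pulse   alpha = %.5g /h^2, m = %.5g /h (peak at %.3g h)\n",
                x$alpha, x$m, 1 / x$m))
  } else {
    cat("  migration pulse   none (alpha = 0)\n")
  }
  cat(sprintf("  transit delay     tau   = %.4g h\n", x$tau))
  cat(sprintf("  dLN loss          delta_alum = %.5g /h (t1/2 %.3g h), delta_saline = %.5g /h (t1/2 %.3g h)\n",
              x$delta_alum, log(2) / x$delta_alum,
              x$delta_saline, log(2) / x$delta_saline))
  invisible(x)
}

match_condition <- function(condition) {
  match.arg(condition, c("saline", "alum"))
}

delta_for <- function(params, condition) {
  if (condition == "alum") params$delta_alum else params$delta_saline
}

#' Instantaneous migration rate from skin
#'
#' The per-cell hazard of leaving the skin for the draining lymph node:
#' `mu0` under saline, `mu0 + alpha * t * exp(-m * t)` under alum/LPS.
#'
#' @param t hours post-injection (>= 0); vectorised.
#' @param params a [rate_parameters()] object.
#' @param condition `"saline"` or `"alum"`.
#' @return Migration rate(s), per hour.
#' @export
migration_rate <- function(t, params, condition) {
  condition <- match_condition(condition)
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("t must be >= 0")
  if (condition == "saline" || params$alpha == 0) {
    rep_len(params$mu0, length(t))
  } else {
    params$mu0 + params$alpha * t * exp(-params$m * t)
  }
}

#' Cumulative migration hazard over an interval
#'
#' Exact integral of [migration_rate()] over `[t1, t2]`; the exponent of the
#' skin survival curve.
#'
#' @param t1,t2 interval endpoints in hours post-injection, `0 <= t1 <= t2`;
#'   vectorised.
#' @inheritParams migration_rate
#' @return Dimensionless cumulative hazard(s), >= 0.
#' @export
cumulative_migration <- function(t1, t2, params, condition) {
  condition <- match_condition(condition)
  stopifnot(is.numeric(t1), is.numeric(t2))
  if (any(t1 < 0)) stop("t1 must be >= 0")
  if (any(t2 < t1)) stop("t2 must be >= t1")
  v <- params$mu0 * (t2 - t1)
  if (condition == "alum" && params$alpha > 0) {
    m <- params$m
    v <- v + params$alpha / m^2 *
      ((1 + m * t1) * exp(-m * t1) - (1 + m * t2) * exp(-m * t2))
  }
  v
}

#' Expected photoconverted cell count in skin
#'
#' Labelled skin pool at time `t`: all loss from the skin is emigration (no
#' local death or proliferation), so the pool decays as
#' `x0 * exp(-cumulative_migration(t_pc, t))`.
#'
#' @param t hours post-injection, `t >= t_pc`; vectorised.
#' @param x0 photoconverted skin count at the photoconversion time (>= 0).
#' @param t_pc photoconversion time, hours post-injection (>= 0).
#' @inheritParams migration_rate
#' @return Expected count(s), cells.
#' @export
skin_timecourse <- function(t, x0, t_pc, params, condition) {
  stopifnot(is.numeric(x0), length(x0) == 1L, x0 >= 0,
            is.numeric(t_pc), length(t_pc) == 1L, t_pc >= 0)
  if (any(t < t_pc)) stop("t must be >= t_pc")
  x0 * exp(-cumulative_migration(t_pc, t, params, condition))
}

#' Expected photoconverted cell count in the draining lymph node
#'
#' Solves the delayed influx-loss balance
#' \deqn{Y(t) = \int_{t_{pc}}^{t-\tau} \mu(s)\,X(s)\,e^{-\delta(t-s-\tau)}\,ds}
#' by deterministic quadrature (composite parabolic rule at fixed step `dt`).
#' `Y` is identically zero until the first cells complete transit at
#' `t_pc + tau`.
#'
#' @inheritParams skin_timecourse
#' @param dt quadrature step, hours.  The integrand is smooth and
#'   exponentially damped; the default resolves it far below measurement
#'   precision.
#' @return Expected count(s), cells.
#' @seealso [dln_constant_mu()] for the analytic constant-rate special case.
#' @export
dln_timecourse <- function(t, x0, t_pc, params, condition, dt = 0.01) {
  condition <- match_condition(condition)
  stopifnot(is.numeric(x0), length(x0) == 1L, x0 >= 0,
            is.numeric(t_pc), length(t_pc) == 1L, t_pc >= 0)
  if (any(t < t_pc)) stop("t must be >= t_pc")
  pulse <- condition == "alum" && params$alpha > 0
  cpp_dln_curve(as.numeric(t), t_pc, x0, params$mu0, params$alpha, params$m,
                pulse, params$tau, delta_for(params, condition), dt)
}

#' Closed-form lymph-node count for a constant migration rate
#'
#' Analytic solution of the delayed influx-loss balance when the migration
#' rate is a constant `mu`: with `u = max(0, t - t_pc - tau)`,
#' `x0 * mu * (exp(-mu u) - exp(-delta u)) / (delta - mu)`, switching to the
#' limit `x0 * mu * u * exp(-mu u)` when `|mu - delta|` falls below
#' `degenerate_tol` (avoids catastrophic cancellation).
#'
#' @inheritParams skin_timecourse
#' @param mu constant migration rate, per hour (> 0).
#' @param delta lymph-node loss rate, per hour (> 0).
#' @param tau transit delay, hours.
#' @param degenerate_tol threshold on `|mu - delta|` (per hour) below which
#'   the limiting expression is used.
#' @return Expected count(s), cells.
#' @export
dln_constant_mu <- function(t, x0, t_pc, mu, delta, tau,
                            degenerate_tol = 1e-8) {
  stopifnot(mu > 0, delta > 0, x0 >= 0, t_pc >= 0, tau >= 0)
  if (any(t < t_pc)) stop("t must be >= t_pc")
  u <- pmax(0, t - t_pc - tau)
  if (abs(mu - delta) < degenerate_tol) {
    x0 * mu * u * exp(-mu * u)
  } else {
    x0 * mu * (exp(-mu * u) - exp(-delta * u)) / (delta - mu)
  }
}

#' Expected counts for a photoconversion design
#'
#' Evaluates the deterministic model for every (site, harvest time) cell of
#' one experimental design: skin rows via [skin_timecourse()], lymph-node
#' rows via [dln_timecourse()].
#'
#' @param design a [pc_design()] object.
#' @param params a [rate_parameters()] object.
#' @param x0 photoconverted skin pool at the design's photoconversion time.
#' @param dt quadrature step passed to [dln_timecourse()].
#' @return A data frame with columns `site`, `t_harvest`, `expected`, one row
#'   per (site, harvest time), sites in design order.
#' @export
predict_observations <- function(design, params, x0, dt = 0.01) {
  stopifnot(inherits(design, "pc_design"))
  if (any(design$harvest_times < design$t_pc))
    stop("harvest before photoconversion")
  out <- do.call(rbind, lapply(design$sites, function(s) {
    expected <- if (s == "skin") {
      skin_timecourse(design$harvest_times, x0, design$t_pc, params,
                      design$condition)
    } else {
      dln_timecourse(design$harvest_times, x0, design$t_pc, params,
                     design$condition, dt = dt)
    }
    data.frame(site = s, t_harvest = design$harvest_times,
               expected = expected)
  }))
  rownames(out) <- NULL
  out
}
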