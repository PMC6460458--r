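# Independent quadrature oracles used to check the compiled solver.

# fine-grid Riemann-sum (trapezoid-weighted) evaluation of the dLN
# convolution integral, independent of the package's solver
riemann_dln <- function(t, x0, t_pc, params, condition, delta, tau,
                        dt = 0.001) {
  u <- t - tau
  if (u <= t_pc) return(0)
  s <- seq(t_pc, u, by = dt)
  if (s[length(s)] < u) s <- c(s, u)
  mu <- migration_rate(s, params, condition)
  X <- skin_timecourse(s, x0, t_pc, params, condition)
  f <- mu * X * exp(-delta * (t - s - tau))
  w <- c(diff(s), 0) / 2 + c(0, diff(s)) / 2
  sum(f * w)
}

# trapezoid quadrature of the migration rate (oracle for the closed-form
# cumulative hazard)
trapz_migration <- function(t1, t2, params, condition, dt = 0.001) {
  s <- seq(t1, t2, by = dt)
  if (s[length(s)] < t2) s <- c(s, t2)
  f <- migration_rate(s, params, condition)
  w <- c(diff(s), 0) / 2 + c(0, diff(s)) / 2
  sum(f * w)
}

canonical_derived <- function(fit) {
  e <- fit$estimates
  c(hl_alum = log(2) / e$delta_alum,
    hl_saline = log(2) / e$delta_saline,
    peak_time = if (e$m > 0) 1 / e$m else NA_real_,
    peak_fold = if (e$m > 0) 1 + e$alpha * exp(-1) / (e$m * e$mu0) else 1,
    skin_residence_d = 1 / e$mu0 / 24,
    tau = e$tau)
}
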