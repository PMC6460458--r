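#' Canonical rate parameters
#'
#' A complete parameter set assembled from published point estimates of the
#' trafficking kinetics: mean skin residence 5.5 d (`mu0 = 1/132` per hour),
#' transit delay 2.6 h, lymph-node half-lives 9.5 h (alum) and 3.8 h
#' (saline), inflammatory migration pulse peaking at 26 h (`m = 1/26`) with
#' `alpha = 9 * mu0 * m * e` so the alum rate tops out at exactly 10-fold
#' the basal rate.
#'
#' @return A [rate_parameters()] object.
#' @export
canonical_parameters <- function() {
  mu0 <- 1 / (5.5 * 24)
  m <- 1 / 26
  rate_parameters(mu0 = mu0,
                  alpha = 9 * mu0 * m * exp(1),
                  m = m,
                  tau = 2.6,
                  delta_alum = log(2) / 9.5,
                  delta_saline = log(2) / 3.8)
}

#' Skin-pool recruitment curve
#'
#' Size of the photoconvertible skin pool as a function of when the light
#' pulse is applied.  Under saline the pool stays at the resident baseline
#' `r0`; under alum/LPS inflammatory recruitment transiently inflates it as
#' `r0 + beta * t * exp(-b * t)` (rise-then-fall within the first two days).
#' The default is calibrated so the inflamed pool peaks at three times the
#' baseline, 18 hours after injection.
#'
#' @param r0 baseline resident pool, cells (>= 0).
#' @param beta recruitment amplitude, cells per hour (>= 0).
#' @param b recruitment decay constant, per hour (> 0 when `beta > 0`).
#' @return An object of class `recruitment_curve`.
#' @export
recruitment_curve <- function(r0 = 500, beta = 2 * 500 * exp(1) / 18,
                              b = 1 / 18) {
  stopifnot(r0 >= 0, beta >= 0, b >= 0)
  if (beta > 0 && b <= 0) stop("b must be > 0 when beta > 0")
  structure(list(r0 = r0, beta = beta, b = b), class = "recruitment_curve")
}

#' Photoconvertible pool size at the switch time
#'
#' @param t_pc photoconversion time, hours post-injection (>= 0); vectorised.
#' @param curve a [recruitment_curve()].
#' @param condition `"saline"` or `"alum"`.
#' @return Pool size(s), cells.
#' @export
recruitment_pool <- function(t_pc, curve = recruitment_curve(), condition) {
  condition <- match_condition(condition)
  stopifnot(all(t_pc >= 0))
  if (condition == "saline") {
    rep_len(curve$r0, length(t_pc))
  } else {
    curve$r0 + curve$beta * t_pc * exp(-curve$b * t_pc)
  }
}

#' Observation-noise model
#'
#' Multiplicative lognormal noise with mean exactly 1
#' (`sigma^2 = log(1 + cv^2)` with the mean-correcting shift), so averaged
#' counts converge to the model expectation.  `cv = 0` reproduces the
#' expected values.  An optional Poisson layer converts the noisy mean to an
#' integer count; it is off by default since the fitted quantities are means.
#'
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param floor minimum reportable count, cells (>= 0).
#' @param poisson draw a Poisson count around the noisy mean.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.2, floor = 0, poisson = FALSE) {
  stopifnot(cv >= 0, floor >= 0, is.logical(poisson))
  structure(list(cv = cv, floor = floor, poisson = poisson),
            class = "noise_model")
}

#' Simulate a photoconversion experiment
#'
#' Generates a tidy dataset of photoconverted-cell counts for a list of
#' designs: the initial labelled pool of each design comes from the
#' recruitment curve at its switch time, expected counts from the
#' deterministic model, and per-mouse counts from the multiplicative noise
#' model.  The generating truth (parameters, curve, per-design pools, noise,
#' seed) is attached as the `truth` attribute and round-trips unchanged.
#'
#' @param designs a list of [pc_design()] objects (or a single design).
#' @param params a [rate_parameters()] object.
#' @param curve a [recruitment_curve()].
#' @param noise a [noise_model()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @param dt quadrature step for the expected-value solver.
#' @return A data frame of class `kaede_dataset` with columns `design_id`,
#'   `condition`, `t_pc`, `site`, `t_harvest`, `replicate`, `count`.
#' @examples
#' d <- simulate_dataset(study_designs(), canonical_parameters(), seed = 1)
#' head(d)
#' @export
simulate_dataset <- function(designs, params = canonical_parameters(),
                             curve = recruitment_curve(),
                             noise = noise_model(), seed = 1, dt = 0.01) {
  if (inherits(designs, "pc_design")) designs <- list(designs)
  stopifnot(length(designs) >= 1,
            all(vapply(designs, inherits, TRUE, "pc_design")))
  ids <- vapply(designs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("design ids must be unique")
  sigma <- sqrt(log(1 + noise$cv^2))
  rows <- withr::with_seed(seed, {
    lapply(designs, function(d) {
      x0 <- recruitment_pool(d$t_pc, curve, d$condition)
      exp_df <- predict_observations(d, params, x0, dt = dt)
      n <- nrow(exp_df)
      reps <- lapply(seq_len(d$n_replicates), function(r) {
        mult <- if (sigma > 0) exp(rnorm(n, -sigma^2 / 2, sigma)) else rep(1, n)
        count <- exp_df$expected * mult
        if (noise$poisson) count <- rpois(n, count)
        data.frame(design_id = d$id, condition = d$condition, t_pc = d$t_pc,
                   site = exp_df$site, t_harvest = exp_df$t_harvest,
                   replicate = r, count = pmax(count, noise$floor))
      })
      do.call(rbind, reps)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  x0 <- setNames(
    vapply(designs, function(d) recruitment_pool(d$t_pc, curve, d$condition),
           0.0),
    ids)
  attr(out, "truth") <- list(params = params, curve = curve, noise = noise,
                             x0 = x0, seed = seed)
  attr(out, "designs") <- designs
  class(out) <- c("kaede_dataset", "data.frame")
  out
}
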