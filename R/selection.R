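#' Least-squares Akaike information criterion
#'
#' `n_obs * log(rss / n_obs) + 2 * (k + 1)`, counting the residual variance
#' as a parameter alongside the `k` fitted ones.  A perfect fit
#' (`rss = 0`) is degenerate for this form; it returns `-Inf` with a
#' warning.
#'
#' @param rss residual sum of squares on the fitting scale (>= 0).
#' @param n_obs number of observations (> `k + 1`).
#' @param k number of fitted parameters.
#' @return Scalar AIC.
#' @export
ls_aic <- function(rss, n_obs, k) {
  stopifnot(rss >= 0, n_obs > k + 1, k >= 0)
  if (rss == 0) {
    warning("rss = 0: perfect fit, AIC degenerate (-Inf)")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + 2 * (k + 1)
}

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = aic_i - min(aic)`.
#'
#' @param aic vector of AIC values.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Default candidate model family
#'
#' Four nested models spanning the assumptions under comparison: constant
#' versus pulsed alum migration, and shared versus per-condition lymph-node
#' loss.  Saline migration is constant throughout.
#'
#' @return Named list of [model_spec()] objects `M0`-`M3` in increasing
#'   complexity (`M3` = pulsed alum migration with per-condition loss).
#' @export
default_model_family <- function() {
  list(M0 = model_spec("constant", "constant", delta_shared = TRUE,
                       label = "M0: constant migration, shared delta"),
       M1 = model_spec("constant", "constant", delta_shared = FALSE,
                       label = "M1: constant migration, per-condition delta"),
       M2 = model_spec("pulse", "constant", delta_shared = TRUE,
                       label = "M2: pulsed alum migration, shared delta"),
       M3 = model_spec("pulse", "constant", delta_shared = FALSE,
                       label = "M3: pulsed alum migration, per-condition delta"))
}

# map a fitted rate vector into the start layout of another spec,
# so larger nested models are warm-started from smaller ones
translate_start <- function(fit, to_spec) {
  p <- fit$estimates
  mu0 <- p$mu0
  v <- log(mu0)
  small <- function(m0) c(log(0.5 * mu0 * m0 * exp(1)), log(m0))
  if (to_spec$saline_rate_form == "pulse") {
    v <- if (fit$spec$saline_rate_form == "pulse" &&
             length(fit$extra) == 2) {
      c(v, log(fit$extra$alpha_saline), log(fit$extra$m_saline))
    } else c(v, small(1 / 24))
  }
  if (to_spec$alum_rate_form == "pulse") {
    v <- if (fit$spec$alum_rate_form == "pulse" && p$alpha > 0) {
      c(v, log(p$alpha), log(p$m))
    } else c(v, small(1 / 24))
  }
  v <- c(v, log(max(p$tau, 1e-6)))
  v <- if (to_spec$delta_shared) {
    c(v, log(sqrt(p$delta_alum * p$delta_saline)))
  } else {
    c(v, log(p$delta_alum), log(p$delta_saline))
  }
  if (to_spec$x0_policy == "recruitment") v <- c(v, log(500), log(75), log(1/18))
  v
}

#' Compare candidate models by AIC
#'
#' Fits every member of the family to the identical dataset via
#' [fit_model()] (larger models are additionally warm-started from the
#' solutions of already-fitted smaller ones, so nested fits cannot lose to
#' their sub-models by optimisation failure) and tabulates RSS, AIC, AIC
#' differences and Akaike weights.  The winner is the minimum-AIC model,
#' except that when a simpler model sits within `parsimony_delta` AIC units
#' of the minimum the simpler one is reported as winner and the tie is
#' flagged.
#'
#' @inheritParams fit_model
#' @param family named list of [model_spec()] objects.
#' @param parsimony_delta AIC margin for the parsimony tie-break.
#' @return An object of class `selection_table`: a data frame sorted by AIC
#'   with columns `model`, `k`, `rss`, `aic`, `delta_aic`, `weight`, plus
#'   attributes `winner`, `tie` and the underlying `fits`.
#' @examples
#' ds <- simulate_dataset(dense_designs(), seed = 1)
#' compare_models(ds, settings = optimizer_settings(n_starts = 2))
#' @export
compare_models <- function(dataset, family = default_model_family(),
                           settings = optimizer_settings(),
                           parsimony_delta = 2) {
  stopifnot(length(family) >= 1)
  if (is.null(names(family)))
    names(family) <- paste0("M", seq_along(family) - 1)
  fits <- list()
  for (nm in names(family)) {
    warm <- lapply(fits, translate_start, to_spec = family[[nm]])
    f <- tryCatch(fit_model(dataset, family[[nm]], settings,
                            extra_starts = unname(warm)),
                  error = function(e) e)
    if (inherits(f, "error") || !f$converged) {
      warning("model '", nm, "' failed to converge; excluded from the table")
      next
    }
    fits[[nm]] <- f
  }
  if (length(fits) == 0) stop("no candidate model converged")
  tab <- data.frame(model = names(fits),
                    k = vapply(fits, `[[`, 0L, "k"),
                    rss = vapply(fits, `[[`, 0.0, "rss"),
                    aic = vapply(fits, `[[`, 0.0, "aic"),
                    row.names = NULL)
  tab <- tab[order(tab$aic), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$weight <- akaike_weights(tab$aic)
  near <- tab[tab$delta_aic < parsimony_delta, ]
  winner <- near$model[which.min(near$k)]
  rownames(tab) <- NULL
  structure(tab, class = c("selection_table", "data.frame"),
            winner = winner, tie = nrow(near) > 1, fits = fits)
}

#' Winning model of a selection table
#' @param x a `selection_table`.
#' @return The winner's label (character scalar).
#' @export
winner <- function(x) {
  stopifnot(inherits(x, "selection_table"))
  attr(x, "winner")
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Model comparison (least-squares AIC)\n")
  print.data.frame(x, digits = 5)
  cat("winner:", attr(x, "winner"),
      if (isTRUE(attr(x, "tie"))) "(parsimony tie-break applied)" else "",
      "\n")
  invisible(x)
}
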