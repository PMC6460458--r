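#' Candidate model specification
#'
#' Defines one member of the candidate family: the functional form of the
#' migration rate under each condition (`"constant"` = basal rate only,
#' `"pulse"` = basal plus `alpha * t * exp(-m * t)`), whether the lymph-node
#' loss rate is shared across conditions, and how the per-design initial
#' pools are handled (`"free"` fits one pool per photoswitch strategy;
#' `"recruitment"` ties the pools to a three-parameter recruitment curve of
#' the switch time).
#'
#' @param alum_rate_form,saline_rate_form `"pulse"` or `"constant"`.
#' @param delta_shared single loss rate for both conditions?
#' @param x0_policy `"free"` or `"recruitment"`.
#' @param label optional short label for selection tables.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(alum_rate_form = c("pulse", "constant"),
                       saline_rate_form = c("constant", "pulse"),
                       delta_shared = FALSE,
                       x0_policy = c("free", "recruitment"),
                       label = NULL) {
  alum_rate_form <- match.arg(alum_rate_form)
  saline_rate_form <- match.arg(saline_rate_form)
  x0_policy <- match.arg(x0_policy)
  stopifnot(is.logical(delta_shared), length(delta_shared) == 1L)
  if (is.null(label)) {
    label <- sprintf("%s-alum/%s-saline, %s delta",
                     alum_rate_form, saline_rate_form,
                     if (delta_shared) "shared" else "per-condition")
  }
  structure(list(alum_rate_form = alum_rate_form,
                 saline_rate_form = saline_rate_form,
                 delta_shared = delta_shared, x0_policy = x0_policy,
                 label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, x0 %s\n", x$label, x$x0_policy))
  invisible(x)
}

# number of free rate-law parameters (excluding pools)
n_rate_params <- function(spec) {
  1 + 2 * (spec$saline_rate_form == "pulse") +
    2 * (spec$alum_rate_form == "pulse") + 1 +
    (if (spec$delta_shared) 1 else 2) +
    (if (spec$x0_policy == "recruitment") 3 else 0)
}

#' Optimiser settings for model fitting
#'
#' @param n_starts number of dispersed Nelder-Mead starts.
#' @param max_iterations iteration cap per start.
#' @param reltol relative convergence tolerance on the objective.
#' @param seed seed controlling the dispersal of starting points (fitting is
#'   deterministic given the seed).
#' @param dt quadrature step used inside the objective, hours.
#' @param offset stabilising offset `c` in the log-scale residuals
#'   `log(count + c) - log(prediction + c)`, cells.
#' @param spread dispersal of the extra starts, decades around the
#'   moment-based initial guess.
#' @return An object of class `optimizer_settings`.
#' @export
optimizer_settings <- function(n_starts = 8, max_iterations = 5000,
                               reltol = 1e-10, seed = 1, dt = 0.05,
                               offset = 1, spread = 1.5) {
  stopifnot(n_starts >= 1, max_iterations >= 1, reltol > 0, dt > 0,
            offset >= 0, spread >= 0)
  structure(list(n_starts = as.integer(n_starts),
                 max_iterations = as.integer(max_iterations),
                 reltol = reltol, seed = as.integer(seed), dt = dt,
                 offset = offset, spread = spread),
            class = "optimizer_settings")
}

# ---- dataset plumbing -------------------------------------------------------

required_columns <- c("design_id", "condition", "t_pc", "site", "t_harvest",
                      "replicate", "count")

validate_dataset <- function(dataset) {
  miss <- setdiff(required_columns, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(dataset) == 0) stop("dataset is empty")
  bad <- which(!dataset$condition %in% c("saline", "alum"))
  if (length(bad))
    stop("invalid condition on row ", bad[1], ": '", dataset$condition[bad[1]], "'")
  bad <- which(!dataset$site %in% c("skin", "dln"))
  if (length(bad))
    stop("invalid site on row ", bad[1], ": '", dataset$site[bad[1]], "'")
  bad <- which(!is.finite(dataset$count) | dataset$count < 0)
  if (length(bad)) stop("negative or non-finite count on row ", bad[1])
  bad <- which(dataset$t_pc < 0)
  if (length(bad)) stop("negative photoconversion time on row ", bad[1])
  bad <- which(dataset$t_harvest < dataset$t_pc)
  if (length(bad))
    stop("harvest before photoconversion on row ", bad[1])
  tp <- tapply(dataset$t_pc, dataset$design_id, function(x) length(unique(x)))
  if (any(tp > 1))
    stop("design '", names(tp)[tp > 1][1], "' has inconsistent t_pc values")
  cn <- tapply(dataset$condition, dataset$design_id,
               function(x) length(unique(x)))
  if (any(cn > 1))
    stop("design '", names(cn)[cn > 1][1], "' has inconsistent conditions")
  invisible(dataset)
}

# design table in order of first appearance
design_table <- function(dataset) {
  ids <- unique(dataset$design_id)
  i <- match(ids, dataset$design_id)
  data.frame(design_id = ids, t_pc = dataset$t_pc[i],
             condition = dataset$condition[i], stringsAsFactors = FALSE)
}

build_fit_context <- function(dataset, spec, dt, offset) {
  validate_dataset(dataset)
  dt_tab <- design_table(dataset)
  list(site = as.integer(dataset$site == "dln"),
       t = as.numeric(dataset$t_harvest),
       design = match(dataset$design_id, dt_tab$design_id) - 1L,
       lny = log(as.numeric(dataset$count) + offset),
       d_tpc = as.numeric(dt_tab$t_pc),
       d_cond = as.integer(dt_tab$condition == "alum"),
       saline_pulse = spec$saline_rate_form == "pulse",
       alum_pulse = spec$alum_rate_form == "pulse",
       delta_shared = isTRUE(spec$delta_shared),
       x0_curve = spec$x0_policy == "recruitment",
       dt = dt, offset = offset,
       design_ids = dt_tab$design_id)
}

#' Names of the free (log-scale) parameters of a model
#'
#' All rate and time parameters are optimised on the log scale, which
#' enforces positivity by construction.  Under the `"free"` pool policy the
#' vector ends with one `log_x0_<design>` entry per design in the dataset.
#'
#' @param spec a [model_spec()].
#' @param dataset a dataset (needed to enumerate designs under the `"free"`
#'   pool policy); may be omitted for the `"recruitment"` policy.
#' @return Character vector of parameter names.
#' @export
par_names <- function(spec, dataset = NULL) {
  nm <- "log_mu0"
  if (spec$saline_rate_form == "pulse")
    nm <- c(nm, "log_alpha_saline", "log_m_saline")
  if (spec$alum_rate_form == "pulse") nm <- c(nm, "log_alpha", "log_m")
  nm <- c(nm, "log_tau")
  nm <- if (spec$delta_shared) c(nm, "log_delta")
        else c(nm, "log_delta_alum", "log_delta_saline")
  if (spec$x0_policy == "recruitment") {
    nm <- c(nm, "log_r0", "log_beta", "log_b")
  } else if (!is.null(dataset)) {
    nm <- c(nm, paste0("log_x0_", design_table(dataset)$design_id))
  }
  nm
}

#' Encode rate parameters as a free-parameter vector
#'
#' Builds the transformed (log-scale) parameter vector that
#' [residual_loss()] and [fit_model()] operate on, from a
#' [rate_parameters()] object and (optionally) per-design pools.  Useful for
#' evaluating the objective at a known truth.
#'
#' @param params a [rate_parameters()] object.
#' @param spec a [model_spec()] with `x0_policy = "free"`.
#' @param x0 named or design-ordered vector of per-design pools; omitted to
#'   encode only the rate part.
#' @return Named numeric vector on the log scale.
#' @export
encode_parameters <- function(params, spec = model_spec(), x0 = NULL) {
  if (spec$saline_rate_form == "pulse")
    stop("cannot encode a saline pulse from rate_parameters")
  if (spec$x0_policy == "recruitment")
    stop("encode_parameters supports the 'free' pool policy only")
  v <- log(params$mu0)
  if (spec$alum_rate_form == "pulse") {
    if (params$alpha <= 0 || params$m <= 0)
      stop("pulse spec needs alpha > 0 and m > 0")
    v <- c(v, log(params$alpha), log(params$m))
  }
  v <- c(v, log(max(params$tau, 1e-12)))
  v <- if (spec$delta_shared) {
    c(v, log(sqrt(params$delta_alum * params$delta_saline)))
  } else {
    c(v, log(params$delta_alum), log(params$delta_saline))
  }
  if (!is.null(x0)) v <- c(v, log(as.numeric(x0)))
  v
}

decode_parameters <- function(lpar, spec) {
  pos <- 0L
  nx <- function() { pos <<- pos + 1L; exp(lpar[pos]) }
  mu0 <- nx()
  extra <- list()
  if (spec$saline_rate_form == "pulse") {
    extra$alpha_saline <- nx(); extra$m_saline <- nx()
  }
  alpha <- 0; m <- 0
  if (spec$alum_rate_form == "pulse") { alpha <- nx(); m <- nx() }
  tau <- nx()
  if (spec$delta_shared) {
    d <- nx(); da <- d; ds <- d
  } else {
    da <- nx(); ds <- nx()
  }
  curve <- NULL
  if (spec$x0_policy == "recruitment")
    curve <- recruitment_curve(nx(), nx(), nx())
  list(params = rate_parameters(mu0 = mu0, alpha = alpha, m = m, tau = tau,
                                delta_alum = da, delta_saline = ds),
       extra = extra, curve = curve, n_used = pos)
}

# ---- objective --------------------------------------------------------------

#' Log-scale least-squares objective
#'
#' Sum over observations of `[log(count + c) - log(prediction + c)]^2`,
#' with `c` the stabilising offset.  The parameter vector is the full
#' transformed vector (see [par_names()]): rate-law parameters followed, for
#' the `"free"` pool policy, by one `log_x0` per design.  Non-finite
#' predictions are penalised with a large finite loss rather than an error,
#' so the objective is always safe to optimise.
#'
#' @param par transformed free-parameter vector.
#' @param dataset a tidy dataset (see [simulate_dataset()] /
#'   [read_timecourse()]).
#' @param spec a [model_spec()].
#' @param dt quadrature step, hours.
#' @param offset stabilising offset `c`, cells.
#' @return Scalar loss (>= 0; zero iff predictions equal counts exactly).
#' @export
residual_loss <- function(par, dataset, spec = model_spec(), dt = 0.01,
                          offset = 1) {
  ctx <- build_fit_context(dataset, spec, dt, offset)
  cpp_loss(as.numeric(par), ctx, FALSE)
}

# ---- starting values --------------------------------------------------------

# moment-based initial guesses on the log scale (rate part only)
heuristic_start <- function(dataset, spec) {
  mu0 <- 0.01
  sk <- dataset[dataset$condition == "saline" & dataset$site == "skin", ]
  if (nrow(sk) >= 4 && length(unique(sk$t_harvest)) >= 2) {
    sl <- coef(lm(log(count + 1) ~ t_harvest, data = sk))[[2]]
    if (is.finite(sl)) mu0 <- min(max(-sl, 1e-4), 0.5)
  }
  delta_init <- function(cond) {
    d <- dataset[dataset$condition == cond & dataset$site == "dln", ]
    if (nrow(d) < 4) return(0.1)
    rel <- d$t_harvest - d$t_pc
    late <- d[rel >= stats::median(rel), , drop = FALSE]
    if (nrow(late) < 4 || length(unique(late$t_harvest)) < 2) return(0.1)
    sl <- coef(lm(log(count + 1) ~ t_harvest, data = late))[[2]]
    if (!is.finite(sl)) return(0.1)
    min(max(-sl, 5e-3), 2)
  }
  m0 <- 1 / 24
  v <- log(mu0)
  if (spec$saline_rate_form == "pulse")
    v <- c(v, log(4 * mu0 * m0 * exp(1)), log(m0))
  if (spec$alum_rate_form == "pulse")
    v <- c(v, log(4 * mu0 * m0 * exp(1)), log(m0))
  v <- c(v, log(2))  # transit delay, hours
  v <- if (spec$delta_shared) {
    c(v, log(sqrt(delta_init("alum") * delta_init("saline"))))
  } else {
    c(v, log(delta_init("alum")), log(delta_init("saline")))
  }
  if (spec$x0_policy == "recruitment") {
    r0 <- stats::median(sk$count)
    if (!is.finite(r0) || r0 <= 0) r0 <- 500
    v <- c(v, log(r0), log(r0 / 18 * exp(1)), log(1 / 18))
  }
  v
}

# ---- fitting ----------------------------------------------------------------

#' Fit a trafficking model by multistart nonlinear least squares
#'
#' Fits the model simultaneously to the skin and lymph-node time courses of
#' every design in the dataset, minimising [residual_loss()] with
#' Nelder-Mead from `n_starts` dispersed log-scale starting points around a
#' moment-based initial guess.  Under the `"free"` pool policy the
#' per-design initial pools are profiled out of the objective in closed form
#' (variable projection), so the search runs over the few nonlinear rate
#' parameters only.  The returned fit carries the best of all starts; the
#' objective value never exceeds the value at any starting point.
#'
#' @inheritParams residual_loss
#' @param settings an [optimizer_settings()] object.
#' @param extra_starts optional list of additional rate-part starting vectors
#'   (log scale), e.g. solutions of nested models.
#' @return An object of class `kaede_fit`: estimates
#'   ([rate_parameters()]), fitted pools `x0`, `rss`, `n_obs`, `k`, `aic`,
#'   `converged`, the full transformed parameter vector `par`, and a
#'   `weak_tau` flag set when no lymph-node observation falls within 12 h of
#'   its design's photoconversion (the transit delay is then weakly
#'   identified).
#' @examples
#' ds <- simulate_dataset(dense_designs(), seed = 1)
#' fit <- fit_model(ds, model_spec(), optimizer_settings(n_starts = 2))
#' fit
#' @export
fit_model <- function(dataset, spec = model_spec(),
                      settings = optimizer_settings(), extra_starts = NULL) {
  ctx <- build_fit_context(dataset, spec, settings$dt, settings$offset)
  nd <- length(ctx$d_tpc)
  nrate <- n_rate_params(spec)
  k <- as.integer(nrate + if (spec$x0_policy == "free") nd else 0)
  n_obs <- nrow(dataset)
  if (n_obs < k)
    stop("dataset has ", n_obs, " observations; need at least k = ", k)

  base <- heuristic_start(dataset, spec)
  starts <- matrix(base, nrow = 1)
  if (settings$n_starts > 1) {
    disp <- withr::with_seed(settings$seed, {
      matrix(runif((settings$n_starts - 1) * length(base), -1, 1) *
               settings$spread * log(10),
             nrow = settings$n_starts - 1)
    })
    starts <- rbind(starts, sweep(disp, 2, base, `+`))
  }
  for (es in extra_starts) {
    if (length(es) == length(base)) starts <- rbind(starts, as.numeric(es))
  }

  profile <- spec$x0_policy == "free"
  fn <- function(p) cpp_loss(p, ctx, profile)
  ctrl <- list(maxit = settings$max_iterations, reltol = settings$reltol)
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], fn, method = "Nelder-Mead", control = ctrl)
    o <- optim(o$par, fn, method = "Nelder-Mead", control = ctrl)  # polish
    if (o$convergence == 0) n_conv <- n_conv + 1L
    better <- is.null(best) || o$value < best$value - 1e-12 ||
      (abs(o$value - best$value) <= 1e-12 * max(1, abs(best$value)) &&
         lex_less(o$par, best$par))
    if (better) best <- o
  }

  det <- cpp_loss_details(best$par, ctx, profile)
  x0 <- setNames(exp(det$lx0), ctx$design_ids)
  full_par <- if (profile) c(best$par, det$lx0) else best$par
  names(full_par) <- par_names(spec, dataset)
  dec <- decode_parameters(best$par, spec)
  if (!is.null(dec$curve))
    x0 <- setNames(recruitment_pool(ctx$d_tpc, dec$curve,
                                    ifelse(ctx$d_cond == 1, "alum", "saline")),
                   ctx$design_ids)
  rss <- det$value
  weak_tau <- !any(ctx$site == 1L & ctx$t < ctx$d_tpc[ctx$design + 1L] + 12)
  converged <- n_conv > 0L && is.finite(rss) && rss < 1e9
  structure(list(spec = spec, settings = settings,
                 estimates = dec$params, extra = dec$extra, curve = dec$curve,
                 x0 = x0, par = full_par, rss = rss, n_obs = n_obs, k = k,
                 aic = ls_aic(rss, n_obs, k), converged = converged,
                 n_starts = nrow(starts), n_starts_converged = n_conv,
                 weak_tau = weak_tau, data = dataset),
            class = "kaede_fit")
}

lex_less <- function(a, b) {
  d <- a - b
  i <- which(abs(d) > 0)
  length(i) > 0 && d[i[1]] < 0
}

#' @export
print.kaede_fit <- function(x, ...) {
  cat(sprintf("Trafficking model fit: %s\n", x$spec$label))
  cat(sprintf("  n_obs = %d, k = %d, RSS = %.6g, AIC = %.4f, converged: %s\n",
              x$n_obs, x$k, x$rss, x$aic, x$converged))
  if (x$weak_tau)
    cat("  note: no dLN observation within 12 h of photoconversion;",
        "transit delay weakly identified\n")
  print(x$estimates)
  invisible(x)
}

# ---- bootstrap --------------------------------------------------------------

#' Bootstrap confidence intervals for fitted parameters
#'
#' Case-resampling bootstrap: within every (design, site, harvest-time) cell
#' the replicate mice are resampled with replacement (cells keep their size,
#' so no cell can empty), the model is refitted, and percentile (2.5, 97.5)
#' intervals are formed per parameter.  Refits are warm-started at the
#' original solution.
#'
#' @inheritParams fit_model
#' @param n_boot number of bootstrap draws (>= 2).
#' @param seed seed for the resampling.
#' @param n_starts_boot Nelder-Mead starts per refit (the warm start is
#'   always added).
#' @param fit optional pre-computed [fit_model()] result for this dataset
#'   and spec, to avoid refitting.
#' @return An object of class `kaede_boot`: a data frame `ci` with columns
#'   `parameter`, `lower`, `estimate`, `upper`, and the raw `draws` matrix.
#' @export
bootstrap_cis <- function(dataset, spec = model_spec(),
                          settings = optimizer_settings(), n_boot = 200,
                          seed = 1, n_starts_boot = 2, fit = NULL) {
  stopifnot(n_boot >= 2)
  if (is.null(fit)) fit <- fit_model(dataset, spec, settings)
  nrate <- n_rate_params(spec)
  warm <- as.numeric(fit$par[seq_len(nrate)])
  bset <- settings
  bset$n_starts <- as.integer(n_starts_boot)
  cells <- interaction(dataset$design_id, dataset$site, dataset$t_harvest,
                       drop = TRUE)
  idx_by_cell <- split(seq_len(nrow(dataset)), cells)
  pnames <- c("mu0", "alpha", "m", "tau", "delta_alum", "delta_saline")
  draws <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(idx_by_cell, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      db <- dataset[idx, , drop = FALSE]
      fb <- fit_model(db, spec, bset, extra_starts = list(warm))
      unlist(fb$estimates[pnames])
    }, numeric(length(pnames))))
  })
  colnames(draws) <- pnames
  est <- unlist(fit$estimates[pnames])
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  ci <- data.frame(parameter = pnames, lower = qs[1, ], estimate = est,
                   upper = qs[2, ], row.names = NULL)
  structure(list(ci = ci, draws = draws, n_boot = n_boot, fit = fit),
            class = "kaede_boot")
}

#' @export
print.kaede_boot <- function(x, ...) {
  cat(sprintf("Case-resampling bootstrap, %d draws (95%% percentile intervals)\n",
              x$n_boot))
  print(x$ci, digits = 4)
  invisible(x)
}
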