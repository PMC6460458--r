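#' Read a photoconversion time-course CSV
#'
#' Expects the tidy observation schema: columns `design_id`, `condition`
#' (`alum`/`saline`), `t_pc`, `site` (`skin`/`dln`), `t_harvest`,
#' `replicate`, `count`, comma-separated, dot decimal, header mandatory,
#' hours as reals.  Rows may come in any order.  Validation errors name the
#' offending (data) row.
#'
#' @param path CSV file path.
#' @param clock `"injection"` (default; `t_harvest` is hours post-injection)
#'   or `"photoconversion"` (`t_harvest` is hours after the switch and is
#'   converted to the post-injection clock on read).
#' @return A validated data frame of class `kaede_dataset`.
#' @export
read_timecourse <- function(path, clock = c("injection", "photoconversion")) {
  clock <- match.arg(clock)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required_columns, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df <- df[required_columns]
  for (col in c("t_pc", "t_harvest", "count"))
    df[[col]] <- as.numeric(df[[col]])
  df$replicate <- as.integer(df$replicate)
  if (clock == "photoconversion") df$t_harvest <- df$t_pc + df$t_harvest
  validate_dataset(df)
  class(df) <- c("kaede_dataset", "data.frame")
  df
}

#' Write a photoconversion time-course CSV
#'
#' @param dataset a dataset with the observation schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(dataset, path) {
  validate_dataset(dataset)
  write.csv(as.data.frame(dataset)[required_columns], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_config <- function() {
  list(simulate = list(designs = "study", cv = 0.2, floor = 0, seed = 1),
       data = NULL,
       family = "default",
       settings = list(),
       bootstrap = list(n_boot = 0, seed = 1),
       out = NULL)
}

#' Run the simulate/fit/select/report pipeline from one configuration
#'
#' Stages: (1) load the input CSV, or simulate a dataset from the canonical
#' parameter set when the config has a `simulate` block; (2) fit the
#' candidate family and select by AIC; (3) optionally bootstrap the winner;
#' (4) assemble a results document (provenance, per-model fits, selection
#' table, kinetic summary of the winner, accumulated warnings) and write it
#' as JSON when `out` is set.
#'
#' @param config a config list or path to a YAML file.  Recognised fields:
#'   `simulate` (`designs` = `"study"`/`"dense"`, `cv`, `floor`, `seed`) or
#'   `data` (CSV path); `family` (`"default"`) or `model` (one of
#'   `"M0"`-`"M3"`); `settings` (see [optimizer_settings()]); `bootstrap`
#'   (`n_boot`, `seed`); `out` (JSON path).
#' @param seed optional override applied to both the simulation and
#'   optimiser seeds.
#' @param verbose print the selection table and summary.
#' @return The results document (a list), invisibly when `out` is written.
#' @examples
#' doc <- run_pipeline(list(simulate = list(designs = "dense", seed = 3),
#'                          settings = list(n_starts = 2)))
#' doc$selection$winner
#' @export
run_pipeline <- function(config = list(), seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(seed)) {
    cfg$simulate$seed <- seed
    cfg$settings$seed <- seed
    cfg$bootstrap$seed <- seed
  }
  warn <- character()
  timing <- list()
  note <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(expr, warning = function(w) {
      warn <<- c(warn, paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  dataset <- note({
    if (!is.null(cfg$data)) {
      read_timecourse(cfg$data)
    } else {
      des <- switch(cfg$simulate$designs %||% "study",
                    study = study_designs(),
                    dense = dense_designs(),
                    stop("unknown design set: ", cfg$simulate$designs))
      simulate_dataset(des, canonical_parameters(), recruitment_curve(),
                       noise_model(cv = cfg$simulate$cv %||% 0.2,
                                   floor = cfg$simulate$floor %||% 0),
                       seed = cfg$simulate$seed %||% 1)
    }
  }, "data")

  settings <- do.call(optimizer_settings, cfg$settings)
  fam <- if (!is.null(cfg$model)) {
    default_model_family()[cfg$model]
  } else if (identical(cfg$family, "default")) {
    default_model_family()
  } else stop("unknown family: ", cfg$family)
  if (any(vapply(fam, is.null, TRUE))) stop("unknown model name in config")

  sel <- note(compare_models(dataset, fam, settings), "fit_select")
  fits <- attr(sel, "fits")
  win <- winner(sel)
  summ <- kinetic_summary(fits[[win]])

  boot <- NULL
  nb <- cfg$bootstrap$n_boot %||% 0
  if (nb >= 2) {
    boot <- note(bootstrap_cis(dataset, fam[[win]], settings, n_boot = nb,
                               seed = cfg$bootstrap$seed %||% 1,
                               fit = fits[[win]]), "bootstrap")
  }

  doc <- list(
    provenance = list(package = "kaedekin",
                      version = as.character(packageVersion("kaedekin")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                      config = cfg, timing = timing),
    data = list(n_obs = nrow(dataset),
                designs = design_table(dataset)),
    fits = lapply(fits, function(f) {
      list(model = f$spec$label, k = f$k, rss = f$rss, aic = f$aic,
           converged = f$converged, estimates = unclass(f$estimates),
           x0 = as.list(f$x0), weak_tau = f$weak_tau)
    }),
    selection = list(table = as.data.frame(sel), winner = win,
                     tie = isTRUE(attr(sel, "tie"))),
    summary = unclass(summ),
    bootstrap = if (!is.null(boot)) list(n_boot = boot$n_boot, ci = boot$ci),
    warnings = warn)

  if (verbose) { print(sel); print(summ) }
  if (!is.null(cfg$out)) {
    dir.create(dirname(cfg$out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(doc, cfg$out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(doc))
  }
  doc
}

`%||%` <- function(a, b) if (is.null(a)) b else a
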