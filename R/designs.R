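#' A photoconversion experimental design
#'
#' One photoswitch strategy: a treatment condition, the time the injection
#' site is exposed to violet light (every cell present is labelled), the
#' harvest times at which sites are measured, and the replicate count.
#'
#' @param condition `"saline"` or `"alum"`.
#' @param t_pc photoconversion time, hours post-injection (>= 0).
#' @param harvest_times harvest times, hours post-injection, all `>= t_pc`.
#' @param n_replicates mice per (site, harvest) cell (>= 1).
#' @param sites non-empty subset of `c("skin", "dln")`.
#' @param id design label; auto-generated when `NULL`.
#' @return An object of class `pc_design`.
#' @export
pc_design <- function(condition, t_pc, harvest_times, n_replicates = 4,
                      sites = c("skin", "dln"), id = NULL) {
  condition <- match_condition(condition)
  stopifnot(is.numeric(t_pc), length(t_pc) == 1L, t_pc >= 0,
            is.numeric(harvest_times), length(harvest_times) >= 1L,
            n_replicates >= 1)
  sites <- match.arg(sites, c("skin", "dln"), several.ok = TRUE)
  if (min(harvest_times) < t_pc)
    stop("all harvest times must be >= the photoconversion time")
  if (is.null(id)) id <- sprintf("%s_pc%g", condition, t_pc)
  structure(list(id = id, condition = condition, t_pc = t_pc,
                 harvest_times = sort(unique(as.numeric(harvest_times))),
                 n_replicates = as.integer(n_replicates), sites = sites),
            class = "pc_design")
}

#' @export
print.pc_design <- function(x, ...) {
  cat(sprintf("<pc_design %s> %s, switch %g h, harvests {%s} h, n = %d, sites %s\n",
              x$id, x$condition, x$t_pc,
              paste(x$harvest_times, collapse = ", "), x$n_replicates,
              paste(x$sites, collapse = "+")))
  invisible(x)
}

#' Standard photoswitch/harvest schedules
#'
#' The three schedule families used in footpad photoconversion studies, for
#' both conditions, with both sites measured and `n_replicates` mice per
#' cell:
#' \describe{
#'   \item{delayed-switch}{switch at 0, 4, 8 or 12 h; harvests at 24 and 48 h
#'     (how much of the eventual migratory pool is recruited after
#'     injection).}
#'   \item{fixed-switch}{switch at 12 h; harvests at 24, 36, 48 and 72 h
#'     (arrival and persistence in the lymph node).}
#'   \item{sliding-switch}{switch at 12, 24, 36 or 60 h; harvest 12 h after
#'     the switch (for how long the site keeps exporting cells).}
#' }
#'
#' @param n_replicates mice per (site, harvest) cell.
#' @return A list of [pc_design()] objects.
#' @export
study_designs <- function(n_replicates = 4) {
  out <- list()
  for (cond in c("saline", "alum")) {
    for (tp in c(0, 4, 8, 12)) {
      out[[length(out) + 1L]] <- pc_design(
        cond, tp, c(24, 48), n_replicates,
        id = sprintf("%s_delayed_pc%g", cond, tp))
    }
    out[[length(out) + 1L]] <- pc_design(
      cond, 12, c(24, 36, 48, 72), n_replicates,
      id = sprintf("%s_fixed_pc12", cond))
    for (tp in c(12, 24, 36, 60)) {
      out[[length(out) + 1L]] <- pc_design(
        cond, tp, tp + 12, n_replicates,
        id = sprintf("%s_sliding_pc%g", cond, tp))
    }
  }
  out
}

#' Dense-harvest designs for transit-time identifiability
#'
#' Both conditions sampled at both sites every `by` hours from the
#' photoconversion time to `t_pc + span`.  The early, closely spaced
#' lymph-node harvests pin down the transit delay, which the sparse standard
#' schedules leave weakly identified.
#'
#' @param t_pc photoconversion time, hours post-injection.
#' @param span hours of follow-up after the switch.
#' @param by harvest spacing, hours.
#' @param n_replicates mice per (site, harvest) cell.
#' @return A list of two [pc_design()] objects (saline, alum).
#' @export
dense_designs <- function(t_pc = 12, span = 24, by = 2, n_replicates = 4) {
  lapply(c("saline", "alum"), function(cond) {
    pc_design(cond, t_pc, seq(t_pc, t_pc + span, by = by), n_replicates,
              id = sprintf("%s_dense_pc%g", cond, t_pc))
  })
}
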