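#' Plot a fitted trafficking model over the data
#'
#' One panel per (site, condition): observed photoconverted counts (points)
#' with the fitted expected time course of each design (lines), on a log10
#' count axis.
#'
#' @param x a `kaede_fit`.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.kaede_fit <- function(x, ...) {
  ds <- x$data
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  dtab <- design_table(ds)
  for (site in c("skin", "dln")) {
    for (cond in c("saline", "alum")) {
      sub <- ds[ds$site == site & ds$condition == cond, ]
      if (nrow(sub) == 0) next
      graphics::plot(sub$t_harvest, pmax(sub$count, 0.5), log = "y",
                     pch = 16, col = "grey40", cex = 0.7,
                     xlab = "hours post-injection",
                     ylab = sprintf("%s count", site),
                     main = sprintf("%s, %s", site, cond))
      dd <- dtab[dtab$condition == cond & dtab$design_id %in% sub$design_id, ]
      for (j in seq_len(nrow(dd))) {
        id <- dd$design_id[j]
        tpc <- dd$t_pc[j]
        tmax <- max(sub$t_harvest[sub$design_id == id])
        tt <- seq(tpc, tmax, length.out = 100)
        yy <- if (site == "skin") {
          skin_timecourse(tt, x$x0[[id]], tpc, x$estimates, cond)
        } else {
          dln_timecourse(tt, x$x0[[id]], tpc, x$estimates, cond)
        }
        graphics::lines(tt, pmax(yy, 0.5), col = j + 1)
      }
    }
  }
  invisible(x)
}
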