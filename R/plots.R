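## Base-graphics plots: lineage-through-time curves with detected shifts,
## and fossil standing-diversity curves.

#' Plot a lineage-through-time curve with optional shift marks
#'
#' Age runs right to left (oldest at the left edge, present at 0) and the
#' lineage count is on a log scale, the conventional LTT presentation.
#' Detected shifts are drawn as vertical arrows.
#'
#' @param tree an ultrametric `phylo`, or a [lttCurve()] data.frame.
#' @param shifts optional numeric ages, or the `shifts` data.frame of a
#'   [ShiftFit-class] (arrow direction follows `direction`).
#' @param ... further arguments passed to [plot()].
#' @return invisibly, the plotted curve.
#' @export
plotLTT <- function(tree, shifts = NULL, ...) {
  curve <- if (is.data.frame(tree)) tree else lttCurve(tree)
  plot(curve$age, curve$lineages, type = "s", log = "y",
       xlim = rev(range(curve$age)), xlab = "Age (Ma)",
       ylab = "Lineages", ...)
  if (!is.null(shifts)) {
    ages <- if (is.data.frame(shifts)) shifts$time else shifts
    up <- if (is.data.frame(shifts) && "direction" %in% names(shifts))
      shifts$direction == "increase" else rep(TRUE, length(ages))
    usr <- par("usr")
    y0 <- 10^(usr[3] + 0.75 * (usr[4] - usr[3]))
    y1 <- 10^(usr[3] + 0.9 * (usr[4] - usr[3]))
    arrows(ages, ifelse(up, y0, y1), ages, ifelse(up, y1, y0),
           length = 0.08, col = "red")
  }
  invisible(curve)
}

#' Plot a fossil standing-diversity curve
#'
#' Total range-through diversity against age (oldest left), optionally
#' split by a grouping column, with a reference line at a highlighted age
#' (e.g. the Grande Coupure at 33.9 Ma).
#'
#' @param ranges data.frame with `first_ma`, `last_ma` and optionally a
#'   `group` column.
#' @param ages sampling grid in Ma.
#' @param highlight optional age(s) marked with dashed vertical lines.
#' @param ... further arguments passed to [plot()].
#' @return invisibly, the total-diversity curve.
#' @export
plotDiversityCurve <- function(ranges, ages = seq(66, 0, by = -1),
                               highlight = NULL, ...) {
  total <- diversityCurve(ranges, ages)
  plot(total$age, total$count, type = "l", lwd = 2,
       xlim = rev(range(ages)), xlab = "Age (Ma)",
       ylab = "Standing diversity (species)", ...)
  if ("group" %in% names(ranges)) {
    grps <- unique(ranges$group)
    for (i in seq_along(grps)) {
      sub <- diversityCurve(ranges[ranges$group == grps[i], ], ages)
      lines(sub$age, sub$count, lty = i + 1)
    }
    legend("topright", legend = c("total", grps), lwd = c(2, rep(1,
           length(grps))), lty = c(1, seq_along(grps) + 1), bty = "n")
  }
  if (!is.null(highlight)) abline(v = highlight, lty = 2)
  invisible(total)
}
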