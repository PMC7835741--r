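#' Manhattan-style plot of window variance explained
#'
#' One point per 0.8 Mb (or chosen size) window at its midpoint along the
#' concatenated genome, height = percentage of additive genetic variance
#' explained, chromosomes in alternating shades, with the significance
#' threshold as a dashed line.
#'
#' @param windows window table with `gvarPercent` (from [windowVariance()]
#'   or [windowVariances()]).
#' @param threshold significance threshold to draw (default 1).
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, the data.frame of plotted coordinates.
#' @importFrom graphics abline axis points
#' @importFrom grDevices hcl.colors
#' @export
plotWindowVariance <- function(windows, threshold = 1, main = "gVar (%) per window",
                               ...) {
  chrOrd <- suppressWarnings(as.numeric(windows$chrom))
  windows <- windows[order(chrOrd, windows$chrom, windows$startBp), ,
                     drop = FALSE]
  chroms <- unique(windows$chrom)
  offset <- 0
  xmid <- numeric(nrow(windows))
  ticks <- numeric(length(chroms))
  for (k in seq_along(chroms)) {
    sel <- windows$chrom == chroms[k]
    span <- max(windows$endBp[sel])
    xmid[sel] <- offset + (windows$startBp[sel] + windows$endBp[sel]) / 2
    ticks[k] <- offset + span / 2
    offset <- offset + span
  }
  cols <- rep(c("grey25", "steelblue"), length.out = length(chroms))
  plot(xmid, windows$gvarPercent, pch = 16, cex = 0.6,
       col = cols[match(windows$chrom, chroms)],
       xaxt = "n", xlab = "Chromosome", ylab = "gVar (%)", main = main, ...)
  axis(1, at = ticks, labels = chroms, tick = FALSE)
  abline(h = threshold, lty = 2, col = "firebrick")
  invisible(data.frame(x = xmid, gvarPercent = windows$gvarPercent,
                       chrom = windows$chrom))
}
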