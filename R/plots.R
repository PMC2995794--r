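# genome-wide x coordinates: chromosomes concatenated in layout order
concat_coords <- function(chrom, x, layout) {
  offs <- c(0, cumsum(layout$length))[seq_len(nrow(layout))]
  names(offs) <- layout$chrom
  x + offs[chrom]
}

chrom_boundaries <- function(layout) cumsum(layout$length)

#' Genome-wide recurrent-CNA plot
#'
#' Gain KC scores are drawn upward, loss KC scores downward (negated),
#' chromosomes concatenated in layout order with alternating shading, and
#' the permutation significance thresholds as dashed lines.
#'
#' @param x A \code{kc_recurrent} result.
#' @param main Plot title.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot_genome_kc <- function(x, main = "Recurrent copy-number aberrations",
                           ...) {
  grid <- x$grid
  layout <- grid$layout
  gx <- concat_coords(grid$chrom, grid$x, layout)
  g <- x$gain$values
  l <- -x$loss$values
  ylim <- range(c(g, l, x$thr_gain, -x$thr_loss), finite = TRUE)
  graphics::plot(NA, xlim = c(0, sum(layout$length)), ylim = ylim,
                 xlab = "Genome position (bp, chromosomes concatenated)",
                 ylab = "KC score (gain up / loss down)", main = main, ...)
  bnd <- chrom_boundaries(layout)
  starts <- c(0, bnd[-length(bnd)])
  for (k in seq_along(bnd))
    if (k %% 2 == 0)
      graphics::rect(starts[k], ylim[1], bnd[k], ylim[2],
                     col = "grey93", border = NA)
  graphics::abline(h = 0, col = "grey60")
  graphics::lines(gx, g, col = "firebrick")
  graphics::lines(gx, l, col = "navy")
  graphics::abline(h = x$thr_gain, col = "red", lty = 2)
  graphics::abline(h = -x$thr_loss, col = "red", lty = 2)
  graphics::mtext(layout$chrom, side = 3,
                  at = (starts + bnd) / 2, cex = 0.6, line = 0)
  invisible(x)
}

#' Two-group comparative profile plot
#'
#' Overlays the per-point class-mean KC profiles; significant differential
#' regions are shaded grey.
#'
#' @param x A \code{kc_comparative} result.
#' @param main Plot title.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{x}.
#' @export
plot_compare <- function(x, main = "Two-class comparative analysis", ...) {
  grid <- x$grid
  layout <- grid$layout
  gx <- concat_coords(grid$chrom, grid$x, layout)
  ylim <- range(c(x$mu1, x$mu2), finite = TRUE)
  graphics::plot(NA, xlim = c(0, sum(layout$length)), ylim = ylim,
                 xlab = "Genome position (bp, chromosomes concatenated)",
                 ylab = "Mean per-sample KC score", main = main, ...)
  if (nrow(x$regions)) {
    rs <- concat_coords(x$regions$chrom, x$regions$start_bp, layout)
    re <- concat_coords(x$regions$chrom, x$regions$end_bp, layout)
    graphics::rect(rs, ylim[1], re, ylim[2], col = "grey85", border = NA)
  }
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(v = chrom_boundaries(layout), col = "grey80")
  graphics::lines(gx, x$mu1, col = "red")
  graphics::lines(gx, x$mu2, col = "black")
  graphics::legend("topright", legend = c("class 1", "class 2"),
                   col = c("red", "black"), lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Scale-space significance heatmap
#'
#' Rows are kernel widths, columns genome positions; the colour encodes
#' the significance level (-log10 empirical p) of significant points, with
#' non-significant cells left blank. Gains and losses are drawn as two
#' stacked panels.
#'
#' @param x A \code{kc_scale_space} result.
#' @param ... Unused.
#' @return Invisibly, \code{x}.
#' @export
plot_scale_space <- function(x, ...) {
  grid <- x$grid
  layout <- grid$layout
  gx <- concat_coords(grid$chrom, grid$x, layout)
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  panel <- function(sig, lab) {
    m <- nrow(sig)
    graphics::image(gx, seq_len(m), t(pmax(sig, 0)),
                    col = c("white", pal),
                    xlab = "Genome position (bp)", ylab = "Kernel width",
                    yaxt = "n", main = paste("Scale space:", lab))
    graphics::axis(2, at = seq_len(m),
                   labels = format(x$kernel_widths, big.mark = ","),
                   cex.axis = 0.7, las = 1)
    graphics::abline(v = chrom_boundaries(layout), col = "grey70")
  }
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 6, 2, 1))
  on.exit(graphics::par(old))
  panel(x$sig_gain, "gains")
  panel(x$sig_loss, "losses")
  invisible(x)
}
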