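#' Plot a stimulus time series
#'
#' Draws `OSS_avg/a`, `WSS_avg/b` and their sum `S_avg` over the loading
#' cycle and marks the compression- and release-phase maxima
#' (`S_Max1`, `S_Max2`).
#'
#' @param x a [averaged_series()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.stimulus_series <- function(x, ...) {
  consts <- attr(x, "consts")
  graphics::plot(x$time, x$s_avg, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = "stimulus (-)",
                 main = attr(x, "design"), ...)
  graphics::lines(x$time, x$oss_avg / consts$a, lty = 2, col = "firebrick")
  graphics::lines(x$time, x$wss_avg / consts$b, lty = 3, col = "steelblue")
  sm <- find_smax(x)
  graphics::points(c(sm$smax1[["time"]], sm$smax2[["time"]]),
                   c(sm$smax1[["value"]], sm$smax2[["value"]]),
                   pch = 17, col = "darkorange", cex = 1.3)
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3),
                   col = c("black", "firebrick", "steelblue"),
                   legend = c("S_avg", "OSS_avg / a", "WSS_avg / b"))
  invisible(x)
}

#' Plot a strand layout (top view)
#'
#' @param x a [build_layout()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.strand_layout <- function(x, ...) {
  spec <- layout_spec(x)
  R <- spec$D_scaffold / 2
  graphics::plot(NA, xlim = c(-R, R), ylim = c(-R, R), asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = spec$name, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(R * cos(th), R * sin(th), col = "grey50")
  w <- spec$D_strand / 2
  for (k in seq_len(nrow(x))) {
    if (x$orientation[k] == 0)
      graphics::rect(x$x0[k], x$offset[k] - w, x$x1[k], x$offset[k] + w,
                     col = grDevices::adjustcolor("tan3", 0.35), border = NA)
    else
      graphics::rect(x$offset[k] - w, x$y0[k], x$offset[k] + w, x$y1[k],
                     col = grDevices::adjustcolor("tan4", 0.35), border = NA)
  }
  invisible(x)
}

#' Plot a sweep report
#'
#' Stacked phenotype surface shares per design, in sweep order.
#'
#' @param x a [run_sweep()] result.
#' @param ... further arguments passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_report <- function(x, ...) {
  pct <- t(vapply(x$summaries, unclass, numeric(length(PHENOTYPE_LEVELS))))
  cols <- c(very_low = "grey80", bone = "steelblue",
            cartilage = "seagreen", fibrous = "goldenrod",
            very_high = "firebrick")
  graphics::barplot(t(pct), col = cols[colnames(pct)], border = NA,
                    las = 2, ylab = "surface share (%)", ...)
  graphics::legend("topright", bty = "n", fill = cols,
                   legend = names(cols), cex = 0.8)
  invisible(x)
}
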