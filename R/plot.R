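# step-expanded coordinates for right-continuous curves
step_coords <- function(t, v, tau) {
  xr <- c(t[-1], tau)
  list(x = as.vector(rbind(t, xr)), y = rep(v, each = 2))
}

#' Plot a fitted survival curve with confidence bands
#'
#' Modified Kaplan-Meier display: right-continuous step curves per arm with
#' shaded normal confidence bands.
#'
#' @param x a [wce_fit()].
#' @param col colors, one per arm.
#' @param ylim y-axis limits.
#' @param xlab,ylab,main usual graphics labels.
#' @param band draw the confidence bands (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.wce_fit <- function(x, col = c("#00589C", "#C03A2B", "#3B8044"),
                         ylim = NULL, xlab = "Days",
                         ylab = "Event-free survival", main = NULL, band = TRUE,
                         ...) {
  arms <- names(x$curves)
  col <- rep(col, length.out = length(arms))
  tau <- x$followup
  if (is.null(ylim)) {
    lo <- min(vapply(x$curves, function(cv) min(cv$ci_lower), 0))
    ylim <- c(max(0, lo - 0.02), 1)
  }
  if (is.null(main))
    main <- if (x$method == "weighted") "Weighted composite endpoint"
            else "Time to first event"
  plot(NA, xlim = c(0, tau), ylim = ylim, xlab = xlab, ylab = ylab,
       main = main, ...)
  for (ai in seq_along(arms)) {
    cv <- x$curves[[ai]]
    if (band && nrow(cv) > 1) {
      lo <- step_coords(cv$time, cv$ci_lower, tau)
      hi <- step_coords(cv$time, cv$ci_upper, tau)
      polygon(c(lo$x, rev(hi$x)), c(lo$y, rev(hi$y)), border = NA,
              col = adjustcolor(col[ai], alpha.f = 0.2))
    }
    sc <- step_coords(cv$time, cv$estimate, tau)
    lines(sc$x, sc$y, col = col[ai], lwd = 2)
  }
  legend("bottomleft", legend = arms, col = col[seq_along(arms)], lwd = 2,
         bty = "n")
  invisible(x)
}

#' Side-by-side traditional vs weighted panels
#'
#' Two-panel display of a [compare_endpoints()] result: the traditional
#' time-to-first-event curves on the left, the weighted composite endpoint
#' curves on the right, both arms with confidence bands.
#'
#' @param x a `wce_comparison`.
#' @param ... passed to [plot.wce_fit()].
#' @return `x`, invisibly.
#' @export
plot.wce_comparison <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  ylim <- c(max(0, min(vapply(
    c(x$fits$traditional$curves, x$fits$weighted$curves),
    function(cv) min(cv$ci_lower), 0)) - 0.02), 1)
  plot(x$fits$traditional, ylim = ylim, ...)
  plot(x$fits$weighted, ylim = ylim, ...)
  invisible(x)
}
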