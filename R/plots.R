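#' Plot velocity and error-rate curves against the force
#'
#' Base-graphics view of the elongation branches: velocity (top) and error
#' rate (bottom) against the entropy production per monomer, one line per
#' branch. Bistable force windows show as overlapping branches.
#'
#' @param x An [velocity_error_curves()] result.
#' @param ... Passed to [plot()].
#' @export
plot.elongation_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  sp <- split(as.data.frame(x), x$branch_id)
  graphics::plot(range(x$A), range(x$v), type = "n",
                 xlab = "A (kT per monomer)", ylab = "v", ...)
  for (b in sp) graphics::lines(b$A, b$v, lty = min(b$branch_id[1], 3))
  graphics::plot(range(x$A), range(x$eps), type = "n",
                 xlab = "A (kT per monomer)", ylab = expression(epsilon), ...)
  for (b in sp) graphics::lines(b$A, b$eps, lty = min(b$branch_id[1], 3))
  invisible(x)
}

#' Plot a phase diagram
#'
#' Image of the realized mean fitness over the (Q, A) grid with phase labels,
#' the spinodal, the melting contour, and the critical and triple points.
#'
#' @param x A [build_phase_diagram()] result.
#' @param what Matrix to color: `"w_bar"`, `"eps2"`, `"v"` or `"eps"`.
#' @param ... Passed to [image()].
#' @export
plot.phase_diagram <- function(x, what = c("w_bar", "eps2", "v", "eps"), ...) {
  what <- match.arg(what)
  graphics::image(log10(x$Q), x$A, x[[what]], xlab = "log10 Q",
                  ylab = "A (kT per monomer)", main = what, ...)
  f <- x$features
  if (nrow(f$spinodal)) graphics::lines(log10(f$spinodal$Q), f$spinodal$A, lwd = 2)
  if (nrow(f$melting)) graphics::lines(log10(f$melting$Q), f$melting$A,
                                       col = "red", lwd = 2)
  if (!is.null(f$critical_point))
    graphics::points(log10(f$critical_point["Q"]), f$critical_point["A"], pch = 19)
  if (!is.null(f$triple_point))
    graphics::points(log10(f$triple_point["Q"]), f$triple_point["A"], pch = 1)
  invisible(x)
}

#' Plot a population trajectory
#'
#' Master frequency and mean fractional Hamming distance to the master over
#' time.
#'
#' @param x A [run_eigen_model()] / [run_crystallization()] trajectory.
#' @param ... Passed to [plot()].
#' @export
plot.population_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$x_master, type = "l", ylim = c(0, 1), xlab = "time",
                 ylab = "frequency / distance", ...)
  graphics::lines(x$t, x$mean_hd, lty = 2)
  graphics::legend("right", legend = c("master frequency", "mean HD to master"),
                   lty = 1:2, bty = "n")
  invisible(x)
}
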