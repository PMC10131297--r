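#' Plot component-ensemble decoupling for one scenario
#'
#' Scatter of species-median ensemble strength (negated Gompertz slope)
#' against component strength (mean 1 - S_red), with 95% interval bars and
#' the exponential-plateau fit overlaid.
#'
#' @param summaries data.frame from [summarize_species()] restricted to
#'   one scenario.
#' @param plateau Overlay the [fit_plateau()] curve.
#' @param ... Passed to [graphics::plot()].
#' @return The `plateau_fit` (or `NULL`), invisibly.
#' @export
plot_decoupling <- function(summaries, plateau = TRUE, ...) {
  x <- summaries$component_strength_median
  y <- summaries$strength_median
  graphics::plot(x, y,
                 xlab = "component strength (1 - S_red)",
                 ylab = "ensemble strength (-beta, Gompertz)",
                 pch = 19, ...)
  graphics::segments(x, summaries$strength_lo, x, summaries$strength_hi,
                     col = "grey60")
  pl <- NULL
  if (plateau && length(x) >= 4) {
    pl <- tryCatch(fit_plateau(x, y), error = function(e) NULL)
    if (!is.null(pl) && !is.na(pl$k_rate)) {
      xs <- seq(min(x), max(x), length.out = 200)
      graphics::lines(xs, pl$ymax - (pl$ymax - pl$y0) * exp(-pl$k_rate * xs),
                      col = "firebrick", lwd = 2)
    }
  }
  invisible(pl)
}

#' Plot one abundance series
#'
#' @param x An `abundance_series`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.abundance_series <- function(x, ...) {
  graphics::plot(seq_along(x$N), x$N, type = "l",
                 xlab = "year (post burn-in)", ylab = "total abundance N",
                 main = sprintf("%s, scenario %s", x$abbr, x$scenario), ...)
  invisible(x)
}
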