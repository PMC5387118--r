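#' @export
plot.viability_map <- function(x, levels = c(0.1, 0.25, 0.5, 0.75, 0.9),
                               ...) {
  graphics::filled.contour(
    x$D_grid * 1e6, x$V_grid, x$eta,
    levels = seq(0, 1, 0.05),
    color.palette = function(n) grDevices::hcl.colors(n, "RdYlGn"),
    plot.title = {
      graphics::title(xlab = expression(D[0] ~ (mu * m)),
                      ylab = expression(V[0] ~ (m / s)),
                      main = "Predicted cell viability")
    },
    ...
  )
  invisible(x)
}

#' @export
plot.viability_distribution <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::barplot(x$bin_frequencies, names.arg = sprintf("%.2f", mids),
                    xlab = expression(eta), ylab = "relative incidence f",
                    main = sprintf("Expected viability %.2f", x$mean_eta),
                    border = NA, las = 2, ...)
  invisible(x)
}
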