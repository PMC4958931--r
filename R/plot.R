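#' Plot a receptive-field centroid map
#'
#' One point per cortical column at its receptive-field centroid position on
#' the input lattice, with digit boundaries dashed -- the standard display
#' for watching the somatotopic map refine, collapse under syndactyly, and
#' recover after release.
#'
#' @param x an [rf_map()].
#' @param type cell type to plot.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rf_map <- function(x, type = c("E", "I"), ...) {
  type <- match.arg(type)
  spec <- attr(x, "spec")
  d <- x[x$type == type, ]
  graphics::plot(d$centroid_col, d$centroid_row, pch = 16, cex = 0.4,
                 xlim = c(1, spec$N), ylim = c(spec$N, 1),
                 xlab = "input column (proximal-distal)",
                 ylab = "input row (across digits)",
                 main = sprintf("%s-cell RF centroids (cycle %d)", type,
                                attr(x, "cycle")), ...)
  b <- digit_bands(spec)
  graphics::abline(h = b$last[-nrow(b)] + 0.5, lty = 2, col = "grey40")
  invisible(x)
}

#' Image of the intracolumnar divergence grid
#'
#' @param map an [rf_map()].
#' @param threshold divergence level marked by the contour of interest.
#' @return The divergence grid matrix, invisibly.
#' @export
plot_divergence <- function(map, threshold = 2 * sqrt(2)) {
  spec <- attr(map, "spec")
  div <- rf_divergence(map)
  g <- matrix(0, spec$N, spec$N)
  g[cbind(div$row, div$col)] <- div$divergence
  graphics::image(seq_len(spec$N), seq_len(spec$N), t(g)[, spec$N:1],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "cortical column", ylab = "cortical row",
                  main = "E-I centroid divergence")
  b <- digit_bands(spec)
  graphics::abline(h = spec$N - b$last[-nrow(b)] + 0.5, lty = 2)
  invisible(g)
}
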