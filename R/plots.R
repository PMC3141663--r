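# Base-graphics views of spectra and PCA results.

#' @export
plot.spectrum1d <- function(x, xlim = NULL, ...) {
  if (is.null(xlim)) xlim <- rev(range(x$ppm))  # ppm runs right to left
  plot(x$ppm, x$intensity, type = "l", xlim = xlim,
       xlab = "chemical shift (ppm)", ylab = "intensity (a.u.)", ...)
  invisible(x)
}

#' @export
plot.dc_pca <- function(x, components = c(1, 2), groups = NULL, ...) {
  sc <- x$scores[, components, drop = FALSE]
  vf <- round(100 * x$variance_fraction[components], 1)
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(sc[, 1], sc[, 2], col = col, pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", components[1], vf[1]),
       ylab = sprintf("PC%d (%.1f%%)", components[2], vf[2]), ...)
  invisible(x)
}
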