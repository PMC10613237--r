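# Base-graphics displays for fields, plates, objects and results.

plot_map <- function(map, grid = NULL, main = "", col = grDevices::hcl.colors(64)) {
  x <- if (!is.null(grid)) grid$x else seq_len(nrow(map))
  graphics::image(x, x, map, asp = 1, col = col, main = main,
                  xlab = if (!is.null(grid)) "x (um)" else "x",
                  ylab = if (!is.null(grid)) "y (um)" else "y",
                  useRaster = TRUE)
}

#' @export
plot.complex_field <- function(x, what = c("amplitude", "phase"), ...) {
  what <- match.arg(what)
  m <- if (what == "amplitude") Mod(x$values) else Arg(x$values)
  plot_map(m, x$grid, main = paste("field", what), ...)
  invisible(x)
}

#' @export
plot.phase_plate <- function(x, ...) {
  g_x <- (seq_len(nrow(x$phase)) - 1 - floor(nrow(x$phase) / 2)) * x$pitch
  graphics::image(g_x, g_x, wrap_phase(x$phase), asp = 1,
                  col = grDevices::hcl.colors(64, "RdYlBu"),
                  main = sprintf("phase plate at z = %g um", x$depth),
                  xlab = "x (um)", ylab = "y (um)", useRaster = TRUE)
  invisible(x)
}

#' @export
plot.object_map <- function(x, ...) {
  plot_map(Mod(x$reflectance)^2, x$grid, main = "object |O|^2", ...)
  invisible(x)
}

#' @export
plot.mst_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot_map(x$image, x$grid, main = "MST image")
  tr <- x$traces
  graphics::plot(tr$cycle, tr$xi1, type = "b", log = "y",
                 xlab = "cycle", ylab = expression(xi[1]),
                 main = "ballistic enhancement")
  invisible(x)
}
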