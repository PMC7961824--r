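#' Sliding-window quantitative parameter maps
#'
#' For every window position the four window-local vessel metrics (diameter,
#' density, PVD, complexity) are computed and stored at the window centre,
#' yielding per-pixel maps of how the vascular parameters are distributed
#' across the image. Borders are reflect-padded so every map has the shape
#' of the input; with `stride_px > 1` the gaps are filled with the nearest
#' computed window value. Window-local complexity uses the reduced box-size
#' ladder of powers of two up to `min(window_px, 8)` (3-point fits on an 8 px
#' window are noisy; a 16 px window gives smoother complexity maps). The
#' diameter map reads the global distance transform inside the window, and
#' PVD/complexity are computed on the skeleton.
#'
#' @param mask binary vessel mask.
#' @param skeleton skeleton of the mask.
#' @param distance_map Euclidean distance transform of the mask.
#' @param window_px window side, >= 2 (8 as in the quantitative-map design).
#' @param stride_px window step, >= 1 (1 = dense map).
#' @param pixel_size_um pixel size for the diameter map.
#' @return List of class `quant_maps` with numeric matrices `diameter` (um),
#'   `density`, `pvd` (both in `[0, 1]`) and `complexity`.
#' @export
compute_quant_maps <- function(mask, skeleton, distance_map, window_px = 8,
                               stride_px = 1, pixel_size_um = 10) {
  y <- as_binary_matrix(mask)
  r <- as_binary_matrix(skeleton, "skeleton")
  if (window_px < 2) stop("`window_px` must be >= 2")
  if (stride_px < 1) stop("`stride_px` must be >= 1")
  if (window_px > nrow(y) || window_px > ncol(y))
    stop("window larger than image")
  if (!identical(dim(y), dim(r)) || !identical(dim(y), dim(distance_map)))
    stop("inputs must share one shape")
  out <- cpp_quant_maps(y, r, distance_map, as.integer(window_px),
                        as.integer(stride_px), pixel_size_um)
  structure(out, window_px = window_px, stride_px = stride_px,
            class = "quant_maps")
}

#' Extract the reflect-padded window centred at a pixel
#'
#' The window convention of [compute_quant_maps()]: for window side w the
#' centre pixel (1-based `i`, `j`) has `floor((w - 1) / 2)` rows above and
#' `floor(w / 2)` below, with out-of-frame positions reflected. Useful for
#' checking a map value against the global metrics on the cropped window.
#'
#' @param x matrix.
#' @param i,j 1-based centre pixel.
#' @param window_px window side.
#' @return `window_px` x `window_px` matrix.
#' @export
extract_window <- function(x, i, j, window_px) {
  lo <- (window_px - 1) %/% 2
  hi <- window_px %/% 2
  ri <- vapply((i - lo):(i + hi), function(k) reflect1(k, nrow(x)), integer(1))
  ci <- vapply((j - lo):(j + hi), function(k) reflect1(k, ncol(x)), integer(1))
  x[ri, ci, drop = FALSE]
}

reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  as.integer(i)
}

#' @export
print.quant_maps <- function(x, ...) {
  cat(sprintf("<quant_maps> %d x %d px, window %d, stride %d\n",
              nrow(x$density), ncol(x$density),
              attr(x, "window_px"), attr(x, "stride_px")))
  for (nm in names(x))
    cat(sprintf("  %-10s [%.4g, %.4g]\n", nm, min(x[[nm]]), max(x[[nm]])))
  invisible(x)
}
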