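#' Image containers
#'
#' Light S3 wrappers around plain matrices/arrays. A `map_image` is the
#' central object of the pipeline: a nonnegative 2D intensity grid I(i,j)
#' obtained by maximum amplitude projection of a photoacoustic volume (or
#' rendered directly by the phantom generator), carrying its lateral pixel
#' size in micrometres and a provenance tag.
#'
#' @param intensity nonnegative numeric matrix.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param provenance `"raw"` or `"median_filtered"`.
#' @return A `map_image` object (matrix with attributes).
#' @export
map_image <- function(intensity, pixel_size_um = 10,
                      provenance = c("raw", "median_filtered")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("`intensity` must be a numeric matrix")
  if (any(!is.finite(intensity)))
    stop("`intensity` must be finite")
  if (any(intensity < 0))
    stop("`intensity` must be nonnegative")
  structure(intensity, pixel_size_um = pixel_size_um,
            provenance = provenance, class = c("map_image", "matrix", "array"))
}

#' @export
print.map_image <- function(x, ...) {
  cat(sprintf("<map_image> %d x %d px, %.3g um/px, %s; intensity [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"),
              attr(x, "provenance"), min(x), max(x)))
  invisible(x)
}

#' Photoacoustic RF volume
#'
#' A 3D grid of time-resolved RF samples indexed (row i, col j, axial k),
#' with axial sample spacing `dz_um` and lateral pixel size `pixel_size_um`.
#'
#' @param samples real 3D array (rows x cols x axial samples).
#' @param dz_um axial sample spacing in micrometres.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @return An `rf_volume` object.
#' @export
rf_volume <- function(samples, dz_um, pixel_size_um = 10) {
  if (!is.array(samples) || length(dim(samples)) != 3)
    stop("`samples` must be a 3D array")
  if (any(!is.finite(samples))) stop("`samples` must be finite")
  if (dz_um <= 0) stop("`dz_um` must be positive")
  structure(list(samples = samples, dz_um = dz_um,
                 pixel_size_um = pixel_size_um), class = "rf_volume")
}

#' @export
print.rf_volume <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<rf_volume> %d x %d lateral, %d axial samples (dz %.3g um)\n",
              d[1], d[2], d[3], x$dz_um))
  invisible(x)
}

as_binary_matrix <- function(x, arg = "mask") {
  if (inherits(x, "map_image")) x <- unclass(x)
  if (!is.matrix(x)) stop(sprintf("`%s` must be a matrix", arg))
  x <- x * 1  # logical -> numeric
  if (any(!(x == 0 | x == 1))) stop(sprintf("`%s` must be binary (0/1)", arg))
  storage.mode(x) <- "integer"
  attributes(x) <- list(dim = dim(x))
  x
}
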