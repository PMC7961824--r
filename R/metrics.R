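#' Mean PA signal of an image region
#'
#' The PA amplitude summary of a MAP image or ROI. Two readings of the
#' "upper 50% of the data" rule are provided: `upper_half` (default) sorts
#' the intensities and averages the pixels at or above the median;
#' `above_half_mean` averages the pixels strictly greater than half the
#' global mean. An all-zero image returns 0 under either mode.
#'
#' @param map_img a [map_image] or numeric matrix.
#' @param mode `"upper_half"` or `"above_half_mean"`.
#' @return Scalar amplitude (same units as the image).
#' @export
pa_signal <- function(map_img, mode = c("upper_half", "above_half_mean")) {
  mode <- match.arg(mode)
  x <- as.numeric(unclass(map_img))
  if (length(x) == 0) stop("empty image")
  if (all(x == 0)) return(0)
  if (mode == "upper_half") {
    mean(x[x >= stats::median(x)])
  } else {
    sel <- x > 0.5 * mean(x)
    if (!any(sel)) return(0)
    mean(x[sel])
  }
}

#' Vessel density
#'
#' Fraction of image pixels covered by the binary vessel mask:
#' `VD = sum(Y) / (m * n)`.
#'
#' @param mask binary matrix Y(i,j).
#' @return Fraction in `[0, 1]`.
#' @export
vessel_density <- function(mask) {
  y <- as_binary_matrix(mask)
  sum(y) / length(y)
}

#' Perfused vessel density
#'
#' Skeleton-pixel fraction. The default follows the printed formula
#' `PVD = sum(R) / (m * n)` (skeleton length per image area, so `PVD <= VD`);
#' `denominator = "skeleton_pixels"` instead divides by the skeleton pixel
#' count, which under the all-skeleton-pixels-perfused convention is 1 for
#' any nonempty skeleton.
#'
#' @param skeleton binary skeleton matrix R(i,j).
#' @param denominator `"image_pixels"` (default) or `"skeleton_pixels"`.
#' @return Fraction in `[0, 1]`.
#' @export
perfused_vessel_density <- function(skeleton,
                                    denominator = c("image_pixels",
                                                    "skeleton_pixels")) {
  denominator <- match.arg(denominator)
  r <- as_binary_matrix(skeleton, "skeleton")
  n_skel <- sum(r)
  if (denominator == "image_pixels") n_skel / length(r)
  else if (n_skel == 0) 0 else 1
}

#' Mean vessel diameter along centrelines
#'
#' Per skeleton pixel the local diameter is `2 * E(i,j) - 1` pixels, where E
#' is the Euclidean distance to the nearest background pixel (exact for
#' odd-width bars under the pixel-centre convention; a -1 px bias for even
#' widths is accepted). VDI is the mean over skeleton pixels, converted to
#' micrometres. Returns 0 for an empty skeleton.
#'
#' @param distance_map Euclidean distance transform of the vessel mask (px).
#' @param skeleton binary skeleton of the same mask.
#' @param pixel_size_um pixel size in micrometres.
#' @return Mean diameter in micrometres.
#' @export
vessel_diameter <- function(distance_map, skeleton, pixel_size_um = 10) {
  r <- as_binary_matrix(skeleton, "skeleton")
  if (!identical(dim(distance_map), dim(r)))
    stop("`distance_map` and `skeleton` must have identical shapes")
  if (sum(r) == 0) return(0)
  mean(2 * distance_map[r == 1L] - 1) * pixel_size_um
}

#' Box counts over a grid of scales
#'
#' Number of s x s grid cells (anchored at the image origin; partial edge
#' cells count) containing at least one foreground pixel, for each s.
#'
#' @param mask binary matrix.
#' @param box_sizes integer box sizes.
#' @return Integer vector of counts, one per size.
#' @export
box_counts <- function(mask, box_sizes) {
  y <- as_binary_matrix(mask)
  fg <- which(y == 1L, arr.ind = TRUE)
  vapply(box_sizes, function(s) {
    if (nrow(fg) == 0) return(0L)
    ci <- (fg[, 1] - 1) %/% s
    cj <- (fg[, 2] - 1) %/% s
    length(unique(ci * (ncol(y) %/% s + 1L) + cj))
  }, integer(1))
}

#' Vessel complexity (box-counting fractal dimension)
#'
#' Least-squares slope of `log(Ns)` against `log(1/s)` over the box-size
#' ladder: ~1 for a line, ~2 for a filled region, log8/log3 = 1.893 for the
#' Sierpinski carpet. Returns 0 for an empty input.
#'
#' @param mask_or_skeleton binary matrix (skeleton by default in the
#'   pipeline: network complexity independent of vessel thickness).
#' @param box_sizes at least 3 strictly increasing box sizes.
#' @return Dimension estimate, ~`[0, 2]` for 2D inputs.
#' @export
vessel_complexity <- function(mask_or_skeleton, box_sizes = c(1, 2, 4, 8, 16, 32)) {
  if (length(box_sizes) < 3 || any(diff(box_sizes) <= 0))
    stop("`box_sizes` must be >= 3 strictly increasing sizes")
  ns <- box_counts(mask_or_skeleton, box_sizes)
  if (all(ns == 0)) return(0)
  fit <- stats::lm.fit(cbind(1, log(box_sizes)), log(ns))
  -unname(fit$coefficients[2])
}

#' Metrics configuration
#'
#' Bundles the switches of the five metrics for [compute_metrics()] and the
#' study runner.
#'
#' @param pa_mode PA signal reading, see [pa_signal()].
#' @param pvd_denominator see [perfused_vessel_density()].
#' @param vc_input compute complexity on the `"skeleton"` (default) or the
#'   `"mask"`.
#' @param box_sizes box-size ladder for [vessel_complexity()].
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(pa_mode = "upper_half",
                           pvd_denominator = "image_pixels",
                           vc_input = c("skeleton", "mask"),
                           box_sizes = c(1, 2, 4, 8, 16, 32)) {
  structure(list(pa_mode = pa_mode, pvd_denominator = pvd_denominator,
                 vc_input = match.arg(vc_input), box_sizes = box_sizes),
            class = "metrics_config")
}

#' Compute the five vascular metrics
#'
#' Bundles PA signal, vessel diameter (VDI), vessel density (VD), perfused
#' vessel density (PVD) and vessel complexity (VC) for one image or ROI,
#' recording the configuration used alongside the values.
#'
#' @param map_img intensity image (for the PA signal).
#' @param mask,skeleton,distance_map segmentation products of the same image.
#' @param config a [metrics_config()].
#' @param pixel_size_um pixel size; defaults to the `map_img` attribute.
#' @param roi_name,timepoint optional provenance labels.
#' @return A `metrics_record`: list with `pa_signal`, `vdi_um`, `vd`, `pvd`,
#'   `vc` plus provenance.
#' @export
compute_metrics <- function(map_img, mask, skeleton, distance_map,
                            config = metrics_config(), pixel_size_um = NULL,
                            roi_name = NA_character_,
                            timepoint = NA_character_) {
  if (is.null(pixel_size_um))
    pixel_size_um <- attr(map_img, "pixel_size_um") %||% 10
  dm <- dim(unclass(map_img))
  if (!identical(dm, dim(mask)) || !identical(dm, dim(skeleton)) ||
      !identical(dm, dim(distance_map)))
    stop("image and segmentation products must share one shape")
  vc_src <- if (config$vc_input == "skeleton") skeleton else mask
  structure(list(
    pa_signal = pa_signal(map_img, config$pa_mode),
    vdi_um = vessel_diameter(distance_map, skeleton, pixel_size_um),
    vd = vessel_density(mask),
    pvd = perfused_vessel_density(skeleton, config$pvd_denominator),
    vc = vessel_complexity(vc_src, config$box_sizes),
    pixel_size_um = pixel_size_um, roi_name = roi_name,
    timepoint = timepoint, config = config
  ), class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "<metrics_record>%s%s PA %.4g | VDI %.4g um | VD %.4g | PVD %.4g | VC %.3g\n",
    if (is.na(x$roi_name)) "" else paste0(" ", x$roi_name),
    if (is.na(x$timepoint)) "" else paste0(" @", x$timepoint),
    x$pa_signal, x$vdi_um, x$vd, x$pvd, x$vc))
  invisible(x)
}

#' @export
as.data.frame.metrics_record <- function(x, ...) {
  data.frame(roi = x$roi_name, timepoint = x$timepoint,
             pa_signal = x$pa_signal, vdi_um = x$vdi_um, vd = x$vd,
             pvd = x$pvd, vc = x$vc, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
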