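#' Hilbert-transform envelope of an RF A-line
#'
#' Magnitude of the analytic signal, computed in the frequency domain: the
#' negative-frequency half of the spectrum is zeroed (positive frequencies
#' doubled) and the inverse FFT magnitude taken. For an amplitude-modulated
#' carrier the envelope recovers the modulation away from the record edges.
#'
#' @param a_line real numeric vector, length >= 8.
#' @return Nonnegative numeric vector of the same length.
#' @export
hilbert_envelope <- function(a_line) {
  if (!is.numeric(a_line) || length(a_line) < 8)
    stop("`a_line` must be a numeric vector of length >= 8")
  if (any(!is.finite(a_line))) stop("`a_line` must be finite")
  n <- length(a_line)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(a_line) * h, inverse = TRUE) / n)
}

#' Maximum amplitude projection of an RF volume
#'
#' For every lateral position the Hilbert envelope of the A-line is computed
#' and its maximum over depth is stored, yielding the 2D MAP image that all
#' downstream segmentation and quantification operates on.
#'
#' @param volume an [rf_volume].
#' @return A [map_image] with provenance `"raw"`.
#' @export
compute_map <- function(volume) {
  stopifnot(inherits(volume, "rf_volume"))
  env <- envelope_volume(volume$samples)
  map_image(apply(env, c(1, 2), max), pixel_size_um = volume$pixel_size_um)
}

# envelope of every A-line, vectorised across the lateral grid via a single
# FFT along the axial dimension
envelope_volume <- function(samples) {
  d <- dim(samples)
  n <- d[3]
  flat <- matrix(aperm(samples, c(3, 1, 2)), nrow = n)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  sp <- stats::mvfft(flat) * h
  env <- Mod(stats::mvfft(sp, inverse = TRUE) / n)
  aperm(array(env, c(n, d[1], d[2])), c(2, 3, 1))
}

#' Depth map from an RF volume
#'
#' Depth of the envelope maximum per lateral position, in micrometres.
#' Positions whose peak envelope does not exceed `noise_floor` are marked
#' `NA`. Ties are broken towards the shallowest sample, so depth-encoded
#' images show the top surface.
#'
#' @param volume an [rf_volume].
#' @param noise_floor nonnegative amplitude threshold.
#' @return Numeric matrix of depths in um (`NA` = below noise floor).
#' @export
compute_depth_map <- function(volume, noise_floor = 0) {
  stopifnot(inherits(volume, "rf_volume"), noise_floor >= 0)
  env <- envelope_volume(volume$samples)
  peak <- apply(env, c(1, 2), max)
  idx <- apply(env, c(1, 2), which.max)  # which.max: first (shallowest) tie
  depth <- (idx - 1) * volume$dz_um
  depth[peak <= noise_floor] <- NA_real_
  depth
}

#' Median-filter denoising of a MAP image
#'
#' Square median filter with reflected borders; `kernel_size = 1` is the
#' identity. Used to suppress isolated noise pixels before morphological
#' evaluation, leaving edges of vessels intact.
#'
#' @param map_img a [map_image] (or plain matrix).
#' @param kernel_size odd integer >= 1.
#' @return A [map_image] with provenance `"median_filtered"`.
#' @export
denoise_median <- function(map_img, kernel_size = 3) {
  if (kernel_size < 1 || kernel_size %% 2 == 0)
    stop("`kernel_size` must be an odd integer >= 1")
  px <- if (inherits(map_img, "map_image")) attr(map_img, "pixel_size_um") else 10
  x <- unclass(map_img)
  attributes(x) <- list(dim = dim(x))
  out <- if (kernel_size == 1) x else cpp_median_filter(x, as.integer(kernel_size))
  map_image(out, pixel_size_um = px, provenance = "median_filtered")
}
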