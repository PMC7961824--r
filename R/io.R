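#' Write a MAP image (or any numeric matrix) as TIFF
#'
#' TIFF sample values live in `[0, 1]`, so raw quantitative values are
#' divided by a scale factor before writing (`normalize = FALSE`, 32-bit
#' float, scale = the value maximum or 1, whichever is larger) and the scale
#' plus pixel size are recorded in a small JSON sidecar (`<path>.json`) that
#' [read_map_tiff()] uses to restore the original values exactly.
#' `normalize = TRUE` instead min-max scales to `[0, 1]` and writes 16-bit
#' (display output, no sidecar).
#'
#' @param x numeric matrix / [map_image].
#' @param path output file.
#' @param normalize min-max scale to `[0, 1]` before writing.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path, normalize = FALSE) {
  m <- unclass(x)
  px <- attr(x, "pixel_size_um")
  attributes(m) <- list(dim = dim(m))
  storage.mode(m) <- "double"
  if (normalize) {
    rng <- range(m)
    if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng) else m <- m * 0
    tiff::writeTIFF(m, path, bits.per.sample = 16)
  } else {
    scale <- max(max(m), 1)
    tiff::writeTIFF(m / scale, path, bits.per.sample = 32, reduce = FALSE)
    jsonlite::write_json(
      list(scale = scale,
           pixel_size_um = if (is.null(px)) NA else px),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a TIFF written by [write_image_tiff()]
#'
#' If the sidecar `<path>.json` written by [write_image_tiff()] exists, the
#' stored scale and pixel size are applied; otherwise values are returned as
#' stored and `pixel_size_um` is taken from the argument.
#'
#' @param path file path.
#' @param pixel_size_um pixel size to attach when no sidecar is present.
#' @return A [map_image].
#' @export
read_map_tiff <- function(path, pixel_size_um = 10) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    m <- m * meta$scale
    if (!is.null(meta$pixel_size_um) && !is.na(meta$pixel_size_um))
      pixel_size_um <- meta$pixel_size_um
  }
  map_image(m, pixel_size_um = pixel_size_um)
}

#' Write ground truth (vessel tree + masks) as JSON + TIFF
#'
#' The tree is serialised as a list of polylines with radii and region
#' labels; masks go to float TIFFs next to the JSON.
#'
#' @param truth a ground-truth list from [render_map_image()].
#' @param tree the [generate_vessel_tree()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return The JSON path, invisibly.
#' @export
write_ground_truth <- function(truth, tree, dir, prefix = "truth") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  segs <- lapply(tree$segments, function(s)
    list(x = unname(s$vertices[, "x"]), y = unname(s$vertices[, "y"]),
         r = unname(s$vertices[, "r"]),
         parent = if (is.na(s$parent)) NULL else s$parent,
         region = s$region))
  js <- file.path(dir, paste0(prefix, "_tree.json"))
  jsonlite::write_json(segs, js, auto_unbox = TRUE, digits = NA)
  write_image_tiff(truth$vessel_mask, file.path(dir, paste0(prefix, "_vessel_mask.tif")))
  write_image_tiff(truth$centerline_mask, file.path(dir, paste0(prefix, "_centerline.tif")))
  write_image_tiff(truth$radius_map, file.path(dir, paste0(prefix, "_radius.tif")))
  invisible(js)
}

#' Write quantitative parameter maps as float TIFFs plus PNG previews
#'
#' One 32-bit float TIFF per metric plus a colormapped PNG preview; when a
#' shared scale per metric is supplied the previews are comparable across
#' timepoints.
#'
#' @param maps a [compute_quant_maps()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param scale optional named list `metric = c(lo, hi)` shared display range.
#' @return Invisibly, the written file paths.
#' @export
write_quant_maps <- function(maps, dir, prefix = "map", scale = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(maps)) {
    tp <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    write_image_tiff(maps[[nm]], tp)
    pp <- file.path(dir, sprintf("%s_%s.png", prefix, nm))
    rng <- if (!is.null(scale[[nm]])) scale[[nm]] else range(maps[[nm]])
    v <- maps[[nm]]
    v <- if (diff(rng) > 0) pmin(pmax((v - rng[1]) / diff(rng), 0), 1) else v * 0
    pal <- grDevices::hcl.colors(256, "Inferno")
    idx <- matrix(pal[pmin(255, floor(v * 255)) + 1], nrow(v), ncol(v))
    grDevices::png(pp, width = ncol(v), height = nrow(v))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(idx), 0, 0, 1, 1,
                          interpolate = FALSE)
    grDevices::dev.off()
    paths <- c(paths, tp, pp)
  }
  invisible(paths)
}

#' Write an RF volume as a multi-page TIFF
#'
#' One 32-bit float page per axial sample. RF samples are signed, so they
#' are mapped to `[0, 1]` by a linear offset/scale recorded in the sidecar
#' `<path>.json` (together with `dz_um` and `pixel_size_um`), from which the
#' original values can be restored as `stored * scale + offset`.
#'
#' @param volume an [rf_volume].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "rf_volume"))
  d <- dim(volume$samples)
  rng <- range(volume$samples)
  scale <- max(rng[2] - rng[1], 1e-300)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- (volume$samples[, , k] - rng[1]) / scale
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale, dz_um = volume$dz_um,
         pixel_size_um = volume$pixel_size_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
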