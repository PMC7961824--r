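#' Rectangular region of interest
#'
#' 0-based, half-open pixel coordinates: the crop covers rows
#' `[y0, y0 + height)` and columns `[x0, x0 + width)`.
#'
#' @param name ROI label (e.g. `A_control`).
#' @param x0,y0 top-left corner (0-based; x = column, y = row).
#' @param width,height extent in pixels.
#' @return An `roi_spec` list.
#' @export
roi_spec <- function(name, x0, y0, width, height) {
  if (width < 1 || height < 1) stop("ROI must have positive extent")
  structure(list(name = name, x0 = x0, y0 = y0, width = width,
                 height = height), class = "roi_spec")
}

#' Crop an image or mask to an ROI
#'
#' @param x matrix or [map_image].
#' @param roi an [roi_spec()].
#' @return The cropped object, preserving `map_image` attributes.
#' @export
extract_roi <- function(x, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  nr <- nrow(x); nc <- ncol(x)
  if (roi$y0 < 0 || roi$x0 < 0)
    stop(sprintf("ROI '%s' has negative origin (%d, %d)", roi$name,
                 roi$x0, roi$y0))
  if (roi$y0 + roi$height > nr)
    stop(sprintf("ROI '%s' exceeds image rows: y0 + height = %d > %d",
                 roi$name, roi$y0 + roi$height, nr))
  if (roi$x0 + roi$width > nc)
    stop(sprintf("ROI '%s' exceeds image cols: x0 + width = %d > %d",
                 roi$name, roi$x0 + roi$width, nc))
  out <- x[(roi$y0 + 1):(roi$y0 + roi$height),
           (roi$x0 + 1):(roi$x0 + roi$width), drop = FALSE]
  if (inherits(x, "map_image"))
    out <- map_image(out, attr(x, "pixel_size_um"), attr(x, "provenance"))
  out
}

#' Signed percent change from a control value
#'
#' `100 * (value - control) / control`; negative means a decrease. A zero
#' control yields `NA` (surfaced in tables rather than raised).
#'
#' @param value,control_value numeric.
#' @return Percent change (vectorised).
#' @export
percent_change <- function(value, control_value) {
  ifelse(control_value == 0, NA_real_,
         100 * (value - control_value) / control_value)
}

#' The study's timepoint labels, in protocol order
#' @export
timepoint_levels <- function() {
  c("pre_injection", "post_RB", "post_PDT1", "post_PDT2")
}

#' Run the quantitative time-course over ROIs and timepoints
#'
#' For every ROI at every timepoint the full pipeline is run on the cropped
#' image (MAP reconstruction first if the input is an RF volume, then
#' optional median denoising, vesselness segmentation, and the five
#' metrics), and each metric is normalised as a signed percent change
#' against the first timepoint (the pre-injection control value, per ROI).
#' Segmentation is per ROI, so a treatment that alters a disjoint part of
#' the frame cannot change a control ROI's values.
#'
#' @param image_series named list of [map_image]s (or [rf_volume]s), names
#'   drawn from [timepoint_levels()], at least 2, first = control; all the
#'   same shape.
#' @param roi_list list of [roi_spec()].
#' @param config list of pipeline settings: `metrics` (a [metrics_config()]),
#'   `median_kernel` (1 = off), and segmentation knobs `scales_px`, `beta`,
#'   `block_size`, `offset`, `min_object_px`, `fill_hole_px`.
#' @return A `timecourse` object: data.frame `table` in long form (roi,
#'   timepoint, metric, value, percent_change) plus the records and config.
#' @export
run_timecourse <- function(image_series, roi_list, config = list()) {
  if (length(image_series) < 2) stop("need at least 2 timepoints")
  if (is.null(names(image_series)) ||
      !all(names(image_series) %in% timepoint_levels()))
    stop("image_series names must be timepoint labels: ",
         paste(timepoint_levels(), collapse = ", "))
  cfg <- utils::modifyList(list(metrics = metrics_config(), median_kernel = 3,
                                scales_px = c(1, 2, 3, 4, 6, 8), beta = 0.5,
                                block_size = 31, offset = 0.01,
                                min_object_px = 20, fill_hole_px = 10),
                           config)
  shapes <- lapply(image_series, function(x)
    if (inherits(x, "rf_volume")) dim(x$samples)[1:2] else dim(x))
  if (length(unique(shapes)) != 1)
    stop("all timepoints must share one image shape")
  tps <- names(image_series)
  rows <- list()
  records <- list()
  for (tp in tps) {
    img <- image_series[[tp]]
    if (inherits(img, "rf_volume")) img <- compute_map(img)
    for (roi in roi_list) {
      crop <- extract_roi(img, roi)
      if (cfg$median_kernel > 1) crop <- denoise_median(crop, cfg$median_kernel)
      seg <- segment_vessels(crop, scales_px = cfg$scales_px, beta = cfg$beta,
                             block_size = cfg$block_size, offset = cfg$offset,
                             min_object_px = cfg$min_object_px,
                             fill_hole_px = cfg$fill_hole_px)
      rec <- compute_metrics(crop, seg$mask, seg$skeleton, seg$distance,
                             config = cfg$metrics, roi_name = roi$name,
                             timepoint = tp)
      records[[paste(roi$name, tp, sep = ".")]] <- rec
      rows[[length(rows) + 1]] <- as.data.frame(rec)
    }
  }
  wide <- do.call(rbind, rows)
  long <- stats::reshape(wide, direction = "long",
                         varying = c("pa_signal", "vdi_um", "vd", "pvd", "vc"),
                         v.names = "value", timevar = "metric",
                         times = c("pa_signal", "vdi_um", "vd", "pvd", "vc"),
                         idvar = c("roi", "timepoint"))
  rownames(long) <- NULL
  control <- long[long$timepoint == tps[1], c("roi", "metric", "value")]
  names(control)[3] <- "control_value"
  long <- merge(long, control, by = c("roi", "metric"), sort = FALSE)
  long$percent_change <- percent_change(long$value, long$control_value)
  long <- long[order(match(long$roi, vapply(roi_list, `[[`, "", "name")),
                     match(long$timepoint, tps),
                     match(long$metric,
                           c("pa_signal", "vdi_um", "vd", "pvd", "vc"))),
               c("roi", "timepoint", "metric", "value", "control_value",
                 "percent_change")]
  rownames(long) <- NULL
  structure(list(table = long, records = records, timepoints = tps,
                 rois = vapply(roi_list, `[[`, "", "name"), config = cfg),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d ROIs x %d timepoints\n", length(x$rois),
              length(x$timepoints)))
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("...", nrow(x$table) - 10, "more rows\n")
  invisible(x)
}

#' Mean percent change across ROIs
#'
#' Arithmetic mean of the per-ROI percent changes of one metric at one
#' timepoint (the cross-ROI summary used to rank metric sensitivity).
#'
#' @param timecourse a [run_timecourse()] result.
#' @param metric one of `pa_signal`, `vdi_um`, `vd`, `pvd`, `vc`.
#' @param timepoint a timepoint label present in the timecourse.
#' @return Scalar percent.
#' @export
summarize_mean_across_rois <- function(timecourse, metric, timepoint) {
  stopifnot(inherits(timecourse, "timecourse"))
  tab <- timecourse$table
  sel <- tab$metric == metric & tab$timepoint == timepoint
  if (!any(sel)) stop("metric/timepoint not present")
  vals <- tab$percent_change[sel]
  if (length(vals) != length(timecourse$rois)) stop("missing ROI rows")
  mean(vals)
}

#' Write the time-course table as tidy CSV
#'
#' Deterministic byte output (fixed row order, no quoting surprises) so
#' repeated runs with the same seed compare equal.
#'
#' @param timecourse a [run_timecourse()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(timecourse, path) {
  utils::write.csv(timecourse$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Grouped-bar percent-change plot, one panel per metric
#'
#' Bars grouped by timepoint within ROI, mirroring how PDT response is read:
#' contrast uptake after injection, then staged decreases after each
#' treatment.
#'
#' @param timecourse a [run_timecourse()] result.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_timecourse <- function(timecourse, path, width = 1400, height = 900) {
  tab <- timecourse$table
  metrics <- c("pa_signal", "vdi_um", "vd", "pvd", "vc")
  labels <- c("PA signal", "Vessel diameter", "Vessel density",
              "Perfused vessel density", "Vessel complexity")
  tps <- timecourse$timepoints
  cols <- grDevices::hcl.colors(length(tps), "Zissou 1")
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 3), mar = c(6, 4, 3, 1))
  for (k in seq_along(metrics)) {
    sub <- tab[tab$metric == metrics[k], ]
    m <- matrix(sub$percent_change[order(match(sub$roi, timecourse$rois),
                                         match(sub$timepoint, tps))],
                nrow = length(tps),
                dimnames = list(tps, timecourse$rois))
    graphics::barplot(m, beside = TRUE, col = cols, las = 2,
                      main = labels[k], ylab = "% change vs pre-injection")
    if (k == 1) graphics::legend("topright", legend = tps, fill = cols,
                                 cex = 0.8, bty = "n")
  }
  invisible(path)
}

#' Simulate the four-timepoint PDT monitoring study
#'
#' Builds the full synthetic protocol on one phantom: baseline imaging
#' (`pre_injection`), contrast uptake after photosensitizer injection
#' (`post_RB`, global vessel/tumor gain), first treatment targeting tumor 1
#' (`post_PDT1`), second treatment targeting tumor 2 (`post_PDT2`). Each
#' treatment is an elliptical irradiation centred on its tumor that destroys
#' a seeded random fraction of in-region vessel segments, shrinks survivors,
#' and knocks down the tumor amplitude. Returns rendered MAP images, ground
#' truths, the four ROIs (control, normal-near-tumor, tumor 1, tumor 2) and
#' the phantom states.
#'
#' @param seed integer; drives everything.
#' @param image_shape c(rows, cols).
#' @param rb_gain contrast-uptake intensity gain after injection (default
#'   1.07, in the 5-8% uptake range).
#' @param kill_fraction,shrink_factor,tumor_factor per-treatment effect
#'   parameters.
#' @param noise_sigma additive noise sd.
#' @param roi_inset_px margin (px) by which each ROI is inset from its
#'   region zone.
#' @return List with `images` (named [map_image] list), `truths`,
#'   `phantoms`, `rois`, `pdt_specs`.
#' @export
simulate_pdt_series <- function(seed, image_shape = c(512, 512),
                                rb_gain = 1.07, kill_fraction = 0.7,
                                shrink_factor = 0.8, tumor_factor = 0.02,
                                noise_sigma = 0.02, roi_inset_px = 2) {
  base <- vessel_phantom(image_shape = image_shape, seed = seed,
                         noise_params = list(sigma = noise_sigma, speckle = 0))
  post_rb <- base
  post_rb$gain <- rb_gain
  zones <- region_zones(image_shape)
  ellipse_for <- function(zone) {
    list(cx = (zone[3] + zone[4]) / 2, cy = (zone[1] + zone[2]) / 2,
         rx = 0.28 * image_shape[2], ry = 0.21 * image_shape[1])
  }
  spec1 <- pdt_effect_spec(ellipse_for(zones$tumor1), kill_fraction,
                           shrink_factor, tumor_factor)
  spec2 <- pdt_effect_spec(ellipse_for(zones$tumor2), kill_fraction,
                           shrink_factor, tumor_factor)
  post_pdt1 <- apply_pdt_effect(post_rb, spec1, seed + 11L)
  post_pdt2 <- apply_pdt_effect(post_pdt1, spec2, seed + 12L)
  phantoms <- list(pre_injection = base, post_RB = post_rb,
                   post_PDT1 = post_pdt1, post_PDT2 = post_pdt2)
  rendered <- lapply(phantoms, render_map_image)
  # each ROI covers its whole region zone (inset a little): segments are
  # confined to their zone, so every ROI is guaranteed to contain its
  # region's vasculature for any seed
  roi_in <- function(name, zone) {
    roi_spec(name,
             x0 = zone[3] + roi_inset_px, y0 = zone[1] + roi_inset_px,
             width = zone[4] - zone[3] - 2 * roi_inset_px,
             height = zone[2] - zone[1] - 2 * roi_inset_px)
  }
  rois <- list(roi_in("A_control", zones$control),
               roi_in("B_normal", zones$normal_near_tumor),
               roi_in("C_melanoma1", zones$tumor1),
               roi_in("D_melanoma2", zones$tumor2))
  list(images = lapply(rendered, `[[`, "map"),
       truths = lapply(rendered, `[[`, "truth"),
       phantoms = phantoms, rois = rois,
       pdt_specs = list(post_PDT1 = spec1, post_PDT2 = spec2))
}
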