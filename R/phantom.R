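# run code with a private, restored RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# the four study regions as 0-based half-open boxes (row0,row1,col0,col1)
region_zones <- function(image_shape) {
  nr <- image_shape[1]; nc <- image_shape[2]
  list(
    control           = c(0, floor(0.45 * nr), 0, floor(0.45 * nc)),
    normal_near_tumor = c(0, floor(0.45 * nr), ceiling(0.55 * nc), nc),
    tumor1            = c(ceiling(0.55 * nr), nr, 0, floor(0.45 * nc)),
    tumor2            = c(ceiling(0.55 * nr), nr, ceiling(0.55 * nc), nc)
  )
}

#' Generate a synthetic vessel tree
#'
#' Seeded random-walk polylines with optional branching, one of the four
#' study region labels per segment (control, normal_near_tumor, tumor1,
#' tumor2 -- roots are distributed round-robin so all four classes are
#' covered), and radii tapering from parent to child. Segments are confined
#' to their region's zone of the frame, so treatment applied to one zone
#' cannot touch vessels of another.
#'
#' @param seed integer seed; the tree is a pure function of seed + params.
#' @param n_roots number of root vessels.
#' @param branching_params list: `prob` (per-root probability of spawning a
#'   child, recursively), `max_depth`, `step_px`, `n_steps` (range),
#'   `angle_jitter` (sd, radians), `taper` (child/parent radius ratio).
#' @param radius_range_px root radius range (min >= 1).
#' @param image_shape c(rows, cols), each >= 64.
#' @return A `vessel_tree`: list of segments, each with `vertices` (matrix
#'   with columns x, y, r; x = column, y = row, 1-based), `parent`, `region`.
#' @export
generate_vessel_tree <- function(seed, n_roots = 12,
                                 branching_params = list(),
                                 radius_range_px = c(2, 10),
                                 image_shape = c(512, 512)) {
  if (any(image_shape < 64)) stop("`image_shape` must be at least 64 x 64")
  if (radius_range_px[1] < 1) stop("minimum radius must be >= 1 px")
  bp <- utils::modifyList(list(prob = 0.35, max_depth = 2, step_px = 6,
                               n_steps = c(12, 30), angle_jitter = 0.25,
                               taper = 0.8), branching_params)
  zones <- region_zones(image_shape)
  region_names <- names(zones)
  with_seed(seed, {
    segments <- list()
    walk <- function(x0, y0, ang, r, zone, parent, depth) {
      n <- sample(bp$n_steps[1]:bp$n_steps[2], 1)
      xs <- numeric(n + 1); ys <- numeric(n + 1)
      xs[1] <- x0; ys[1] <- y0
      for (k in seq_len(n)) {
        ang <- ang + stats::rnorm(1, 0, bp$angle_jitter)
        xs[k + 1] <- min(max(xs[k] + bp$step_px * cos(ang), zone[3] + r + 1),
                         zone[4] - r)
        ys[k + 1] <- min(max(ys[k] + bp$step_px * sin(ang), zone[1] + r + 1),
                         zone[2] - r)
      }
      segments[[length(segments) + 1]] <<- list(
        vertices = cbind(x = xs, y = ys, r = rep(r, n + 1)),
        parent = parent, region = region_names[[zone_id]])
      me <- length(segments)
      if (depth < bp$max_depth && stats::runif(1) < bp$prob) {
        at <- sample(2:(n + 1), 1)
        walk(xs[at], ys[at], ang + stats::runif(1, -1, 1),
             max(radius_range_px[1], r * bp$taper), zone, me, depth + 1)
      }
    }
    for (i in seq_len(n_roots)) {
      zone_id <- ((i - 1) %% length(zones)) + 1
      zone <- zones[[zone_id]]
      r <- stats::runif(1, radius_range_px[1], radius_range_px[2])
      x0 <- stats::runif(1, zone[3] + r + 1, zone[4] - r)
      y0 <- stats::runif(1, zone[1] + r + 1, zone[2] - r)
      walk(x0, y0, stats::runif(1, 0, 2 * pi), r, zone, NA_integer_, 0)
    }
    structure(list(segments = segments, image_shape = image_shape),
              class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  regs <- vapply(x$segments, `[[`, "", "region")
  cat(sprintf("<vessel_tree> %d segments in %d x %d frame (%s)\n",
              length(x$segments), x$image_shape[1], x$image_shape[2],
              paste(names(table(regs)), table(regs), sep = ":",
                    collapse = ", ")))
  invisible(x)
}

# perturbed-ellipse tumor blob mask
tumor_blob <- function(image_shape, cx, cy, rx, ry, seed) {
  with_seed(seed, {
    ph <- stats::runif(3, 0, 2 * pi)
    am <- stats::runif(3, 0.03, 0.08)
    nr <- image_shape[1]; nc <- image_shape[2]
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    row <- matrix(seq_len(nr), nr, nc)
    th <- atan2((row - cy) / ry, (col - cx) / rx)
    rad <- sqrt(((col - cx) / rx)^2 + ((row - cy) / ry)^2)
    bound <- 1 + am[1] * sin(2 * th + ph[1]) + am[2] * sin(3 * th + ph[2]) +
      am[3] * sin(5 * th + ph[3])
    (rad <= bound) * 1L
  })
}

#' Assemble a synthetic PAM phantom
#'
#' Couples a vessel tree with two tumor blobs, intensity and noise settings,
#' and a seed. Fully deterministic: rendering the same phantom twice gives
#' identical images.
#'
#' @param tree a [generate_vessel_tree()] result (default: generated from
#'   `seed`).
#' @param image_shape c(rows, cols).
#' @param pixel_size_um lateral pixel size (default 10 um/px, a ~5 mm field
#'   at 512 px).
#' @param seed integer; drives tree, tumor shapes, and noise.
#' @param noise_params list: `sigma` additive Gaussian sd (image units),
#'   `speckle` multiplicative noise factor.
#' @param intensity_params list: `vessel` peak amplitude, `tumor_factor`
#'   (tumor amplitude as a multiple of vessel peak), `background` level.
#' @param gain global vessel/tumor intensity gain (contrast uptake; 1 = none).
#' @param tumor_amp_factors per-tumor amplitude multipliers (treatment state).
#' @return A `vessel_phantom` object.
#' @export
vessel_phantom <- function(tree = NULL, image_shape = c(512, 512),
                           pixel_size_um = 10, seed = 1,
                           noise_params = list(sigma = 0.02, speckle = 0),
                           intensity_params = list(vessel = 1,
                                                   tumor_factor = 1.5,
                                                   background = 0.02),
                           gain = 1, tumor_amp_factors = c(1, 1)) {
  if (is.null(tree)) tree <- generate_vessel_tree(seed, image_shape = image_shape)
  noise_params <- utils::modifyList(list(sigma = 0.02, speckle = 0), noise_params)
  intensity_params <- utils::modifyList(
    list(vessel = 1, tumor_factor = 1.5, background = 0.02), intensity_params)
  zones <- region_zones(image_shape)
  nr <- image_shape[1]; nc <- image_shape[2]
  mk_blob <- function(zone, sd_off) {
    cx <- (zone[3] + zone[4]) / 2
    cy <- (zone[1] + zone[2]) / 2
    tumor_blob(image_shape, cx, cy, 0.11 * nc, 0.09 * nr, seed + sd_off)
  }
  tumor_masks <- list(mk_blob(zones$tumor1, 101L), mk_blob(zones$tumor2, 202L))
  structure(list(tree = tree, tumor_masks = tumor_masks,
                 image_shape = image_shape, pixel_size_um = pixel_size_um,
                 noise_params = noise_params,
                 intensity_params = intensity_params, gain = gain,
                 tumor_amp_factors = tumor_amp_factors, seed = seed),
            class = "vessel_phantom")
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf(
    "<vessel_phantom> %d x %d px, %d segments, gain %.3g, noise sd %.3g\n",
    x$image_shape[1], x$image_shape[2], length(x$tree$segments), x$gain,
    x$noise_params$sigma))
  invisible(x)
}

# densely resample a polyline at ~0.5 px spacing
resample_polyline <- function(v, spacing = 0.5) {
  if (nrow(v) < 2) return(v)
  out <- list()
  for (k in seq_len(nrow(v) - 1)) {
    d <- sqrt(sum((v[k + 1, 1:2] - v[k, 1:2])^2))
    n <- max(2L, ceiling(d / spacing) + 1L)
    t <- seq(0, 1, length.out = n)
    out[[k]] <- cbind(x = v[k, 1] + t * (v[k + 1, 1] - v[k, 1]),
                      y = v[k, 2] + t * (v[k + 1, 2] - v[k, 2]),
                      r = v[k, 3] + t * (v[k + 1, 3] - v[k, 3]))
  }
  do.call(rbind, out)
}

# distance of every pixel to a segment's rasterized centreline, computed far
# from frame borders by padding (margin px) before the distance transform
centerline_distance <- function(cl_mask, margin) {
  nr <- nrow(cl_mask); nc <- ncol(cl_mask)
  inv <- matrix(1L, nr + 2 * margin, nc + 2 * margin)
  inv[margin + (1:nr), margin + (1:nc)] <- 1L - cl_mask
  d <- distance_transform(inv)
  d[margin + (1:nr), margin + (1:nc)]
}

#' Render the MAP image of a phantom, with ground truth
#'
#' Every vessel segment is drawn with a radially decaying Gaussian
#' cross-section of FWHM = 2 * radius (the diffraction-limited OR-PAM
#' appearance of a cylindrical absorber); tumors are bright blobs at
#' `tumor_factor` times the vessel peak; multiplicative speckle and additive
#' Gaussian noise are applied last and the image clamped at zero. The ground
#' truth holds the half-maximum support of the noiseless vessel rendering
#' (pixels within one radius of the centreline), the centreline mask, the
#' radius map, and per-region true metrics.
#'
#' @param phantom a [vessel_phantom()].
#' @return List with `map` (a [map_image]) and `truth` (list: `vessel_mask`,
#'   `centerline_mask`, `radius_map`, `tumor_mask`, `region_metrics`).
#' @export
render_map_image <- function(phantom) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  nr <- phantom$image_shape[1]; nc <- phantom$image_shape[2]
  V <- matrix(0, nr, nc)
  vessel_mask <- matrix(0L, nr, nc)
  centerline <- matrix(0L, nr, nc)
  radius_map <- matrix(0, nr, nc)
  for (seg in phantom$tree$segments) {
    pts <- resample_polyline(seg$vertices)
    ij <- cbind(pmin(pmax(round(pts[, "y"]), 1), nr),
                pmin(pmax(round(pts[, "x"]), 1), nc))
    ij <- ij[!duplicated(ij), , drop = FALSE]
    cl <- matrix(0L, nr, nc)
    cl[ij] <- 1L
    r <- seg$vertices[1, "r"]
    sigma <- 2 * r / (2 * sqrt(2 * log(2)))  # FWHM = 2r
    margin <- ceiling(3.5 * sigma) + 2
    d <- centerline_distance(cl, margin)
    V <- pmax(V, exp(-d^2 / (2 * sigma^2)))
    vessel_mask[d <= r] <- 1L
    centerline[cl == 1L] <- 1L
    radius_map[ij] <- pmax(radius_map[ij], r)
  }
  ip <- phantom$intensity_params
  Tfield <- matrix(0, nr, nc)
  for (t in 1:2) {
    blob <- as.matrix(EBImage::gblur(phantom$tumor_masks[[t]] * 1, sigma = 2))
    Tfield <- pmax(Tfield, phantom$tumor_amp_factors[t] * ip$tumor_factor *
                     ip$vessel * blob)
  }
  img <- ip$background + phantom$gain * pmax(ip$vessel * V, Tfield)
  np <- phantom$noise_params
  if (np$speckle > 0 || np$sigma > 0) {
    noise <- with_seed(phantom$seed + 7L, list(
      mult = matrix(stats::rnorm(nr * nc), nr, nc),
      add = matrix(stats::rnorm(nr * nc), nr, nc)))
    if (np$speckle > 0) img <- img * (1 + np$speckle * noise$mult)
    if (np$sigma > 0) img <- img + np$sigma * noise$add
    img <- pmax(img, 0)
  }
  tumor_mask <- (phantom$tumor_masks[[1]] | phantom$tumor_masks[[2]]) * 1L
  truth <- list(vessel_mask = vessel_mask, centerline_mask = centerline,
                radius_map = radius_map, tumor_mask = tumor_mask,
                region_metrics = region_true_metrics(phantom, vessel_mask,
                                                     centerline, radius_map))
  list(map = map_image(img, pixel_size_um = phantom$pixel_size_um),
       truth = truth)
}

region_true_metrics <- function(phantom, vessel_mask, centerline, radius_map) {
  zones <- region_zones(phantom$image_shape)
  do.call(rbind, lapply(names(zones), function(nm) {
    z <- zones[[nm]]
    ri <- (z[1] + 1):z[2]; ci <- (z[3] + 1):z[4]
    vm <- vessel_mask[ri, ci]; cl <- centerline[ri, ci]
    rm <- radius_map[ri, ci]
    data.frame(region = nm, vd = mean(vm), centerline_density = mean(cl),
               mean_diameter_um = if (sum(cl) > 0)
                 mean(2 * rm[cl == 1]) * phantom$pixel_size_um else 0,
               stringsAsFactors = FALSE)
  }))
}

#' Render an RF volume encoding the phantom in depth
#'
#' Each A-line is an amplitude-modulated cosine carrier: a Gaussian axial
#' envelope whose peak height is the pixel's noiseless MAP value and whose
#' peak position encodes the depth profile. The Hilbert envelope of a
#' rendered A-line recovers the modulation within ~2% away from the record
#' edges, so MAP reconstruction round-trips the rendered image.
#'
#' @param phantom a [vessel_phantom()] (rendered noiseless here; add noise
#'   via the phantom's `noise_params` to the MAP stage instead).
#' @param carrier_freq carrier frequency in cycles/sample, <= 0.5 (Nyquist).
#' @param n_axial number of axial samples.
#' @param dz_um axial sample spacing.
#' @param depth_profile matrix of depths (um) per pixel, or `NULL` for a
#'   smooth default ramp spanning the axial range.
#' @param axial_sigma Gaussian envelope sd in samples.
#' @return An [rf_volume].
#' @export
render_rf_volume <- function(phantom, carrier_freq = 0.25, n_axial = 128,
                             dz_um = 3, depth_profile = NULL,
                             axial_sigma = 5) {
  if (carrier_freq > 0.5)
    stop("`carrier_freq` violates Nyquist (carrier period < 2 samples)")
  ph0 <- phantom
  ph0$noise_params <- list(sigma = 0, speckle = 0)
  A <- unclass(render_map_image(ph0)$map)
  nr <- nrow(A); nc <- ncol(A)
  if (is.null(depth_profile)) {
    zmax <- (n_axial - 1) * dz_um
    depth_profile <- matrix(seq(0.25 * zmax, 0.75 * zmax, length.out = nr),
                            nr, nc)
  }
  k0 <- depth_profile / dz_um
  vol <- array(0, c(nr, nc, n_axial))
  for (k in seq_len(n_axial)) {
    t <- (k - 1) - k0
    vol[, , k] <- A * exp(-t^2 / (2 * axial_sigma^2)) *
      cos(2 * pi * carrier_freq * t)
  }
  rf_volume(vol, dz_um = dz_um, pixel_size_um = phantom$pixel_size_um)
}

#' Specification of one PDT treatment's effect on a phantom
#'
#' @param target_region binary matrix (the irradiated area), or a list
#'   `list(cx, cy, rx, ry)` describing an axis-aligned ellipse in pixels
#'   (the LED spot is elliptical).
#' @param vessel_kill_fraction probability that a vessel segment intersecting
#'   the target region is destroyed, in `[0, 1]`.
#' @param diameter_shrink_factor radius multiplier for surviving in-region
#'   segments (vasoconstriction), in `(0, 1]`.
#' @param tumor_amplitude_factor amplitude multiplier for tumors inside the
#'   target region, in `[0, 1]`.
#' @return A `pdt_effect_spec` list.
#' @export
pdt_effect_spec <- function(target_region, vessel_kill_fraction,
                            diameter_shrink_factor = 1,
                            tumor_amplitude_factor = 1) {
  if (vessel_kill_fraction < 0 || vessel_kill_fraction > 1)
    stop("`vessel_kill_fraction` must be in [0, 1]")
  if (diameter_shrink_factor <= 0 || diameter_shrink_factor > 1)
    stop("`diameter_shrink_factor` must be in (0, 1]")
  if (tumor_amplitude_factor < 0 || tumor_amplitude_factor > 1)
    stop("`tumor_amplitude_factor` must be in [0, 1]")
  structure(list(target_region = target_region,
                 vessel_kill_fraction = vessel_kill_fraction,
                 diameter_shrink_factor = diameter_shrink_factor,
                 tumor_amplitude_factor = tumor_amplitude_factor),
            class = "pdt_effect_spec")
}

rasterize_target <- function(target, image_shape) {
  if (is.matrix(target)) return(target * 1L)
  nr <- image_shape[1]; nc <- image_shape[2]
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr), nr, nc)
  (((col - target$cx) / target$rx)^2 + ((row - target$cy) / target$ry)^2 <= 1) * 1L
}

#' Apply a PDT treatment to a phantom
#'
#' Vessel segments whose centreline intersects the target region are
#' destroyed independently with probability `vessel_kill_fraction` (seeded;
#' the per-segment uniform draws are shared across fractions, so a larger
#' fraction always kills a superset of segments). Descendants of a destroyed
#' segment are removed with it (downstream perfusion loss). Surviving
#' in-region segments have their radii scaled by `diameter_shrink_factor`;
#' tumors inside the region have their amplitude scaled. Segments fully
#' outside the region are untouched, so at zero noise the rest of the image
#' is bit-identical.
#'
#' @param phantom a [vessel_phantom()].
#' @param spec a [pdt_effect_spec()].
#' @param seed integer seed for the kill draws.
#' @return The treated `vessel_phantom`.
#' @export
apply_pdt_effect <- function(phantom, spec, seed) {
  stopifnot(inherits(spec, "pdt_effect_spec"))
  target <- rasterize_target(spec$target_region, phantom$image_shape)
  nr <- phantom$image_shape[1]; nc <- phantom$image_shape[2]
  segs <- phantom$tree$segments
  in_region <- vapply(segs, function(seg) {
    pts <- resample_polyline(seg$vertices)
    ij <- cbind(pmin(pmax(round(pts[, "y"]), 1), nr),
                pmin(pmax(round(pts[, "x"]), 1), nc))
    any(target[ij] == 1L)
  }, logical(1))
  u <- with_seed(seed, stats::runif(length(segs)))
  killed <- in_region & (u < spec$vessel_kill_fraction)
  # propagate to descendants
  repeat {
    parents <- vapply(segs, function(s) s$parent %||% NA_integer_, integer(1))
    more <- !killed & !is.na(parents) & killed[pmax(parents, 1L)] &
      parents >= 1L
    if (!any(more)) break
    killed <- killed | more
  }
  keep <- which(!killed)
  remap <- match(seq_along(segs), keep)
  new_segs <- lapply(keep, function(i) {
    s <- segs[[i]]
    if (in_region[i]) s$vertices[, "r"] <- s$vertices[, "r"] *
        spec$diameter_shrink_factor
    p <- s$parent
    s$parent <- if (is.na(p) || is.na(remap[p])) NA_integer_ else remap[p]
    s
  })
  out <- phantom
  out$tree$segments <- new_segs
  for (t in 1:2) {
    if (any(phantom$tumor_masks[[t]] & target))
      out$tumor_amp_factors[t] <- out$tumor_amp_factors[t] *
        spec$tumor_amplitude_factor
  }
  out
}

#' Deterministic binary test patterns
#'
#' Exact fixtures for the metric oracles: `line` (1-px centre row), `bar`
#' (params `width`, `length`), `disk` (`radius`), `ring` (`outer`, `inner`),
#' `filled_square` (`side`), `sierpinski` (`depth`; side `3^depth` with
#' `8^depth` foreground cells, ignoring `size`).
#'
#' @param kind pattern name.
#' @param size canvas side (square), or c(rows, cols).
#' @param params pattern parameters, see above.
#' @return Integer 0/1 matrix.
#' @export
make_fixture <- function(kind, size = 64, params = list()) {
  if (length(size) == 1) size <- c(size, size)
  nr <- size[1]; nc <- size[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  row <- matrix(seq_len(nr), nr, nc)
  m <- switch(kind,
    line = {
      z <- matrix(0L, nr, nc); z[round(cy), ] <- 1L; z
    },
    bar = {
      w <- params$width %||% 9; l <- params$length %||% nc
      z <- matrix(0L, nr, nc)
      r0 <- round(cy - w / 2 + 0.5); c0 <- round(cx - l / 2 + 0.5)
      z[r0:(r0 + w - 1), c0:(c0 + l - 1)] <- 1L
      z
    },
    disk = {
      r <- params$radius %||% 10
      ((row - cy)^2 + (col - cx)^2 <= r^2) * 1L
    },
    ring = {
      ro <- params$outer %||% 15; ri <- params$inner %||% 8
      d2 <- (row - cy)^2 + (col - cx)^2
      (d2 <= ro^2 & d2 > ri^2) * 1L
    },
    filled_square = {
      s <- params$side %||% min(nr, nc)
      z <- matrix(0L, nr, nc)
      r0 <- round(cy - s / 2 + 0.5); c0 <- round(cx - s / 2 + 0.5)
      z[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- 1L
      z
    },
    sierpinski = {
      d <- params$depth %||% 3
      m <- matrix(1L, 1, 1)
      for (k in seq_len(d)) {
        n <- nrow(m)
        big <- matrix(0L, 3 * n, 3 * n)
        for (bi in 0:2) for (bj in 0:2) {
          if (bi == 1 && bj == 1) next
          big[bi * n + (1:n), bj * n + (1:n)] <- m
        }
        m <- big
      }
      m
    },
    stop(sprintf("unknown fixture kind '%s'", kind))
  )
  m
}
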