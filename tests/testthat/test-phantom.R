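`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("phantom rendering is a pure function of seed and parameters", {
  a <- render_map_image(vessel_phantom(image_shape = c(96, 96), seed = 5))
  b <- render_map_image(vessel_phantom(image_shape = c(96, 96), seed = 5))
  expect_identical(unclass(a$map), unclass(b$map))
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  c_ <- render_map_image(vessel_phantom(image_shape = c(96, 96), seed = 6))
  expect_false(identical(unclass(a$map), unclass(c_$map)))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(vessel_phantom(image_shape = c(96, 96), seed = 5))
  expect_identical(runif(3), before)
})

test_that("vessel trees cover all four regions and stay inside their zones", {
  tree <- generate_vessel_tree(2, image_shape = c(128, 128))
  regs <- vapply(tree$segments, `[[`, "", "region")
  expect_setequal(unique(regs),
                  c("control", "normal_near_tumor", "tumor1", "tumor2"))
  zones <- list(control = c(0, 57, 0, 57),
                normal_near_tumor = c(0, 57, 71, 128),
                tumor1 = c(71, 128, 0, 57),
                tumor2 = c(71, 128, 71, 128))
  for (seg in tree$segments) {
    z <- zones[[seg$region]]
    expect_true(all(seg$vertices[, "y"] >= z[1] & seg$vertices[, "y"] <= z[2]))
    expect_true(all(seg$vertices[, "x"] >= z[3] & seg$vertices[, "x"] <= z[4]))
  }
  expect_error(generate_vessel_tree(1, image_shape = c(32, 32)), "64")
  expect_error(generate_vessel_tree(1, radius_range_px = c(0.5, 2)), ">= 1")
})

test_that("ground truth is geometrically consistent with the rendering", {
  ph <- tube_phantom(4, shape = c(96, 96), sigma = 0)
  out <- render_map_image(ph)
  tr <- out$truth
  # centreline lies inside the vessel mask; radius map is set on it
  expect_true(all(tr$vessel_mask[tr$centerline_mask == 1L] == 1L))
  expect_true(all(tr$radius_map[tr$centerline_mask == 1L] == 4))
  # the noiseless image peaks at vessel + background on the centreline
  img <- unclass(out$map)
  expect_equal(max(img), 0.02 + 1, tolerance = 1e-6)
  # mask width equals the half-max support 2r + 1
  expect_true(all(colSums(tr$vessel_mask[, 40:56]) == 9))
  # region metrics table covers the four regions
  expect_setequal(tr$region_metrics$region,
                  c("control", "normal_near_tumor", "tumor1", "tumor2"))
  expect_true(all(tr$region_metrics$vd >= 0 & tr$region_metrics$vd <= 1))
})

test_that("tumor blobs render at tumor_factor times the vessel peak", {
  ph <- vessel_phantom(image_shape = c(128, 128), seed = 9,
                       noise_params = list(sigma = 0))
  out <- render_map_image(ph)
  img <- unclass(out$map)
  # deep inside tumor 1 (zone centre) the intensity is bg + 1.5 * vessel,
  # unless a brighter vessel crosses it; never above bg + tumor_factor
  t1 <- ph$tumor_masks[[1]]
  interior <- EBImage::erode(t1, EBImage::makeBrush(15, "disc")) > 0
  expect_gte(max(img[interior]), 0.02 + 1.5 - 1e-6)
  expect_lte(max(img), 0.02 + 1.5 + 1e-6)
})

test_that("apply_pdt_effect kills nested segment sets and spares the rest", {
  ph <- vessel_phantom(image_shape = c(128, 128), seed = 12)
  zones <- list(tumor1 = c(71, 128, 0, 57))
  target <- list(cx = 28, cy = 99, rx = 36, ry = 27)
  ids <- function(p) vapply(p$tree$segments, function(s)
    paste(s$region, s$vertices[1, "x"], s$vertices[1, "y"]), "")
  survivors <- lapply(c(0.3, 0.6, 0.9), function(kf) {
    sp <- pdt_effect_spec(target, kf, 0.8, 0.1)
    ids(apply_pdt_effect(ph, sp, seed = 77))
  })
  # larger kill fractions kill supersets: survivor sets are nested
  expect_true(all(survivors[[2]] %in% survivors[[1]]))
  expect_true(all(survivors[[3]] %in% survivors[[2]]))
  # non-tumor1 segments are never touched
  sp <- pdt_effect_spec(target, 1, 0.5, 0.1)
  treated <- apply_pdt_effect(ph, sp, seed = 77)
  regs <- vapply(treated$tree$segments, `[[`, "", "region")
  before <- vapply(ph$tree$segments, `[[`, "", "region")
  expect_equal(sum(regs == "control"), sum(before == "control"))
  untouched <- Filter(function(s) s$region == "control", treated$tree$segments)
  orig <- Filter(function(s) s$region == "control", ph$tree$segments)
  expect_identical(lapply(untouched, `[[`, "vertices"),
                   lapply(orig, `[[`, "vertices"))
  # tumor-1 amplitude factor is applied, tumor 2 untouched
  expect_equal(treated$tumor_amp_factors, c(0.1, 1))
  # kill fraction 1 removes every tumor1 segment inside the full-zone target
  full_target <- matrix(0L, 128, 128); full_target[72:128, 1:57] <- 1L
  gone <- apply_pdt_effect(ph, pdt_effect_spec(full_target, 1), seed = 1)
  expect_equal(sum(vapply(gone$tree$segments, `[[`, "", "region") == "tumor1"), 0L)
  expect_error(pdt_effect_spec(target, 1.2), "\\[0, 1\\]")
  expect_error(pdt_effect_spec(target, 0.5, 0), "\\(0, 1\\]")
})

test_that("descendants of a killed segment are removed with it", {
  # force branching so some segment has a child
  tree <- generate_vessel_tree(4, n_roots = 8, image_shape = c(128, 128),
                               branching_params = list(prob = 1, max_depth = 2))
  parents <- vapply(tree$segments, function(s) s$parent %||% NA_integer_,
                    integer(1))
  expect_true(any(!is.na(parents)))  # the scenario has children at all
  ph <- vessel_phantom(tree = tree, image_shape = c(128, 128), seed = 4)
  full <- matrix(1L, 128, 128)
  gone <- apply_pdt_effect(ph, pdt_effect_spec(full, 1), seed = 2)
  expect_equal(length(gone$tree$segments), 0L)
  # surviving trees keep valid parent indices
  half <- apply_pdt_effect(ph, pdt_effect_spec(full, 0.5), seed = 2)
  ps <- vapply(half$tree$segments, function(s) s$parent %||% NA_integer_,
               integer(1))
  expect_true(all(is.na(ps) | (ps >= 1 & ps <= length(half$tree$segments))))
})

test_that("render_rf_volume encodes depth and respects Nyquist", {
  ph <- tube_phantom(3, shape = c(32, 32), sigma = 0)
  expect_error(render_rf_volume(ph, carrier_freq = 0.6), "Nyquist")
  depth <- matrix(120, 32, 32)
  vol <- render_rf_volume(ph, n_axial = 96, dz_um = 3, depth_profile = depth)
  expect_s3_class(vol, "rf_volume")
  expect_equal(dim(vol$samples), c(32, 32, 96))
  d <- compute_depth_map(vol, noise_floor = 0.05)
  expect_equal(stats::median(d[!is.na(d)]), 120, tolerance = 3)
})

test_that("make_fixture produces the documented exact patterns", {
  s <- make_fixture("sierpinski", params = list(depth = 3))
  expect_equal(dim(s), c(27, 27))
  expect_equal(sum(s), 8^3)
  b <- make_fixture("bar", size = 32, params = list(width = 5, length = 20))
  expect_equal(sum(b), 100)
  expect_equal(range(colSums(b)[colSums(b) > 0]), c(5, 5))
  l <- make_fixture("line", size = 16)
  expect_equal(sum(l), 16)
  expect_error(make_fixture("nope"), "unknown fixture")
})
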