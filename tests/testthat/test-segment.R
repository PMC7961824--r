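test_that("vesselness peaks on a bright ridge and vanishes on flat images", {
  img <- matrix(0.02, 64, 64)
  for (i in 1:64) for (j in 1:64)
    img[i, j] <- img[i, j] + exp(-((i - 32)^2) / (2 * 2^2))
  v <- vesselness_multiscale(img, scales_px = c(1, 2, 3))
  expect_true(all(v >= 0 & v <= 1))
  # response is maximal on the ridge centreline, interior columns
  expect_true(all(apply(v[, 10:54], 2, which.max) == 32))
  # flat image: zero response everywhere
  expect_true(all(vesselness_multiscale(matrix(1, 32, 32)) == 0))
  expect_error(vesselness_multiscale(img, scales_px = numeric(0)), "nonempty")
  expect_error(vesselness_multiscale(img, scales_px = 0.5), ">= 1")
})

test_that("adaptive_threshold matches the brute local-mean oracle", {
  set.seed(21)
  x <- matrix(runif(16 * 14), 16, 14)
  for (block in c(3, 5)) {
    got <- adaptive_threshold(x, block_size = block, offset = 0.02)
    want <- (x > brute_local_mean(x, block) + 0.02) * 1L
    storage.mode(want) <- "integer"
    expect_identical(got, want)
  }
  # strict comparison: a constant image yields an empty mask at zero offset
  expect_true(all(adaptive_threshold(matrix(0.7, 10, 10), 3, 0) == 0L))
  expect_error(adaptive_threshold(x, block_size = 4), "odd")
})

test_that("clean_mask removes specks and fills interior holes only", {
  m <- matrix(0L, 20, 20)
  m[5:15, 5:15] <- 1L   # 121-px object
  m[8, 8] <- 0L         # 1-px interior hole
  m[2, 2] <- 1L         # 1-px speck
  m[1, 10:12] <- 1L     # 3-px speck touching the border
  out <- clean_mask(m, min_object_px = 5, fill_hole_px = 4)
  expect_equal(out[2, 2], 0L)
  expect_equal(sum(out[1, ]), 0L)
  expect_equal(out[8, 8], 1L)
  expect_equal(sum(out), 121L)
  # border-touching background is never treated as a hole
  m2 <- matrix(1L, 10, 10); m2[1:3, 5] <- 0L
  expect_equal(sum(clean_mask(m2, 0, 50) == 0L), 3L)
  expect_error(clean_mask(m, min_object_px = -1), ">= 0")
})

test_that("skeletonize thins to one-pixel paths and preserves topology", {
  bar <- make_fixture("bar", size = 64, params = list(width = 9, length = 50))
  sk <- skeletonize(bar)
  expect_true(all(sk[bar == 0L] == 0L))       # subset of the mask
  expect_equal(count_components(sk, 8), 1L)   # connectivity preserved
  # no fully set 2x2 block -> truly one pixel wide
  expect_true(all(sk[1:63, 1:63] + sk[2:64, 1:63] +
                  sk[1:63, 2:64] + sk[2:64, 2:64] < 4L))
  # a simple path: exactly two endpoints, everything else 2 neighbours
  nb <- neighbour_counts(sk)
  expect_equal(sum(nb[sk == 1L] == 1L), 2L)
  expect_true(all(nb[sk == 1L] %in% c(1L, 2L)))
  # path length: thinning erodes up to ~width/2 from each free end
  expect_gte(sum(sk), 50 - 9)
  expect_lte(sum(sk), 50 + 2)
  # two disjoint bars stay two components
  two <- matrix(0L, 40, 40)
  two[5:9, 5:35] <- 1L; two[25:29, 5:35] <- 1L
  expect_equal(count_components(skeletonize(two), 8), 2L)
  # a ring keeps its cycle: one component, no endpoints
  ring <- make_fixture("ring", size = 41, params = list(outer = 15, inner = 8))
  skr <- skeletonize(ring)
  expect_equal(count_components(skr, 8), 1L)
  expect_true(all(neighbour_counts(skr)[skr == 1L] >= 2L))
})

test_that("distance_transform matches brute force and the border-ring convention", {
  set.seed(31)
  for (k in 1:5) {
    m <- random_mask(20, 17, p = 0.5)
    expect_equal(distance_transform(m), brute_edt(m), tolerance = 1e-9)
  }
  # all-ones mask: distances come from the virtual background ring
  ones <- matrix(1L, 9, 9)
  d <- distance_transform(ones)
  expect_equal(d[5, 5], 5)
  expect_equal(d[1, 1], 1)
  expect_true(all(distance_transform(matrix(0L, 6, 6)) == 0))
})

test_that("refine_mask_halfmax restores the half-maximum width of a tube", {
  r <- 4
  ph <- tube_phantom(r, shape = c(96, 96), sigma = 0)
  img <- render_map_image(ph)$map
  v <- vesselness_multiscale(img)
  det <- adaptive_threshold(v)
  ref <- refine_mask_halfmax(img, det)
  # half-max support of a FWHM = 2r Gaussian tube is 2r + 1 px wide
  widths <- colSums(ref[, 40:56])
  expect_true(all(widths == 2 * r + 1))
  # empty detections pass through untouched
  empty <- matrix(0L, 96, 96)
  expect_identical(refine_mask_halfmax(img, empty), empty)
})

test_that("the noise significance floor rejects structure-free images", {
  set.seed(41)
  img <- matrix(pmax(0.02 + rnorm(96 * 96, 0, 0.02), 0), 96, 96)
  seg <- segment_vessels(denoise_median(map_image(img), 3))
  expect_equal(sum(seg$mask), 0L)
  expect_equal(sum(seg$skeleton), 0L)
})

test_that("segment_vessels returns a consistent set of products", {
  ph <- tube_phantom(3, shape = c(96, 96))
  img <- denoise_median(render_map_image(ph)$map, 3)
  seg <- segment_vessels(img)
  expect_named(seg, c("vesselness", "mask", "skeleton", "distance"))
  expect_identical(dim(seg$mask), dim(unclass(img)))
  expect_true(all(seg$skeleton[seg$mask == 0L] == 0L))
  expect_true(all(seg$distance[seg$mask == 0L] == 0))
  expect_true(all(seg$distance[seg$mask == 1L] > 0))
  expect_gt(sum(seg$mask), 0)
})
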