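test_that("extract_roi uses 0-based half-open coordinates and names errors", {
  x <- matrix(1:30, 5, 6)
  roi <- roi_spec("R1", x0 = 1, y0 = 2, width = 3, height = 2)
  expect_equal(extract_roi(x, roi), x[3:4, 2:4])
  img <- map_image(matrix(runif(30), 5, 6), pixel_size_um = 7)
  out <- extract_roi(img, roi)
  expect_s3_class(out, "map_image")
  expect_equal(attr(out, "pixel_size_um"), 7)
  expect_error(extract_roi(x, roi_spec("far", 4, 0, 5, 2)), "far")
  expect_error(extract_roi(x, roi_spec("deep", 0, 4, 2, 5)), "deep")
  expect_error(roi_spec("bad", 0, 0, 0, 5), "positive extent")
})

test_that("percent_change is signed, vectorised and NA-safe", {
  expect_equal(percent_change(110, 100), 10)
  expect_equal(percent_change(80, 100), -20)
  expect_equal(percent_change(c(1, 2), c(2, 2)), c(-50, 0))
  expect_true(is.na(percent_change(5, 0)))
})

test_that("run_timecourse leaves ROIs disjoint from a treatment unchanged", {
  ph <- vessel_phantom(image_shape = c(128, 128), seed = 14,
                       noise_params = list(sigma = 0))
  target <- matrix(0L, 128, 128); target[72:128, 1:57] <- 1L  # tumor1 zone
  treated <- apply_pdt_effect(ph, pdt_effect_spec(target, 1, 0.8, 0), seed = 3)
  imgs <- list(pre_injection = render_map_image(ph)$map,
               post_PDT1 = render_map_image(treated)$map)
  rois <- list(roi_spec("A_control", 2, 2, 53, 53),
               roi_spec("C_melanoma1", 2, 73, 53, 53))
  tc <- run_timecourse(imgs, rois)
  tab <- tc$table
  ctrl <- tab[tab$roi == "A_control", ]
  expect_true(all(ctrl$percent_change == 0))
  # the treated ROI lost vessels
  vdC <- tab[tab$roi == "C_melanoma1" & tab$metric == "vd", ]
  expect_lt(vdC$percent_change[vdC$timepoint == "post_PDT1"], 0)
})

test_that("run_timecourse produces a complete, well-formed long table", {
  sim <- simulate_pdt_series(seed = 3, image_shape = c(128, 128))
  tc <- run_timecourse(sim$images, sim$rois)
  tab <- tc$table
  expect_equal(nrow(tab), 4 * 4 * 5)
  expect_setequal(unique(tab$metric), c("pa_signal", "vdi_um", "vd", "pvd", "vc"))
  expect_setequal(unique(tab$timepoint), timepoint_levels())
  # control_value column repeats each ROI/metric's pre-injection value
  pre <- tab[tab$timepoint == "pre_injection", ]
  expect_true(all(pre$value == pre$control_value))
  expect_true(all(pre$percent_change == 0))
  expect_error(run_timecourse(sim$images[1], sim$rois), "at least 2")
  bad <- sim$images[1:2]; names(bad) <- c("pre_injection", "whenever")
  expect_error(run_timecourse(bad, sim$rois), "timepoint labels")
})

test_that("summarize_mean_across_rois averages percent changes", {
  sim <- simulate_pdt_series(seed = 3, image_shape = c(128, 128))
  tc <- run_timecourse(sim$images, sim$rois)
  tab <- tc$table
  want <- mean(tab$percent_change[tab$metric == "vd" &
                                  tab$timepoint == "post_PDT1"])
  expect_equal(summarize_mean_across_rois(tc, "vd", "post_PDT1"), want)
  expect_error(summarize_mean_across_rois(tc, "vd", "post_PDT9"), "not present")
})

test_that("timecourse CSV output is byte-deterministic and faithful", {
  sim <- simulate_pdt_series(seed = 8, image_shape = c(128, 128))
  tc <- run_timecourse(sim$images[1:2], sim$rois)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f1)
  write_timecourse_csv(tc, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- utils::read.csv(f1)
  expect_equal(nrow(back), nrow(tc$table))
  expect_equal(back$value, tc$table$value, tolerance = 1e-12)
})

test_that("plot_timecourse writes a PNG", {
  sim <- simulate_pdt_series(seed = 8, image_shape = c(128, 128))
  tc <- run_timecourse(sim$images[1:2], sim$rois)
  f <- tempfile(fileext = ".png")
  plot_timecourse(tc, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("simulate_pdt_series is deterministic and correctly staged", {
  a <- simulate_pdt_series(seed = 5, image_shape = c(128, 128))
  b <- simulate_pdt_series(seed = 5, image_shape = c(128, 128))
  expect_identical(lapply(a$images, unclass), lapply(b$images, unclass))
  expect_named(a$images, timepoint_levels())
  expect_equal(vapply(a$rois, `[[`, "", "name"),
               c("A_control", "B_normal", "C_melanoma1", "D_melanoma2"))
  # post-RB differs from pre only by the gain (and the shared noise field):
  # same vessel tree, brighter vessels
  expect_equal(a$phantoms$post_RB$gain, 1.07)
  expect_identical(a$phantoms$post_RB$tree, a$phantoms$pre_injection$tree)
  # the first PDT removes tumor-1 amplitude, the second tumor-2
  expect_lt(a$phantoms$post_PDT1$tumor_amp_factors[1], 1)
  expect_equal(a$phantoms$post_PDT1$tumor_amp_factors[2], 1)
  expect_lt(a$phantoms$post_PDT2$tumor_amp_factors[2], 1)
})
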