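test_that("crop geometry matches the page layout", {
  scan <- generate_ecg_scan(list(), seed = 6)
  all12 <- crop_view(scan, ecg_crop_params("all12"))
  expect_equal(dim(all12), c(1840L, 1840L))
  limb <- ecg_crop_params("limb")
  prec <- ecg_crop_params("precordial")
  expect_equal(dim(crop_view(scan, limb)), c(960L, 960L))
  # limb crop sits in the upper half, precordial anchored to the bottom edge
  px <- scan$pixels
  expect_identical(crop_view(px, limb), px[1:960, 1:960])
  expect_identical(crop_view(px, prec), px[881:1840, 1:960])
  # uniform white page stays uniform
  white <- matrix(255L, 1840, 3187)
  expect_true(all(crop_view(white, limb) == 255L))
  expect_error(crop_view(px, ecg_crop_params("all12"), origin = 3000),
               "exceeds page width")
})

test_that("crops equal brute-force array slices at every shift anchor", {
  set.seed(10)
  page <- matrix(sample(0:255, 120 * 400, replace = TRUE), 120, 400)
  p <- ecg_crop_params("limb", crop_side = 60L, resize_to = 60L,
                       shift_offset = 17L,
                       shift_counts = c(none = 5L, mild = 5L, moderate = 5L,
                                        severe = 7L))
  crops <- shift_augment(page, p, "none")
  expect_length(crops, 5L)
  for (i in seq_along(crops)) {
    anchor <- (i - 1L) * 17L
    expect_equal(unname(crops[[i]]),
                 page[1:60, (anchor + 1):(anchor + 60)],
                 ignore_attr = TRUE)
  }
})

test_that("bilinear resize hits the stated output sizes and fixed points", {
  expect_equal(dim(resize_view(matrix(0, 1840, 1840), 512)), c(512L, 512L))
  expect_equal(dim(resize_view(matrix(0, 960, 960), 256)), c(256L, 256L))
  u <- matrix(137, 300, 300)
  expect_true(all(abs(resize_view(u, 77) - 137) < 1e-9))
  # idempotent on an already-target-sized image
  expect_equal(resize_view(u, 300), u * 1)
  expect_error(resize_view(matrix(0, 10, 20), 5), "square")
  # intensity range preserved within rounding
  set.seed(1)
  img <- matrix(runif(100 * 100, 0, 255), 100, 100)
  out <- resize_view(img, 31)
  expect_true(min(out) >= min(img) - 1e-9 && max(out) <= max(img) + 1e-9)
})

test_that("shift augmentation yields the per-grade counts, 42 for severe LVD", {
  scan <- generate_ecg_scan(list(LVD = "severe"), seed = 12)
  p <- ecg_crop_params("all12", disease = "LVD")
  crops <- shift_augment(scan, p, "severe")
  expect_length(crops, 42L)
  expect_true(all(vapply(crops, function(m) all(dim(m) == c(512L, 512L)),
                         logical(1))))
  expect_length(shift_augment(scan, p, "none"), 3L)
  # zero offset duplicates the anchor crop
  p0 <- ecg_crop_params("all12", shift_offset = 0L)
  crops0 <- shift_augment(scan, p0, "none")
  expect_identical(crops0[[1]][], crops0[[3]][])
})

test_that("infeasible shift counts are rejected with the maximal feasible count", {
  scan_px <- matrix(255L, 1840, 3187)
  # offset 30 on the 12-lead view: floor((3187-1840)/30)+1 = 45 crops fit
  p <- ecg_crop_params("all12", shift_offset = 30L,
                       shift_counts = c(none = 3L, mild = 3L, moderate = 3L,
                                        severe = 46L))
  expect_error(shift_augment(scan_px, p, "severe"), "45")
  p45 <- ecg_crop_params("all12", shift_offset = 30L,
                         shift_counts = c(none = 3L, mild = 3L, moderate = 3L,
                                          severe = 45L))
  expect_length(shift_augment(scan_px, p45, "severe"), 45L)
  # default offsets keep the largest factor (x44) on the page
  expect_length(shift_augment(scan_px, ecg_crop_params("all12", "MR"),
                              "severe"), 44L)
  expect_length(shift_augment(scan_px, ecg_crop_params("limb", "MR"),
                              "severe"), 44L)
})
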