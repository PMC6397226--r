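geom9 <- pattern_geometry()  # 3 x 3 dot grid

test_that("dot detection finds a 3x3 grid within a pixel of ground truth", {
  img <- simulate_image_series(frap_ground_truth(noise_sd = 0), geom9,
                               seed = 21)
  det <- detect_dots(img$prebleach, geom9)
  expect_equal(nrow(det), 9)
  err <- vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((img$centers$row - det$row[i])^2 +
               (img$centers$col - det$col[i])^2))
  }, numeric(1))
  expect_true(all(err < 1))
  # and under realistic noise
  imgn <- simulate_image_series(frap_ground_truth(), geom9, seed = 22)
  detn <- detect_dots(imgn$prebleach, geom9)
  expect_equal(nrow(detn), 9)
})

test_that("uniform images yield no dots, dim dots fall below threshold", {
  u <- matrix(100, geom9$height, geom9$width)
  expect_warning(det <- detect_dots(u, geom9), "no dots")
  expect_equal(nrow(det), 0)
  # two dots, one with contrast too low to clear the detection threshold
  gt2 <- frap_ground_truth(noise_sd = 0, contrast = c(0.6, 0.05))
  geom2 <- pattern_geometry(n_dots_x = 2, n_dots_y = 1)
  img2 <- simulate_image_series(gt2, geom2, seed = 23)
  det2 <- detect_dots(img2$prebleach, geom2)
  expect_equal(nrow(det2), 1)
})

test_that("ON rectangles are 7x7 px for 1 um dots at 0.1 um pixels", {
  # oracle geometry: largest square inscribed in a 10 px disk has side 7
  img <- simulate_image_series(frap_ground_truth(noise_sd = 0), geom9,
                               seed = 21)
  rois <- build_masks(img$centers, geom9, dim(img$prebleach))
  expect_length(rois, 9)
  expect_true(all(vapply(rois, function(r) length(r$on_idx), numeric(1)) == 49))
  # ON and OFF regions are disjoint, OFF has at least as many pixels
  for (r in rois) {
    expect_length(intersect(r$on_idx, r$off_idx), 0)
    expect_gte(length(r$off_idx), length(r$on_idx))
  }
})

test_that("annuli of adjacent dots do not overlap any ON rectangle", {
  img <- simulate_image_series(frap_ground_truth(noise_sd = 0), geom9,
                               seed = 21)
  rois <- build_masks(img$centers, geom9, dim(img$prebleach))
  all_on <- unlist(lapply(rois, function(r) r$on_idx))
  for (r in rois) expect_length(intersect(r$off_idx, all_on), 0)
})

test_that("dots too close to the image edge are skipped", {
  img <- simulate_image_series(frap_ground_truth(noise_sd = 0), geom9,
                               seed = 21)
  centers <- rbind(img$centers,
                   data.frame(dot = 10, row = 2, col = 2))
  expect_message(rois <- build_masks(centers, geom9, dim(img$prebleach)),
                 "skipped 1")
  expect_length(rois, 9)
})

test_that("contrast follows its definition and gates inclusion", {
  expect_equal(dot_contrast(1.0, 0.5), 0.5)
  expect_equal(dot_contrast(1.0, 1.0), 0)
  expect_equal(dot_contrast(1.0, 0.7), 0.3)
  expect_error(dot_contrast(0, 0.5), "F_ON")
  mk <- function(con) {
    structure(list(dot = 1L, row = 1, col = 1, on_idx = 1L, off_idx = 2L,
                   contrast = con), class = "dot_roi")
  }
  rois <- lapply(c(0.5, 0.39, 0.41), mk)
  expect_length(suppressMessages(filter_dots(rois)), 2)
  expect_length(suppressMessages(filter_dots(rois, min_contrast = 0)), 3)
  expect_warning(suppressMessages(kept <- filter_dots(list(mk(0.3)))),
                 "below")
  expect_length(kept, 0)
  # a 0.3-contrast dot is excluded at the default 0.4 threshold
  expect_warning(
    kept2 <- suppressMessages(filter_dots(list(mk(dot_contrast(1, 0.7))))),
    "below")
  expect_length(kept2, 0)
})

test_that("measured contrast matches construction within pixelation", {
  for (con in c(0.4, 0.5, 0.6)) {
    gt <- frap_ground_truth(noise_sd = 0, contrast = con)
    img <- simulate_image_series(gt, geom9, seed = 24)
    h <- nrow(img$prebleach)
    bg_idx <- which(matrix(seq_len(h), h, ncol(img$prebleach)) <=
                      geom9$background_px)
    rois <- build_masks(img$centers, geom9, dim(img$prebleach))
    rois <- measure_contrast(rois, img$prebleach, bg_idx)
    cons <- vapply(rois, function(r) r$contrast, numeric(1))
    expect_true(all(abs(cons - con) < 0.05))
  }
})
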