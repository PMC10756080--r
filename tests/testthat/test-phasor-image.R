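# Phasor-space denoising, histograms, pseudocolor rendering, cursors and
# reciprocity.

test_that("median filtering leaves constant regions in place and removes outliers", {
  G <- matrix(0.4, 5, 5)
  S <- matrix(0.2, 5, 5)
  f <- field_from_gs(G, S)
  expect_equal(median_filter_phasor(f, 3)$G, G)
  expect_equal(median_filter_phasor(f, 3, repeats = 3)$S, S)
  G2 <- G
  G2[3, 3] <- 0.9 # single outlier
  f2 <- median_filter_phasor(field_from_gs(G2, S), 3)
  expect_equal(f2$G, G)
  expect_error(median_filter_phasor(f, kernel = 4), "odd")
  expect_error(median_filter_phasor(f, kernel = 1), "odd")
})

test_that("median filtering shrinks the phasor scatter of a noisy material", {
  ph <- two_material_phantom(noise = TRUE, seed = 21, mean_counts = 300)
  f <- phasor_transform(ph$stack, intensity_threshold = 50)
  filt <- median_filter_phasor(f, 3)
  left <- ph$labels == "left"
  sd_raw <- stats::sd(f$G[left]) + stats::sd(f$S[left])
  sd_filt <- stats::sd(filt$G[left]) + stats::sd(filt$S[left])
  expect_lt(sd_filt, sd_raw)
  expect_identical(filt$valid_mask, f$valid_mask)
  expect_identical(filt$total_intensity, f$total_intensity)
})

test_that("phasor histograms count valid pixels on the [-1,1]^2 grid", {
  f <- field_from_gs(matrix(0.25, 6, 6), matrix(0.5, 6, 6))
  h <- phasor_histogram(f, bins = 64)
  expect_equal(sum(h$counts), 36)
  expect_equal(sum(h$counts > 0), 1L) # all pixels in one bin
  # empty valid mask
  f0 <- field_from_gs(matrix(NA_real_, 3, 3), matrix(NA_real_, 3, 3))
  expect_equal(sum(phasor_histogram(f0, bins = 32)$counts), 0)
})

test_that("two-material histogram modes sit at the ground-truth phasors", {
  ph <- two_material_phantom(noise = TRUE, seed = 5)
  f <- phasor_transform(ph$stack, intensity_threshold = 100)
  h <- phasor_histogram(f, bins = 64)
  bw <- diff(h$breaks[1:2])
  # the two strongest bins, one per material
  ord <- order(h$counts, decreasing = TRUE)
  modes <- arrayInd(ord[1:2], dim(h$counts))
  got <- cbind(h$mids[modes[, 1]], h$mids[modes[, 2]])
  for (i in 1:2) {
    tr <- ph$truth[i, ]
    d <- sqrt((got[, 1] - tr$G)^2 + (got[, 2] - tr$S)^2)
    expect_lt(min(d), bw * sqrt(2) + 1e-12) # within one bin width
  }
})

test_that("pseudocolor phase maps clamp to the configured range and blank invalid pixels", {
  lo <- 45; hi <- 180
  phases <- c(112.5, 45, 180, 10, 350, NA) # mid, endpoints, clamped, invalid
  G <- matrix(cospi(phases / 180) * 0.8, 2, 3)
  S <- matrix(sinpi(phases / 180) * 0.8, 2, 3)
  img <- pseudocolor_phase(field_from_gs(G, S), phase_range = c(lo, hi))
  mid_col <- as.vector(grDevices::col2rgb(grDevices::hsv(0.375, 1, 1)) / 255)
  lo_col <- as.vector(grDevices::col2rgb(grDevices::hsv(0, 1, 1)) / 255)
  hi_col <- as.vector(grDevices::col2rgb(grDevices::hsv(0.75, 1, 1)) / 255)
  expect_equal(as.vector(img[1, 1, ]), mid_col, tolerance = 1e-6)
  expect_equal(as.vector(img[2, 1, ]), lo_col, tolerance = 1e-6)
  expect_equal(as.vector(img[1, 2, ]), hi_col, tolerance = 1e-6)
  expect_equal(as.vector(img[2, 2, ]), lo_col, tolerance = 1e-6) # clamped low
  expect_equal(as.vector(img[1, 3, ]), hi_col, tolerance = 1e-6) # clamped high
  expect_equal(as.vector(img[2, 3, ]), c(0, 0, 0)) # invalid -> black
  expect_error(pseudocolor_phase(field_from_gs(G, S), c(90, 90)), "lo < hi")
})

test_that("red-shifted material renders at the violet end; hue classification matches labels", {
  ph <- two_material_phantom(noise = FALSE, seed = 1)
  f <- phasor_transform(ph$stack, intensity_threshold = 100)
  img <- pseudocolor_phase(f, phase_range = c(45, 180))
  hsv_px <- grDevices::rgb2hsv(
    rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3])),
    maxColorValue = 1
  )
  hue <- matrix(hsv_px["h", ], nrow(img), ncol(img))
  # material A at 60 deg -> hue 0.083; material B at 120 deg -> hue 0.417
  predicted <- ifelse(hue < 0.25, "left", "right")
  agreement <- mean(predicted == ph$labels)
  expect_gte(agreement, 0.99)
  expect_gt(
    mean(hue[ph$labels == "right"]), mean(hue[ph$labels == "left"])
  )
})

test_that("cursor selection honours geometry with inclusive boundaries", {
  ph <- two_material_phantom(noise = TRUE, seed = 9)
  f <- phasor_transform(ph$stack, intensity_threshold = 100)
  # a circle containing the whole unit disc selects every valid pixel
  all_mask <- select_by_cursor(f, cursor_circle(0, 0, 2))
  expect_true(all(all_mask == f$valid_mask))
  # a far-away circle selects nothing
  none <- select_by_cursor(f, cursor_circle(-5, -5, 0.1))
  expect_false(any(none))
  # a 90-180 degree wedge selects exactly the 120-degree material
  wedge <- cursor_wedge(90, 180)
  sel <- select_by_cursor(f, wedge)
  expect_true(all(sel == (ph$labels == "right" & f$valid_mask)))
  # polygon cursor: box around the 60-degree material's phasor
  tr <- ph$truth[ph$truth$region == "left", ]
  poly <- cursor_polygon(
    tr$G + c(-0.2, 0.2, 0.2, -0.2), tr$S + c(-0.2, -0.2, 0.2, 0.2)
  )
  psel <- select_by_cursor(f, poly)
  expect_true(all(ph$labels[psel] == "left"))
  expect_gt(mean(psel[ph$labels == "left"]), 0.95)
  expect_error(cursor_wedge(180, 90), "smaller")
  expect_error(cursor_circle(0, 0, -1), "positive")
  expect_error(cursor_polygon(c(0, 1), c(0, 1)), "3 vertices")
})

test_that("reciprocity closure: ROI phasors of a cursor selection satisfy the cursor", {
  ph <- two_material_phantom(noise = TRUE, seed = 13)
  f <- phasor_transform(ph$stack, intensity_threshold = 100)
  cur <- cursor_wedge(90, 180, mod_lo = 0.2, mod_hi = 1)
  mask <- select_by_cursor(f, cur)
  sec <- phasor_of_roi(f, mask)
  pm <- phase_modulation(sec)
  ok <- sec$valid_mask
  expect_true(all(pm$phase[ok] >= 90 & pm$phase[ok] <= 180))
  expect_true(all(pm$modulation[ok] >= 0.2 & pm$modulation[ok] <= 1))
  expect_true(all(sec$valid_mask == (mask & f$valid_mask)))
})

test_that("ROI restriction keeps geometry and validates shape", {
  ph <- two_material_phantom(noise = TRUE, seed = 17)
  f <- phasor_transform(ph$stack, intensity_threshold = 100)
  full <- phasor_of_roi(f, matrix(TRUE, 20, 20))
  expect_equal(full$G, f$G)
  expect_identical(full$valid_mask, f$valid_mask)
  one <- matrix(FALSE, 20, 20)
  one[4, 7] <- TRUE
  single <- phasor_of_roi(f, one)
  expect_equal(sum(single$valid_mask), 1L)
  expect_equal(single$G[4, 7], f$G[4, 7])
  expect_error(phasor_of_roi(f, matrix(TRUE, 5, 5)), "dimensions")
})
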