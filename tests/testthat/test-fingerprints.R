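# Pure-component fingerprints, k-means centroids and linear unmixing.

test_that("k = 1 centroid is the arithmetic mean phasor", {
  f <- field_from_gs(matrix(0.3, 4, 4), matrix(0.6, 4, 4))
  ctr <- component_centroid(f, 1)
  expect_equal(unname(ctr[1, ]), c(0.3, 0.6))
  ph <- two_material_phantom(noise = TRUE, seed = 2)
  fld <- phasor_transform(ph$stack, intensity_threshold = 100)
  ctr1 <- component_centroid(fld, 1)
  expect_equal(
    unname(ctr1[1, ]),
    c(mean(fld$G[fld$valid_mask]), mean(fld$S[fld$valid_mask])),
    tolerance = 1e-12
  )
})

test_that("k = 2 centroids of a noiseless two-material phantom hit ground truth", {
  # near-delta emitters: quantization cannot move a one-channel phasor
  ph <- two_material_phantom(noise = FALSE, seed = 1, fwhm = 0.5)
  f <- phasor_transform(ph$stack, intensity_threshold = 100)
  ctr <- component_centroid(f, 2)
  got <- ctr[order(ctr[, "G"]), ]
  want <- as.matrix(ph$truth[order(ph$truth$G), c("G", "S")])
  expect_equal(unname(got), unname(want), tolerance = 1e-6)
  # reproducible across calls, and RNG state untouched
  set.seed(123); before <- stats::runif(1)
  ctr2 <- component_centroid(f, 2)
  expect_identical(ctr, ctr2)
  expect_error(component_centroid(f, 1e6), "exceeds")
})

test_that("two-component unmixing recovers segment position and residual", {
  a <- c(0.8, 0.2)
  b <- c(-0.1, 0.7)
  expect_equal(unmix_two(a, a, b)$fraction_a, 1)
  expect_equal(unmix_two(a, a, b)$residual, 0)
  expect_equal(unmix_two(b, a, b)$fraction_a, 0)
  expect_equal(unmix_two((a + b) / 2, a, b)$fraction_a, 0.5)
  # off-segment point: projection plus perpendicular residual
  mid <- (a + b) / 2
  perp <- c(-(b - a)[2], (b - a)[1]) / sqrt(sum((b - a)^2))
  off <- mid + 0.05 * perp
  u <- unmix_two(off, a, b)
  expect_equal(u$fraction_a, 0.5, tolerance = 1e-12)
  expect_equal(u$residual, 0.05, tolerance = 1e-12)
  expect_error(unmix_two(a, a, a), "degenerate")
})

test_that("forward two-component mixtures are recovered exactly without noise", {
  ax <- paper_axis()
  spec_a <- gaussian_emission(470, 60)(channel_centers(ax))
  spec_b <- gaussian_emission(590, 60)(channel_centers(ax))
  spec_a <- spec_a / sum(spec_a) # intensity-normalized components
  spec_b <- spec_b / sum(spec_b)
  fp_a <- spectrum_phasor(spec_a, ax)
  fp_b <- spectrum_phasor(spec_b, ax)
  for (fa in c(0.3, 0.05, 0.92)) {
    mix <- fa * spec_a + (1 - fa) * spec_b
    p <- spectrum_phasor(mix, ax)
    u <- unmix_two(c(p$G, p$S), c(fp_a$G, fp_a$S), c(fp_b$G, fp_b$S))
    expect_equal(u$fraction_a, fa, tolerance = 1e-6)
    expect_lt(u$residual, 1e-9)
    # invariance to overall intensity scaling of the mixture
    p2 <- spectrum_phasor(mix * 411, ax)
    u2 <- unmix_two(c(p2$G, p2$S), c(fp_a$G, fp_a$S), c(fp_b$G, fp_b$S))
    expect_equal(u2$fraction_a, u$fraction_a, tolerance = 1e-12)
  }
})

test_that("two-component fractions stay within 0.02 under Poisson noise at 1000 counts", {
  ax <- paper_axis()
  spec_a <- gaussian_emission(470, 60)(channel_centers(ax))
  spec_b <- gaussian_emission(590, 60)(channel_centers(ax))
  spec_a <- spec_a / sum(spec_a)
  spec_b <- spec_b / sum(spec_b)
  fp_a <- spectrum_phasor(spec_a, ax)
  fp_b <- spectrum_phasor(spec_b, ax)
  expected <- 1000 * (0.3 * spec_a + 0.7 * spec_b)
  set.seed(31)
  err <- replicate(100, {
    noisy <- stats::rpois(30, expected)
    p <- spectrum_phasor(noisy, ax)
    abs(unmix_two(
      c(p$G, p$S), c(fp_a$G, fp_a$S), c(fp_b$G, fp_b$S)
    )$fraction_a - 0.3)
  })
  expect_lte(mean(err), 0.02)
})

test_that("three-component barycentric unmixing recovers fractions and flags outsiders", {
  a <- c(0.9, 0.1); b <- c(-0.2, 0.8); c3 <- c(-0.3, -0.5)
  expect_equal(unname(unmix_three(a, a, b, c3)$fractions), c(1, 0, 0))
  ctr <- (a + b + c3) / 3
  expect_equal(unname(unmix_three(ctr, a, b, c3)$fractions), rep(1 / 3, 3),
    tolerance = 1e-12
  )
  # forward mixture through the transform
  ax <- paper_axis()
  sp <- lapply(c(460, 530, 620), function(pk) {
    s <- gaussian_emission(pk, 55)(channel_centers(ax))
    s / sum(s)
  })
  fps <- lapply(sp, function(s) {
    p <- spectrum_phasor(s, ax); c(p$G, p$S)
  })
  mix <- 0.2 * sp[[1]] + 0.3 * sp[[2]] + 0.5 * sp[[3]]
  p <- spectrum_phasor(mix, ax)
  u <- unmix_three(c(p$G, p$S), fps[[1]], fps[[2]], fps[[3]])
  expect_false(u$outside)
  expect_equal(unname(u$fractions), c(0.2, 0.3, 0.5), tolerance = 1e-6)
  # a point outside the triangle is flagged and renormalized
  far <- a + 2 * (a - ctr)
  uo <- unmix_three(far, a, b, c3)
  expect_true(uo$outside)
  expect_equal(sum(uo$fractions), 1)
  expect_true(all(uo$fractions >= 0))
  expect_error(
    unmix_three(a, c(0, 0), c(0.4, 0.4), c(0.8, 0.8)),
    "unmix_two"
  )
})

test_that("fingerprint libraries are computed on-axis and round-trip through CSV", {
  lib <- fingerprint_library()
  expect_equal(nrow(lib), 8L)
  expect_true(all(lib$G^2 + lib$S^2 <= 1 + 1e-9))
  # blue-to-red component ordering maps to increasing phase
  phase_of <- function(nm) {
    r <- lib[lib$name == nm, ]
    (atan2(r$S, r$G) * 180 / pi) %% 360
  }
  expect_lt(phase_of("collagen_I"), phase_of("FAD"))
  expect_lt(phase_of("FAD"), phase_of("melanin"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_fingerprints(lib, path)
  back <- read_fingerprints(path)
  expect_equal(back$G, lib$G, tolerance = 1e-12)
  expect_identical(back$name, lib$name)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_fingerprints(bad), "columns")
  # shipped synthetic library matches a fresh computation
  shipped <- read_fingerprints(
    system.file("extdata", "fingerprints_synthetic_library.csv",
      package = "specphasor"
    )
  )
  expect_equal(shipped$G, lib$G, tolerance = 1e-6)
})

test_that("fingerprint overlays render to file for full and empty libraries", {
  ph <- two_material_phantom(noise = TRUE, seed = 8)
  h <- phasor_histogram(phasor_transform(ph$stack, intensity_threshold = 100))
  lib <- fingerprint_library()
  f1 <- withr::local_tempfile(fileext = ".png")
  overlay_fingerprints(h, lib, file = f1)
  expect_gt(file.size(f1), 0)
  f2 <- withr::local_tempfile(fileext = ".png")
  overlay_fingerprints(h, lib[0, ], file = f2) # bare histogram
  expect_gt(file.size(f2), 0)
})
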