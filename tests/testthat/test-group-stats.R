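# Centre-of-mass summaries, pooled t-tests, confidence ellipses and the
# two-group cohort comparison.

test_that("centre of mass is the weighted mean with sane edge behaviour", {
  expect_equal(histogram_cm(5)$value, 5)
  expect_equal(histogram_cm(c(1, 2, 3))$value, 2)
  expect_equal(histogram_cm(c(1, 2, 3), weights = c(0, 0, 4))$value, 3)
  # translation equivariance
  set.seed(4)
  x <- stats::rnorm(50)
  w <- stats::runif(50)
  expect_equal(
    histogram_cm(x + 17.5, w)$value, histogram_cm(x, w)$value + 17.5
  )
  # bounded by the data range
  cm <- histogram_cm(x, w)$value
  expect_gte(cm, min(x)); expect_lte(cm, max(x))
  expect_error(histogram_cm(numeric(0)), "finite values")
  expect_error(histogram_cm(c(NA_real_, NaN)), "finite values")
  expect_error(histogram_cm(1:3, weights = c(0, 0, 0)), "all zero")
  expect_error(histogram_cm(1:3, weights = c(1, -1, 1)), "nonnegative")
})

test_that("printed cohort table summarizes as expected", {
  tab <- utils::read.csv(
    system.file("extdata", "melanocytic_lesions.csv", package = "specphasor")
  )
  breslow <- tab$breslow_mm[tab$group == "melanoma"]
  expect_equal(histogram_cm(breslow)$value, 2.26)
  expect_equal(stats::sd(breslow), 2.22, tolerance = 0.005)
  expect_equal(stats::median(breslow), 1.4)
})

test_that("pooled t-test matches the closed-form statistic and its conventions", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 4, 6, 8)
  # hand-computed pooled t
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  res <- two_sample_ttest(a, b)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 6)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), 6), tolerance = 1e-12)
  # identical groups
  same <- two_sample_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # separation limit
  far <- two_sample_ttest(c(1, 2, 3), c(101, 102.001, 103))
  expect_lt(far$p, 1e-6)
  # degenerate variances
  z1 <- two_sample_ttest(c(2, 2), c(2, 2))
  expect_equal(z1$p, 1)
  expect_message(z2 <- two_sample_ttest(c(1, 1), c(2, 2)), "convention")
  expect_equal(z2$p, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("confidence ellipses follow the covariance eigenstructure", {
  # points with exactly unit sample covariance -> k = 2 gives a circle of
  # radius 2 about the mean
  pts <- sqrt(3 / 2) * rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  pts <- sweep(pts, 2, c(5, -2), "+")
  e <- confidence_ellipse(pts, k = 2)
  expect_equal(unname(e$center), c(5, -2))
  expect_equal(unname(e$semi_axes), c(2, 2))
  expect_true(all(in_ellipse(pts, e)))
  expect_false(in_ellipse(rbind(c(5 + 2.1, -2)), e))
  # anisotropic cloud: membership is Mahalanobis, not axis-aligned
  set.seed(6)
  z <- matrix(stats::rnorm(4000), ncol = 2)
  tilted <- z %*% rbind(c(2, 1.2), c(0, 0.4))
  et <- confidence_ellipse(tilted, k = 2)
  expect_gt(et$semi_axes[1], et$semi_axes[2])
  # collinear points: degenerate warning path
  line <- cbind(1:5, 2 * (1:5))
  expect_warning(confidence_ellipse(line, k = 1), "degenerate")
  expect_error(confidence_ellipse(rbind(c(0, 0), c(1, 1)), 2), "3 points")
})

test_that("k-sigma ellipse coverage matches the closed-form 2-D Gaussian mass", {
  set.seed(8)
  z <- matrix(stats::rnorm(2 * 20000), ncol = 2)
  for (k in 1:3) {
    e <- confidence_ellipse(z, k = k)
    inside <- mean(in_ellipse(z, e))
    expect_equal(inside, 1 - exp(-k^2 / 2), tolerance = 0.015)
  }
  cov_tab <- ellipse_coverage(1:3)
  expect_equal(cov_tab$coverage_2d, c(0.3935, 0.8647, 0.9889),
    tolerance = 1e-3
  )
  expect_identical(cov_tab$label_1d, c("68.5%", "95.5%", "99.7%"))
})

test_that("cohort comparison recovers an injected group separation", {
  co <- make_cohort(n_nevus = 3, n_melanoma = 3, size = 32, seed = 14)
  cmp <- cohort_compare(cohort_fields(co, intensity_threshold = 250))
  expect_equal(nrow(cmp$per_sample), 6L)
  truth_phase <- vapply(co, `[[`, numeric(1), "truth_phase")
  labels <- vapply(co, `[[`, character(1), "label")
  for (lb in c("nevus", "melanoma")) {
    got <- cmp$per_sample$phase_cm[cmp$per_sample$label == lb]
    expect_equal(mean(got), mean(truth_phase[labels == lb]), tolerance = 0.02)
  }
  expect_lt(cmp$tests$phase$p, 0.01)
  expect_lt(cmp$tests$modulation$p, 0.01)
  expect_s3_class(cmp$ellipses$nevus$k2, "confidence_ellipse")
  expect_output(print(cmp), "t-test")
})

test_that("cohort comparison handles degenerate and incomplete inputs", {
  f <- field_from_gs(matrix(0.3, 4, 4), matrix(0.4, 4, 4))
  mk <- matrix(TRUE, 4, 4)
  mk_sample <- function(id, label, mask = mk) {
    list(id = id, label = label, field = f, mask = mask)
  }
  # two identical samples per group: zero SD, t-test degenerate path
  cmp <- cohort_compare(list(
    mk_sample("n1", "nevus"), mk_sample("n2", "nevus"),
    mk_sample("m1", "melanoma"), mk_sample("m2", "melanoma")
  ))
  expect_equal(cmp$group_summary$phase_sd, c(0, 0))
  expect_equal(cmp$tests$phase$p, 1)
  expect_null(cmp$ellipses$nevus) # fewer than 3 points per group
  # single-group input errors naming the missing label
  expect_error(
    cohort_compare(list(mk_sample("n1", "nevus"), mk_sample("n2", "nevus"))),
    "melanoma"
  )
  # missing ROI: skipped with a warning, then too few samples
  expect_warning(
    try(cohort_compare(list(
      mk_sample("n1", "nevus"), mk_sample("n2", "nevus"),
      mk_sample("m1", "melanoma"),
      list(id = "m2", label = "melanoma", field = f, mask = NULL)
    )), silent = TRUE),
    "missing ROI"
  )
})
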