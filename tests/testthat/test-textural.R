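# Autocorrelation, GLCM/Haralick, LBP, and PCA reduction.

test_that("autocorrelation equals the direct double-sum oracle", {
  set.seed(61)
  for (d in list(c(4, 4), c(5, 7), c(16, 16))) {
    px <- matrix(runif(prod(d)), d[1], d[2])
    g <- autocorrelation(px)
    oracle <- pointtex:::fftshift2(naive_autocorr(px))
    expect_equal(g$G, oracle, tolerance = 1e-9)
    # global maximum at zero lag
    expect_equal(unname(which(g$G == max(g$G), arr.ind = TRUE)[1, ]),
                 g$center)
  }
})

test_that("a constant image has a flat autocorrelation", {
  px <- matrix(3, 8, 8)
  g <- autocorrelation(px)
  expect_equal(g$G, matrix(9 * 64, 8, 8), tolerance = 1e-9)
  expect_warning(fv <- autocorr_features(g), "half maximum")
  expect_equal(fv[["fwhm"]], max(g$rho))
  expect_equal(fv[["max_grad"]], 0)
  expect_equal(fv[["min_grad"]], 0)
  expect_equal(fv[["tail_variance"]], 0)
  expect_length(fv, 5)
})

test_that("FWHM of a Gaussian blob follows the convolution identity", {
  # autocorrelation of a Gaussian of width s is Gaussian of width s*sqrt(2),
  # so the profile FWHM is 2*sqrt(2 log 2)*sqrt(2)*s
  for (s in c(3, 5)) {
    x <- 1:128
    blob <- outer(exp(-(x - 64)^2 / (2 * s^2)),
                  exp(-(x - 64)^2 / (2 * s^2)))
    fv <- autocorr_features(blob)
    expect_equal(fv[["fwhm"]], 2 * sqrt(2 * log(2)) * sqrt(2) * s,
                 tolerance = 0.05)
  }
})

test_that("GLCM matches hand co-occurrence counts", {
  w <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  g <- glcm(w, d = 1, n_levels = 2)
  m0 <- g$matrices[["0"]]
  expect_equal(m0, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  h <- haralick_coefficients(m0)
  expect_equal(h[["contrast"]], 0)
  # vertical direction pairs levels 0 and 1 exclusively
  m90 <- g$matrices[["90"]]
  expect_equal(m90, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(haralick_coefficients(m90)[["contrast"]], 1)
})

test_that("GLCMs are normalized, symmetric, and constant images are flat", {
  set.seed(62)
  px <- matrix(runif(72 * 72), 72, 72)
  g <- glcm(px)
  for (m in g$matrices) {
    expect_equal(sum(m), 1, tolerance = 1e-12)
    expect_equal(m, t(m))
  }
  fv <- glcm_features(matrix(1, 72, 72))
  expect_equal(fv[["contrast"]], 0)
  expect_equal(fv[["variance"]], 0)
  expect_named(fv, c("contrast", "variance", "sum_variance",
                     "difference_variance", "sum_average"))
  expect_length(glcm_features(px, all_coefficients = TRUE), 14)
  expect_error(glcm_features(matrix(0, 10, 10)), "window larger")
})

test_that("LBP codes follow the clockwise-from-top-left bit order", {
  # constant region: all differences zero, b(0) = 1, code 255
  expect_true(all(lbp_codes(matrix(7, 5, 5)) == 255))
  # center strictly above all neighbors: code 0
  p <- matrix(1, 3, 3)
  p[2, 2] <- 5
  expect_equal(as.integer(lbp_codes(p)), 0L)
  # hand-assembled code: neighbors clockwise from top-left
  # (6,4,4,4,4,4,4,6) around center 5 -> bits 1,0,0,0,0,0,0,1 -> 129
  q <- matrix(c(6, 4, 4,
                6, 5, 4,
                4, 4, 4), 3, 3, byrow = TRUE)
  expect_equal(as.integer(lbp_codes(q)), 129L)
})

test_that("LBP histograms are normalized and monotone-invariant", {
  set.seed(63)
  px <- matrix(runif(80 * 80), 80, 80)
  h <- lbp_features(px, region_size = 72)
  expect_length(h, 256)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # strictly monotone intensity transforms leave the codes unchanged
  expect_equal(lbp_codes(exp(2 * px)), lbp_codes(px))
  expect_equal(lbp_features(px^3 + 1, region_size = 72), h)
  expect_error(lbp_features(matrix(0, 10, 10)), "window larger")
})

test_that("PCA reduction preserves 5-dim spaces and finds low rank", {
  set.seed(64)
  x5 <- matrix(rnorm(200 * 5), 200, 5)
  red <- pca_reduce(x5, ndim = 5)
  # identity up to rotation: total variance preserved
  expect_equal(sum(apply(red$scores, 2, var)),
               sum(apply(scale(x5), 2, var)), tolerance = 1e-9)
  expect_equal(t(red$rotation) %*% red$rotation, diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(red$sdev) <= 1e-12))
  # exact 2-plane embedded in 14 dims
  basis <- matrix(rnorm(14 * 2), 14, 2)
  x14 <- matrix(rnorm(100 * 2), 100, 2) %*% t(basis)
  red2 <- pca_reduce(x14, ndim = 5, scale = FALSE)
  expect_lt(sum(red2$sdev[3:5]), 1e-8)
  expect_error(pca_reduce(matrix(rnorm(40), 10, 4), ndim = 5), "below")
})

test_that("PCA fitted on a subset ignores held-out rows entirely", {
  set.seed(65)
  x <- matrix(rnorm(60 * 8), 60, 8)
  fit_idx <- 1:40
  a <- pca_reduce(x, ndim = 5, fit_idx = fit_idx)
  x_corrupt <- x
  x_corrupt[41:60, ] <- 1e6 * matrix(rnorm(20 * 8), 20, 8)
  b <- pca_reduce(x_corrupt, ndim = 5, fit_idx = fit_idx)
  expect_equal(a$rotation, b$rotation)
  expect_equal(a$center, b$center)
  expect_equal(a$scores[fit_idx, ], b$scores[fit_idx, ])
})

test_that("every feature method emits exactly the common dimension", {
  set.seed(66)
  f <- sample_gaussian_field(class_params("C1", n_markers = 600))
  img <- render_image(f, 0.8, crop = 216)
  expect_length(image_features(img, "autocorrelation"), 5)
  expect_length(image_features(img, "glcm"), 5)
  expect_length(image_features(img, "distance", sigma_psf = 0.8), 5)
  expect_length(image_features(img, "ripley", use_truth = TRUE), 5)
  # LBP is 256 raw and reduced to 5 by the classification-stage PCA
  expect_length(image_features(img, "lbp"), 256)
})
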