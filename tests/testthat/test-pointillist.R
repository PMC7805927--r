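# Distance sets, distance features, Ripley K / Besag L and curve features.

test_that("distance sets match hand geometry on a 3-4-5 triangle", {
  f <- field_at(c(0, 0, 3, 0, 3, 4), dim = 10)
  ds <- distance_sets(f)
  expect_setequal(round(ds$pairwise, 10), c(3, 4, 5))
  expect_equal(sort(ds$nearest_neighbor), c(3, 3, 4))
  ctr <- c(2, 4 / 3)
  expect_equal(sort(ds$to_centroid),
               sort(c(sqrt(4 + 16 / 9), sqrt(1 + 16 / 9),
                      sqrt(1 + 64 / 9))))
  # coincident points
  ds2 <- distance_sets(field_at(c(5, 5, 5, 5), dim = 10))
  expect_equal(ds2$pairwise, 0)
  expect_equal(ds2$nearest_neighbor, c(0, 0))
  # lattice
  expect_true(all(distance_sets(grid_field(by = 2))$nearest_neighbor == 2))
  expect_error(distance_sets(field_at(c(1, 1))), "2 markers")
})

test_that("distance features recover known generating distributions", {
  set.seed(51)
  n <- 5000
  # the fixed-family estimators, applied to samples with known parameters
  pw <- rrayleigh(n, sigma = 5)
  expect_equal(sqrt(mean(pw^2) / 2), 5, tolerance = 0.03)
  ce <- rexp(n, rate = 0.2)
  expect_equal(1 / mean(ce), 0.2, tolerance = 0.03)
  # end-to-end: output is exactly the 5 named parameters, finite
  set.seed(52)
  f <- sample_gaussian_field(class_params("C1", n_markers = 400))
  fv <- distance_features(f)
  expect_named(fv, c("sigma_R", "lambda_E", "xi_G", "sigma_G", "mu_G"))
  expect_true(all(is.finite(fv)))
  expect_gt(fv[["sigma_R"]], 0)
  expect_gt(fv[["sigma_G"]], 0)
  expect_gt(fv[["lambda_E"]], 0)
})

test_that("pairwise subsampling leaves the Rayleigh scale stable", {
  set.seed(53)
  f <- sample_gaussian_field(class_params("C1", n_markers = 800))
  full <- distance_features(f, max_pairs = Inf)
  sub <- distance_features(f, max_pairs = 2e4)
  expect_equal(sub[["sigma_R"]], full[["sigma_R"]], tolerance = 0.02)
  # deterministic given the subsample seed
  expect_identical(distance_features(f, max_pairs = 2e4),
                   distance_features(f, max_pairs = 2e4))
})

test_that("Ripley K matches hand counts and the empty-indicator case", {
  w <- window_geometry(c(0, 100), c(0, 100))
  pts <- matrix(c(50, 50, 51, 50, 80, 80), ncol = 2, byrow = TRUE)
  k <- ripley_k(pts, window = w, radii = c(0, 2))
  expect_equal(k$K, c(0, 1e4 / 6 * 2), tolerance = 1e-12)
  # radius below the minimum pairwise distance: K = 0
  k0 <- ripley_k(pts, window = w, radii = c(0, 0.5))
  expect_equal(k0$K, c(0, 0))
  expect_error(ripley_k(pts, window = w, radii = c(0, 200)), "diagonal")
  expect_error(ripley_k(matrix(c(150, 50), 1, 2), window = w), "2 markers")
  expect_error(
    ripley_k(matrix(c(150, 50, 10, 10), 2, 2, byrow = TRUE), window = w,
             radii = c(0, 5)),
    "inside the window"
  )
})

test_that("optimized K equals the naive double-loop oracle", {
  set.seed(54)
  w <- csr_window(50)
  for (n in c(5, 15, 30)) {
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    radii <- seq(0, 20, by = 2.5)
    fast <- ripley_k(pts, window = w, radii = radii)$K
    slow <- naive_ripley_k(pts, w, radii)
    expect_equal(fast, slow, tolerance = 1e-9)
    # and without correction
    fast0 <- ripley_k(pts, window = w, radii = radii,
                      correction = "none")$K
    slow0 <- naive_ripley_k(pts, w, radii, correction = FALSE)
    expect_equal(fast0, slow0, tolerance = 1e-9)
  }
})

test_that("the exact arc-fraction geometry agrees with angular quadrature", {
  w <- window_geometry(c(0, 40), c(0, 30))
  quad_frac <- function(x, y, r) {
    th <- (seq_len(32768) - 0.5) / 32768 * 2 * pi
    mean(x + r * cos(th) >= w$xlim[1] & x + r * cos(th) <= w$xlim[2] &
           y + r * sin(th) >= w$ylim[1] & y + r * sin(th) <= w$ylim[2])
  }
  cases <- rbind(c(20, 15, 5),   # interior
                 c(2, 15, 5),    # one edge
                 c(2, 3, 5),     # corner
                 c(1, 1, 12),    # deep corner overlap
                 c(20, 2, 10))   # bottom edge
  for (i in seq_len(nrow(cases))) {
    got <- pointtex:::circle_inside_fraction(cases[i, 1], cases[i, 2],
                                             cases[i, 3], w)
    expect_equal(got, quad_frac(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 5e-4)
  }
})

test_that("edge correction weights are >= 1 and raise K near boundaries", {
  set.seed(55)
  pts <- cbind(runif(60, 0, 30), runif(60, 0, 30))
  w <- csr_window(30)
  radii <- seq(0, 7.5, length.out = 16)
  k_corr <- ripley_k(pts, window = w, radii = radii)$K
  k_none <- ripley_k(pts, window = w, radii = radii, correction = "none")$K
  expect_true(all(k_corr >= k_none - 1e-12))
  expect_gt(max(k_corr - k_none), 0) # some circle must exit the window
  frac <- pointtex:::circle_inside_fraction(pts[, 1], pts[, 2],
                                            rep(5, 60), w)
  expect_true(all(frac <= 1 + 1e-12))
  expect_true(all(1 / frac >= 1 - 1e-12))
})

test_that("Besag normalization is zero under CSR expectation", {
  w <- csr_window(100)
  r <- seq(0, 20, length.out = 21)
  curve <- structure(list(r = r, K = pi * r^2, Khat = NULL, n = 100,
                          window = w, correction = "ripley"),
                     class = "kfun_curve")
  kh <- besag_l(curve)$Khat
  expect_equal(kh, rep(0, length(r)), tolerance = 1e-12)
  # K = 4 pi at r = 1 gives Khat = 1
  c2 <- structure(list(r = 1, K = 4 * pi, Khat = NULL, n = 10, window = w,
                       correction = "ripley"), class = "kfun_curve")
  expect_equal(besag_l(c2)$Khat, 1)
  c2$K <- -1
  expect_error(besag_l(c2), "non-negative")
})

test_that("K-curve features match hand finite differences", {
  w <- csr_window(10)
  mk <- function(r, kh) {
    structure(list(r = r, K = rep(0, length(r)), Khat = kh, n = 10,
                   window = w, correction = "ripley"),
              class = "kfun_curve")
  }
  # linear curve
  f1 <- k_curve_features(mk(0:10, 0:10))
  expect_equal(unname(f1), c(10, 1, 1, 10, 1))
  # peaked curve (0, 2, 1)
  f2 <- k_curve_features(mk(0:2, c(0, 2, 1)))
  expect_equal(f2[["max_Khat"]], 2)
  expect_equal(f2[["r_at_max"]], 1)
  expect_equal(f2[["max_grad_pre"]], 2)
  expect_equal(f2[["min_grad_post"]], -1)
  expect_length(f2, 5)
  # constant curve: Spearman 0 with warning
  expect_warning(f3 <- k_curve_features(mk(0:3, rep(1, 4))), "Spearman")
  expect_equal(f3[["spearman"]], 0)
  expect_error(k_curve_features(mk(0:1, 0:1)), "3 radii")
})

test_that("CSR fields center Khat at zero; clustering lifts it", {
  set.seed(56)
  # small CSR calibration (the full 100-field version runs in acceptance)
  kh <- replicate(20, {
    f <- csr_field(200, 100)
    besag_l(ripley_k(f$coords, window = csr_window(100),
                     radii = seq(0, 20, length.out = 11)))$Khat
  })
  m <- rowMeans(kh)
  se <- apply(kh, 1, sd) / sqrt(ncol(kh))
  expect_true(all(abs(m[-1]) <= 3 * se[-1]))
  # clustered fields sit above the CSR 97.5th percentile at r = mu_D / 2
  set.seed(57)
  r_test <- c(0, 17.5)
  khat_at <- function(coords, dims) {
    besag_l(ripley_k(coords, window = window_geometry(c(0.5, dims + 0.5),
                                                      c(0.5, dims + 0.5)),
                     radii = r_test))$Khat[2]
  }
  c3 <- vapply(1:10, function(i) {
    khat_at(sample_clustered_field(class_params("C3"))$coords, 256)
  }, numeric(1))
  csr <- vapply(1:40, function(i) {
    khat_at(cbind(runif(3000, 1, 256), runif(3000, 1, 256)), 256)
  }, numeric(1))
  expect_gt(mean(c3), quantile(csr, 0.975))
})
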