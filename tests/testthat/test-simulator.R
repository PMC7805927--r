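# Marker-field generation, rendering, and the resolution ratio.

test_that("class parameters encode the benchmark densities and counts", {
  c1 <- class_params("C1")
  c2 <- class_params("C2")
  c3 <- class_params("C3")
  expect_equal(class_density(c1), 0.30)
  expect_equal(class_density(c2), 1 / 3, tolerance = 1e-9)
  expect_equal(class_density(c2) - class_density(c1), 0.30 / 9,
               tolerance = 1e-9)
  expect_equal(c3$n_markers, 3000L)
  expect_error(class_params("C1", n_markers = 0), "positive")
  expect_error(class_params("C1", spread_x = -1), "spread")
  expect_error(class_params("C3", n_seeds = 0), "positive")
})

test_that("Gaussian fields have exact counts and in-frame coordinates", {
  set.seed(11)
  for (cl in c("C1", "C2")) {
    f <- sample_gaussian_field(class_params(cl))
    expect_equal(nrow(f$coords), 3000L)
    expect_true(all(f$coords[, 1] >= 1 & f$coords[, 1] <= 256))
    expect_true(all(f$coords[, 2] >= 1 & f$coords[, 2] <= 256))
  }
  expect_error(sample_gaussian_field(class_params("C3")), "Gaussian")
})

test_that("untruncated Gaussian sampling reproduces the nominal spread", {
  set.seed(42)
  f <- sample_gaussian_field(class_params("C1", n_markers = 1e5),
                             truncate = FALSE)
  expect_equal(sd(f$coords[, 1]), 100, tolerance = 0.02)
  expect_equal(sd(f$coords[, 2]), 100, tolerance = 0.02)
  expect_equal(mean(f$coords[, 1]), 126, tolerance = 0.02)
})

test_that("clustered fields honor seed geometry and the radial law", {
  set.seed(12)
  f <- sample_clustered_field(class_params("C3"))
  expect_equal(nrow(f$coords), 3000L)
  expect_true(all(f$coords >= 1 & f$coords <= 256))
  # zero-spread limit: markers collapse onto their seed
  f0 <- sample_clustered_field(
    class_params("C3", n_seeds = 1, markers_per_seed = 10,
                 mean_radial_offset = 1e-9)
  )
  expect_equal(nrow(f0$coords), 10L)
  expect_lt(max(dist(f0$coords)), 1e-6)
  # Monte-Carlo mean of the exponential radial offsets
  set.seed(13)
  r <- rexp(1e5, rate = 1 / 35)
  expect_equal(mean(r), 35, tolerance = 0.01)
})

test_that("rendering conserves intensity and superposes kernels", {
  # single impulse: image is the kernel itself, unit total intensity
  im <- render_image(field_at(c(128, 128)), 0.8)
  expect_equal(sum(im$pixels), 1, tolerance = 1e-9)
  kmax <- which(im$pixels == max(im$pixels), arr.ind = TRUE)
  expect_equal(as.integer(kmax), c(128L, 128L))
  # delta kernel: raw counts
  f2 <- field_at(c(10, 20, 10, 20, 200, 100))
  im0 <- render_image(f2, 0)
  expect_equal(sum(im0$pixels), 3)
  expect_equal(im0$pixels[20, 10], 2) # [y, x]; two coincident markers
  expect_equal(im0$pixels[100, 200], 1)
  # superposition: two markers = sum of two single-marker images
  fa <- field_at(c(120, 128, 130, 128))
  ia <- render_image(fa, 2)
  ib <- render_image(field_at(c(120, 128)), 2)
  ic <- render_image(field_at(c(130, 128)), 2)
  expect_equal(ia$pixels, ib$pixels + ic$pixels, tolerance = 1e-12)
  # direct spatial-domain convolution oracle on interior markers
  counts <- matrix(0, 256, 256)
  counts[128, 120] <- 1
  counts[128, 130] <- 1
  oracle <- pointtex:::conv2_direct(counts, gaussian_kernel(2))
  expect_equal(ia$pixels, oracle, tolerance = 1e-9)
  # two local maxima within 1 px of the markers
  mx <- which(ia$pixels >= 0.99 * max(ia$pixels), arr.ind = TRUE)
  expect_true(any(abs(mx[, 2] - 120) <= 1) && any(abs(mx[, 2] - 130) <= 1))
})

test_that("intensity before crop equals marker count for any sigma", {
  set.seed(21)
  for (s in c(0, 0.51, 0.8, 2.04)) {
    f <- sample_gaussian_field(class_params("C1", n_markers = 500))
    im <- render_image(f, s)
    expect_equal(sum(im$pixels), 500, tolerance = 1e-6 * 500)
  }
})

test_that("cropping windows the image and remaps the truth", {
  f <- field_at(c(50, 50, 128, 128, 250, 250))
  im <- render_image(f, 1, crop = 216)
  expect_equal(dim(im$pixels), c(216L, 216L))
  expect_equal(im$crop_window, c(21L, 236L, 21L, 236L))
  # markers at 50 and 128 stay (shifted by 20); 250 exceeds the window
  expect_equal(nrow(im$truth$coords), 2L)
  expect_equal(im$truth$coords[, 1], c(30, 108))
  im2 <- render_image(f, 1, crop = c(100, 150, 100, 150))
  expect_equal(nrow(im2$truth$coords), 1L)
  expect_error(render_image(f, 1, crop = c(0, 255, 1, 256)), "crop")
  expect_error(render_image(f, 1, crop = 300), "crop")
})

test_that("resolution ratio follows k = d_min / sigma_psf", {
  expect_equal(resolution_ratio(1.02, 0.8)$k, 1.275)
  expect_equal(resolution_ratio(2, 2)$k, 1)
  expect_equal(resolution_ratio(1.02, 2.04)$k, 0.5)
  expect_equal(resolution_ratio(1.02, 0.8)$regime, "super-resolved")
  expect_equal(resolution_ratio(1.02, 2.04)$regime, "sub-resolved")
  expect_error(resolution_ratio(0, 1), "positive")
  expect_error(resolution_ratio(1, -1), "positive")
  # regime switch sits exactly at sigma = d_min
  sig <- default_sigma_grid()
  k <- 1.02 / sig
  expect_length(sig, 11)
  expect_equal(range(k), c(0.5, 2))
  expect_true(all((k > 1) == (sig < 1.02)))
})

test_that("estimate_dmin is the min-over-classes mean NN distance", {
  g <- grid_field(by = 2)
  expect_equal(estimate_dmin(list(g), list(g)), 2)
  fa <- field_at(c(0, 0, 5, 0))
  fb <- field_at(c(0, 0, 3, 0))
  expect_equal(estimate_dmin(list(fa), list(fb)), 3)
  expect_error(estimate_dmin(list(field_at(c(1, 1))), list(fa)), "2 markers")
})

test_that("simulation is deterministic under a fixed seed", {
  p <- class_params("C1", n_markers = 200)
  a <- pointtex:::with_seed(99, sample_gaussian_field(p))
  b <- pointtex:::with_seed(99, sample_gaussian_field(p))
  expect_identical(a$coords, b$coords)
})
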