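# Textural feature spaces: autocorrelation, GLCM/Haralick, LBP, and the
# PCA reduction to the common 5-feature dimension.

as_pixels <- function(image) {
  if (inherits(image, "cell_image")) image$pixels else image
}

#' Circular image autocorrelation via the Wiener-Khinchin theorem
#'
#' Computes `G = F^-1[ |F[i]|^2 ]` (the inverse Fourier transform of the
#' power spectrum), equal to the circular autocorrelation
#' `G(a, b) = sum_xy i(x, y) i(x - a, y - b)`. The zero lag is shifted to
#' the central position and a radial profile is formed by annular
#' averaging at 1-pixel bins around it.
#'
#' @param image a `cell_image` or numeric matrix.
#' @return an `autocorr_surface`: `G` (zero lag centered), `power_spectrum`
#'   (unshifted), `profile` (radial means), `rho` (bin radii, pixels),
#'   `center` (row, col of zero lag).
#' @export
autocorrelation <- function(image) {
  px <- as_pixels(image)
  stopifnot(is.matrix(px), length(px) > 0)
  ps <- Mod(stats::fft(px))^2
  g <- Re(stats::fft(ps, inverse = TRUE)) / length(px)
  gs <- fftshift2(g)
  ctr <- c(nrow(px) %/% 2 + 1, ncol(px) %/% 2 + 1)
  rr <- sqrt(outer((seq_len(nrow(px)) - ctr[1])^2,
                   (seq_len(ncol(px)) - ctr[2])^2, "+"))
  bin <- as.integer(round(rr)) + 1L
  prof <- as.numeric(tapply(as.numeric(gs), bin, mean))
  rho <- sort(unique(bin)) - 1L
  structure(list(G = gs, power_spectrum = ps, profile = prof,
                 rho = as.numeric(rho), center = ctr),
            class = "autocorr_surface")
}

#' The 5-feature summary of an autocorrelation surface
#'
#' Features of the radial profile `p(rho)`: the maximum (zero-lag) value;
#' the full width at half maximum, taken as twice the linearly
#' interpolated radius where `p` first crosses `p(0)/2` (if it never
#' crosses, the full profile extent with a warning); the maximum and
#' minimum finite-difference gradients; and the variance of the profile
#' tail beyond twice the half-width at half maximum (the central-peak
#' removal rule).
#'
#' @param surface an `autocorr_surface`, `cell_image`, or matrix.
#' @return named numeric vector
#'   `(max_autocorr, fwhm, max_grad, min_grad, tail_variance)`.
#' @export
autocorr_features <- function(surface) {
  if (!inherits(surface, "autocorr_surface")) {
    surface <- autocorrelation(surface)
  }
  p <- surface$profile
  rho <- surface$rho
  m <- length(p)
  half <- p[1] / 2
  below <- which(p < half)
  if (length(below) == 0) {
    warning("profile never crosses half maximum; FWHM set to full extent",
            call. = FALSE)
    hwhm <- rho[m]
    fwhm <- rho[m]
  } else {
    i <- below[1]
    hwhm <- if (i == 1) {
      0
    } else {
      rho[i - 1] + (p[i - 1] - half) / (p[i - 1] - p[i]) *
        (rho[i] - rho[i - 1])
    }
    fwhm <- 2 * hwhm
  }
  grad <- if (m > 1) diff(p) / diff(rho) else 0
  tail <- p[rho > 2 * hwhm]
  c(max_autocorr = p[1],
    fwhm = fwhm,
    max_grad = max(grad),
    min_grad = min(grad),
    tail_variance = if (length(tail) > 1) stats::var(tail) else 0)
}

#' Gray-level co-occurrence matrices of one window
#'
#' Quantizes the window to `n_levels` gray levels by min-max scaling and
#' accumulates, for each orientation (0, 45, 90, 135 degrees) at offset
#' distance `d`, the symmetric co-occurrence matrix, normalized to sum 1.
#'
#' @param window numeric matrix (one texture window).
#' @param d offset distance in pixels.
#' @param n_levels number of gray levels.
#' @return a `glcm_set`: list of four normalized `n_levels x n_levels`
#'   matrices named `"0"`, `"45"`, `"90"`, `"135"`, plus `d`, `n_levels`.
#' @export
glcm <- function(window, d = 1, n_levels = 32) {
  stopifnot(is.matrix(window), d >= 1)
  rng <- range(window)
  q <- if (rng[2] > rng[1]) {
    pmin(as.integer((window - rng[1]) / (rng[2] - rng[1]) * n_levels),
         n_levels - 1L)
  } else {
    matrix(0L, nrow(window), ncol(window))
  }
  dim(q) <- dim(window)
  nr <- nrow(q)
  nc <- ncol(q)
  # offsets in (row, col); 0 deg = horizontal, angles counter-clockwise
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0),
               `135` = c(-d, -d))
  mats <- lapply(offs, function(o) {
    rs <- max(1, 1 - o[1]):min(nr, nr - o[1])
    cs <- max(1, 1 - o[2]):min(nc, nc - o[2])
    if (length(rs) == 0 || length(cs) == 0) {
      stop("offset exceeds window size")
    }
    a <- q[rs, cs, drop = FALSE]
    b <- q[rs + o[1], cs + o[2], drop = FALSE]
    counts <- tabulate(as.integer(a) * n_levels + as.integer(b) + 1L,
                       nbins = n_levels^2)
    cm <- matrix(counts, n_levels, n_levels, byrow = TRUE)
    cm <- cm + t(cm) # symmetric accumulation
    cm / sum(cm)
  })
  structure(list(matrices = mats, d = d, n_levels = n_levels),
            class = "glcm_set")
}

#' The 14 Haralick coefficients of a normalized GLCM
#'
#' Standard definitions on gray levels `0 .. n_levels - 1`: angular second
#' moment, contrast, correlation, variance (sum of squares), inverse
#' difference moment, sum average, sum variance, sum entropy, entropy,
#' difference variance, difference entropy, the two information measures
#' of correlation, and the maximal correlation coefficient (guarded for
#' degenerate matrices). Natural logarithms; `0 log 0 = 0`.
#'
#' @param p normalized, symmetric co-occurrence matrix.
#' @return named numeric vector of 14 coefficients.
#' @export
haralick_coefficients <- function(p) {
  ng <- nrow(p)
  lev <- 0:(ng - 1)
  px <- rowSums(p)
  py <- colSums(p)
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum((lev - mu_x)^2 * px))
  sd_y <- sqrt(sum((lev - mu_y)^2 * py))
  ii <- matrix(lev, ng, ng)
  jj <- t(ii)
  xlogx <- function(z) ifelse(z > 0, z * log(z), 0)
  # p_{x+y}(k), k = 0 .. 2(ng-1); p_{x-y}(k), k = 0 .. ng-1
  psum <- as.numeric(tapply(as.numeric(p), as.numeric(ii + jj), sum))
  psum_full <- numeric(2 * ng - 1)
  psum_full[sort(unique(as.numeric(ii + jj))) + 1] <- psum
  pdiff <- as.numeric(tapply(as.numeric(p), as.numeric(abs(ii - jj)), sum))
  pdiff_full <- numeric(ng)
  pdiff_full[sort(unique(as.numeric(abs(ii - jj)))) + 1] <- pdiff
  ks <- 0:(2 * ng - 2)
  kd <- 0:(ng - 1)
  asm <- sum(p^2)
  contrast <- sum(kd^2 * pdiff_full)
  correlation <- if (sd_x > 0 && sd_y > 0) {
    (sum(ii * jj * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else {
    0
  }
  mu <- mu_x # symmetric matrix: mu_x == mu_y
  variance <- sum((ii - mu)^2 * p)
  idm <- sum(p / (1 + (ii - jj)^2))
  sum_average <- sum(ks * psum_full)
  sum_variance <- sum((ks - sum_average)^2 * psum_full)
  sum_entropy <- -sum(xlogx(psum_full))
  entropy <- -sum(xlogx(p))
  diff_average <- sum(kd * pdiff_full)
  difference_variance <- sum((kd - diff_average)^2 * pdiff_full)
  difference_entropy <- -sum(xlogx(pdiff_full))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxy > 0, p * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  hx <- -sum(xlogx(px))
  hy <- -sum(xlogx(py))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  mcc <- tryCatch({
    nz <- px > 0 & py > 0
    if (sum(nz) < 2) {
      0
    } else {
      q <- (p[nz, nz, drop = FALSE] / px[nz]) %*%
        (t(p[nz, nz, drop = FALSE]) / py[nz])
      ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, min(ev[2], 1)))
    }
  }, error = function(e) 0)
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_average = sum_average,
    sum_variance = sum_variance, sum_entropy = sum_entropy,
    entropy = entropy, difference_variance = difference_variance,
    difference_entropy = difference_entropy, imc1 = imc1, imc2 = imc2,
    mcc = mcc)
}

# Tile an image into non-overlapping square windows, top-left anchored;
# partial edge tiles are discarded.
tile_windows <- function(px, window_size) {
  nr <- nrow(px)
  nc <- ncol(px)
  if (window_size > nr || window_size > nc) {
    stop("window larger than image")
  }
  tiles <- list()
  for (r0 in seq(1, nr - window_size + 1, by = window_size)) {
    for (c0 in seq(1, nc - window_size + 1, by = window_size)) {
      tiles[[length(tiles) + 1]] <-
        px[r0:(r0 + window_size - 1), c0:(c0 + window_size - 1),
           drop = FALSE]
    }
  }
  tiles
}

#' GLCM/Haralick feature vector of an image
#'
#' The image is tiled into non-overlapping `window_size` squares; per
#' window the four-orientation GLCM is computed at offset `d`, the 14
#' Haralick coefficients are averaged over orientations (isotropy
#' assumption), and window vectors are averaged. By default the 5 named
#' coefficients found most informative (contrast, variance, sum variance,
#' difference variance, sum average) are returned; `all_coefficients =
#' TRUE` returns the full 14-vector for downstream PCA.
#'
#' @param image a `cell_image` or matrix (at least one full window).
#' @param window_size texture window side in pixels.
#' @param d GLCM offset distance.
#' @param n_levels gray levels for quantization.
#' @param all_coefficients return all 14 Haralick coefficients.
#' @return named numeric feature vector (5 or 14 values).
#' @export
glcm_features <- function(image, window_size = 72, d = 1, n_levels = 32,
                          all_coefficients = FALSE) {
  px <- as_pixels(image)
  tiles <- tile_windows(px, window_size)
  per_tile <- vapply(tiles, function(w) {
    g <- glcm(w, d = d, n_levels = n_levels)
    rowMeans(vapply(g$matrices, haralick_coefficients, numeric(14)))
  }, numeric(14))
  feats <- rowMeans(per_tile)
  if (all_coefficients) {
    feats
  } else {
    feats[c("contrast", "variance", "sum_variance", "difference_variance",
            "sum_average")]
  }
}

#' Local binary pattern codes of an image
#'
#' For every interior pixel, the 8 neighbors are compared to the center;
#' neighbor `n` (numbered from the top-left corner, clockwise) contributes
#' `2^n` when its intensity is greater than or equal to the center
#' (ties count as 1).
#'
#' @param image a `cell_image` or matrix.
#' @return integer matrix of codes in `[0, 255]` for the interior pixels
#'   (`(nrow - 2) x (ncol - 2)`).
#' @export
lbp_codes <- function(image) {
  px <- as_pixels(image)
  nr <- nrow(px)
  nc <- ncol(px)
  if (nr < 3 || nc < 3) stop("image must be at least 3x3")
  ctr <- px[2:(nr - 1), 2:(nc - 1)]
  # neighbor offsets (row, col), top-left then clockwise; bit n weight 2^n
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, nr - 2, nc - 2)
  for (n in seq_along(offs)) {
    o <- offs[[n]]
    nb <- px[(2 + o[1]):(nr - 1 + o[1]), (2 + o[2]):(nc - 1 + o[2])]
    code <- code + bitwShiftL(as.integer(nb >= ctr), n - 1L)
  }
  code
}

#' LBP histogram feature vector of an image
#'
#' The image is tiled into non-overlapping `region_size` squares; per
#' region the 256-bin normalized histogram of interior LBP codes is
#' computed, and histograms are averaged across regions. The resulting
#' 256-vector is reduced to 5 dimensions by PCA downstream (fit policy in
#' the classification stage).
#'
#' @param image a `cell_image` or matrix (at least one full region).
#' @param region_size region side in pixels.
#' @return numeric vector of length 256 summing to 1.
#' @export
lbp_features <- function(image, region_size = 72) {
  px <- as_pixels(image)
  tiles <- tile_windows(px, region_size)
  hists <- vapply(tiles, function(w) {
    codes <- lbp_codes(w)
    h <- tabulate(as.integer(codes) + 1L, nbins = 256)
    h / sum(h)
  }, numeric(256))
  rowMeans(hists)
}

#' PCA reduction of a feature table
#'
#' Centering, scaling and rotation are learned on the designated fit
#' subset only (e.g. the training folds) and applied to all rows, so
#' held-out data never leaks into the projection. Columns with zero
#' variance on the fit subset are kept with unit scale. Components are
#' ordered by explained variance.
#'
#' @param x numeric matrix (rows = observations).
#' @param ndim target dimension.
#' @param fit_idx row indices used to fit the projection.
#' @param scale logical; divide by fit-subset standard deviations.
#' @return list with `scores` (all rows, `ndim` columns), `rotation`,
#'   `center`, `scale`, `sdev` (fit-subset component standard deviations).
#' @export
pca_reduce <- function(x, ndim = 5, fit_idx = seq_len(nrow(x)),
                       scale = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) < ndim) {
    stop("feature dimension ", ncol(x), " is below the target ", ndim)
  }
  if (length(fit_idx) == 0) stop("fit subset is empty")
  xf <- x[fit_idx, , drop = FALSE]
  ctr <- colMeans(xf)
  scl <- if (scale) {
    s <- apply(xf, 2, stats::sd)
    s[s == 0 | !is.finite(s)] <- 1
    s
  } else {
    rep(1, ncol(x))
  }
  xs <- sweep(sweep(xf, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  if (ncol(pc$rotation) < ndim) {
    stop("rank ", ncol(pc$rotation), " is below the target dimension ",
         ndim)
  }
  rot <- pc$rotation[, seq_len(ndim), drop = FALSE]
  all_s <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(scores = all_s %*% rot, rotation = rot, center = ctr, scale = scl,
       sdev = pc$sdev[seq_len(ndim)])
}
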