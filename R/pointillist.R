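# Pointillist feature spaces: distance-distribution parameters and
# Besag-normalized Ripley K-curve descriptors.

#' Observation window for spatial statistics
#'
#' @param xlim,ylim rectangle bounds (continuous pixel units).
#' @return a `window_geometry` with `xlim`, `ylim`, `area`.
#' @export
window_geometry <- function(xlim, ylim) {
  stopifnot(length(xlim) == 2, length(ylim) == 2,
            diff(xlim) > 0, diff(ylim) > 0)
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 area = diff(xlim) * diff(ylim)),
            class = "window_geometry")
}

# Window covering all pixels of a w x h image under the 1-based
# pixel-center convention: [0.5, w + 0.5] x [0.5, h + 0.5].
image_window <- function(image_dims) {
  window_geometry(c(0.5, image_dims[1] + 0.5), c(0.5, image_dims[2] + 0.5))
}

#' The three distance sets of a marker field
#'
#' Exact Euclidean distances: all pairwise inter-marker distances, each
#' marker's distance to the centroid (arithmetic mean position), and each
#' marker's nearest-neighbor distance.
#'
#' @param field a `marker_field` with at least 2 markers.
#' @return a `distance_sets` list: `pairwise` (n(n-1)/2 values),
#'   `to_centroid` (n values), `nearest_neighbor` (n values).
#' @export
distance_sets <- function(field) {
  coords <- if (inherits(field, "marker_field")) field$coords else field
  n <- nrow(coords)
  if (n < 2) stop("at least 2 markers required")
  ctr <- colMeans(coords)
  structure(list(
    pairwise = as.numeric(stats::dist(coords)),
    to_centroid = sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2),
    nearest_neighbor = nn_distances(coords)
  ), class = "distance_sets")
}

#' The 5-parameter distance-distribution feature vector
#'
#' Fits the fixed distribution families identified for each distance set:
#' Rayleigh (scale `sigma_R`) to the pairwise distances, exponential (rate
#' `lambda_E`) to the centroid distances, and GEV (shape `xi_G`, scale
#' `sigma_G`, location `mu_G`) to the nearest-neighbor distances, all by
#' maximum likelihood. Pairwise distances are subsampled (seeded) to
#' `max_pairs` when the pair count exceeds it; the fits are insensitive at
#' that size.
#'
#' @param field a `marker_field` (>= 2 markers) or coordinate matrix.
#' @param max_pairs subsampling cap for the pairwise set.
#' @param subsample_seed seed for the subsampling draw.
#' @return named numeric vector `(sigma_R, lambda_E, xi_G, sigma_G, mu_G)`.
#' @export
distance_features <- function(field, max_pairs = 1e5, subsample_seed = 1) {
  ds <- distance_sets(field)
  pw <- ds$pairwise
  if (length(pw) > max_pairs) {
    pw <- with_seed(subsample_seed,
                    pw[sample.int(length(pw), max_pairs)])
  }
  sigma_r <- sqrt(mean(pw^2) / 2)
  lambda_e <- 1 / mean(ds$to_centroid)
  gev <- tryCatch(fit_gev(ds$nearest_neighbor), error = function(e) {
    stop("GEV fit of nearest-neighbor distances failed: ",
         conditionMessage(e))
  })
  c(sigma_R = sigma_r, lambda_E = lambda_e,
    xi_G = gev$shape, sigma_G = gev$scale, mu_G = gev$loc)
}

# Fraction of the circle of radius r centered at (x, y) lying inside the
# rectangular window; exact arc geometry (adjacent-corner overlap terms).
# Vectorized over points/radii of equal length.
circle_inside_fraction <- function(x, y, r, window) {
  # acos(pmin(d/r, 1)) is 0 whenever the circle stays inside an edge, and
  # the adjacent-corner overlap term is non-positive exactly when the
  # circle does not reach past the corner, so no explicit conditionals
  # are needed.
  a1 <- acos(pmin((x - window$xlim[1]) / r, 1))
  a2 <- acos(pmin((window$xlim[2] - x) / r, 1))
  a3 <- acos(pmin((y - window$ylim[1]) / r, 1))
  a4 <- acos(pmin((window$ylim[2] - y) / r, 1))
  hp <- pi / 2
  out <- 2 * (a1 + a2 + a3 + a4) -
    pmax(a1 + a3 - hp, 0) - pmax(a1 + a4 - hp, 0) -
    pmax(a2 + a3 - hp, 0) - pmax(a2 + a4 - hp, 0)
  pmax(1 - out / (2 * pi), 1e-9)
}

#' Ripley's K-function with isotropic edge correction
#'
#' Implements the ordered-pair estimator
#' `K(r, n) = |Omega| / (n (n - 1)) * sum_{x != y} 1(|x - y| <= r) f(x, y)`
#' with Ripley's isotropic boundary correction
#' `f(x, y) = (P(x, y) + P(y, x)) / 2`, where `P(x, y)` is the full
#' circumference of the circle centered at `x` through `y` divided by the
#' arc length inside the window (so `f >= 1`, and `f = 1` for fully
#' interior circles). Under complete spatial randomness the expectation is
#' `pi r^2`.
#'
#' @param field a `marker_field` or coordinate matrix (>= 2 markers, all
#'   inside the window).
#' @param window a `window_geometry`; defaults to the field's image frame.
#' @param radii increasing radius grid (pixels); defaults to 100 steps up
#'   to a quarter of the shorter window side.
#' @param correction `"ripley"` (isotropic) or `"none"`.
#' @return a `kfun_curve`: `r`, `K`, `Khat` (`NULL` until [besag_l()]),
#'   `n`, `window`, `correction`.
#' @export
ripley_k <- function(field, window = NULL, radii = NULL,
                     correction = c("ripley", "none")) {
  correction <- match.arg(correction)
  coords <- if (inherits(field, "marker_field")) field$coords else field
  n <- nrow(coords)
  if (n < 2) stop("at least 2 markers required")
  if (is.null(window)) {
    if (!inherits(field, "marker_field")) {
      stop("window required when field is a bare matrix")
    }
    window <- image_window(field$image_dims)
  }
  if (is.null(radii)) {
    rmax <- min(diff(window$xlim), diff(window$ylim)) / 4
    radii <- seq(0, rmax, length.out = 101)
  }
  radii <- sort(radii)
  diag_len <- sqrt(diff(window$xlim)^2 + diff(window$ylim)^2)
  if (max(radii) > diag_len) stop("radii exceed the window diagonal")
  if (any(coords[, 1] < window$xlim[1] | coords[, 1] > window$xlim[2] |
            coords[, 2] < window$ylim[1] | coords[, 2] > window$ylim[2])) {
    stop("all markers must lie inside the window")
  }
  rmax <- max(radii)
  cp <- close_pairs_cpp(coords, rmax)
  K <- numeric(length(radii))
  if (length(cp$d) > 0) {
    dk <- cp$d
    i <- cp$i
    j <- cp$j
    if (correction == "ripley") {
      fi <- 1 / circle_inside_fraction(coords[j, 1], coords[j, 2], dk, window)
      fj <- 1 / circle_inside_fraction(coords[i, 1], coords[i, 2], dk, window)
      w <- (fi + fj) / 2
    } else {
      w <- rep(1, length(dk))
    }
    ord <- order(dk)
    cw <- cumsum(w[ord])
    idx <- findInterval(radii, dk[ord])
    K <- ifelse(idx > 0, cw[pmax(idx, 1)], 0) *
      2 * window$area / (n * (n - 1))
  }
  structure(list(r = radii, K = K, Khat = NULL, n = n, window = window,
                 correction = correction),
            class = "kfun_curve")
}

#' Besag's variance-stabilized L normalization
#'
#' Fills `Khat(r) = sqrt(K(r) / pi) - r`, which is zero-centered under
#' complete spatial randomness and positive where the pattern is clustered.
#'
#' @param curve a `kfun_curve` with raw `K` computed.
#' @return the curve with `Khat` filled.
#' @export
besag_l <- function(curve) {
  stopifnot(inherits(curve, "kfun_curve"))
  if (any(curve$K < 0)) stop("K must be non-negative")
  curve$Khat <- sqrt(curve$K / pi) - curve$r
  curve
}

#' @export
print.kfun_curve <- function(x, ...) {
  cat(sprintf("kfun_curve: %d radii in [%.3g, %.3g], n = %d markers%s\n",
              length(x$r), min(x$r), max(x$r), x$n,
              if (is.null(x$Khat)) " (raw K)" else " (Besag-normalized)"))
  invisible(x)
}

#' The 5-feature summary of a Besag-normalized K curve
#'
#' Gradients are central finite differences (one-sided at the ends). The
#' features are: the maximum `Khat` value; the maximum gradient over
#' `[0, argmax]`; the minimum gradient over `[argmax, end]`; the radius at
#' the maximum (ties broken toward the smallest radius); and the Spearman
#' rank correlation between `Khat` and `r` (0, with a warning, for a
#' constant curve).
#'
#' @param curve a `kfun_curve` with `Khat` filled (>= 3 radii).
#' @return named numeric vector
#'   `(max_Khat, max_grad_pre, min_grad_post, r_at_max, spearman)`.
#' @export
k_curve_features <- function(curve) {
  stopifnot(inherits(curve, "kfun_curve"))
  if (is.null(curve$Khat)) curve <- besag_l(curve)
  r <- curve$r
  kh <- curve$Khat
  m <- length(r)
  if (m < 3) stop("at least 3 radii required")
  grad <- numeric(m)
  grad[1] <- (kh[2] - kh[1]) / (r[2] - r[1])
  grad[m] <- (kh[m] - kh[m - 1]) / (r[m] - r[m - 1])
  mid <- 2:(m - 1)
  grad[mid] <- (kh[mid + 1] - kh[mid - 1]) / (r[mid + 1] - r[mid - 1])
  imax <- which.max(kh) # which.max already takes the first (smallest r) tie
  sp <- if (stats::sd(kh) == 0) {
    warning("constant Khat curve; Spearman correlation set to 0",
            call. = FALSE)
    0
  } else {
    suppressWarnings(stats::cor(kh, r, method = "spearman"))
  }
  c(max_Khat = kh[imax],
    max_grad_pre = max(grad[1:imax]),
    min_grad_post = min(grad[imax:m]),
    r_at_max = r[imax],
    spearman = sp)
}

#' Ripley-K feature vector of a marker field
#'
#' Convenience wrapper: raw K, Besag normalization, curve features.
#' @inheritParams ripley_k
#' @return named numeric vector of 5 features.
#' @export
ripley_features <- function(field, window = NULL, radii = NULL) {
  k_curve_features(besag_l(ripley_k(field, window, radii)))
}
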