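# Shared fixtures: small deterministic fields and images built in code.

# A field with markers at given coordinates in a square frame.
field_at <- function(coords, dim = 256, class_id = NA_character_) {
  marker_field(matrix(coords, ncol = 2, byrow = TRUE),
               class_id = class_id, image_dims = c(dim, dim))
}

# Regular grid field with spacing `by` inside [lo, hi].
grid_field <- function(lo = 10, hi = 50, by = 2, dim = 256) {
  g <- expand.grid(x = seq(lo, hi, by = by), y = seq(lo, hi, by = by))
  marker_field(cbind(g$x, g$y), image_dims = c(dim, dim))
}

# Uniform (CSR) field of n points in a [0, side]^2 window.
csr_field <- function(n, side = 100) {
  marker_field(cbind(stats::runif(n, 0, side), stats::runif(n, 0, side)),
               image_dims = c(side, side))
}

csr_window <- function(side = 100) window_geometry(c(0, side), c(0, side))

# Independent naive Ripley-K oracle: double loop over ordered pairs with
# a scalar, re-derived exact arc-fraction correction for the rectangle.
naive_ripley_k <- function(coords, window, radii, correction = TRUE) {
  n <- nrow(coords)
  frac_inside <- function(x, y, r) {
    if (r == 0) return(1)
    dl <- x - window$xlim[1]; dr <- window$xlim[2] - x
    db <- y - window$ylim[1]; dt <- window$ylim[2] - y
    ang <- 0
    for (d in c(dl, dr, db, dt)) if (d < r) ang <- ang + 2 * acos(d / r)
    for (pair in list(c(dl, db), c(dl, dt), c(dr, db), c(dr, dt))) {
      if (r^2 > sum(pair^2)) {
        ang <- ang - (acos(pair[1] / r) + acos(pair[2] / r) - pi / 2)
      }
    }
    max(1 - ang / (2 * pi), 1e-9)
  }
  vapply(radii, function(r) {
    s <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        if (d <= r) {
          f <- if (correction) {
            0.5 * (1 / frac_inside(coords[i, 1], coords[i, 2], d) +
                     1 / frac_inside(coords[j, 1], coords[j, 2], d))
          } else {
            1
          }
          s <- s + f
        }
      }
    }
    window$area / (n * (n - 1)) * s
  }, numeric(1))
}

# Direct double-sum circular autocorrelation (brute-force oracle).
naive_autocorr <- function(px) {
  nr <- nrow(px)
  nc <- ncol(px)
  g <- matrix(0, nr, nc)
  for (a in 0:(nr - 1)) {
    for (b in 0:(nc - 1)) {
      s <- 0
      for (x in 1:nr) {
        for (y in 1:nc) {
          s <- s + px[x, y] * px[(x - 1 - a) %% nr + 1, (y - 1 - b) %% nc + 1]
        }
      }
      g[a + 1, b + 1] <- s
    }
  }
  g
}
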