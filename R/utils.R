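# Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `code`, and
#' restores the previous state on exit. Used wherever an operation needs
#' reproducible internal randomness (e.g. seeded subsampling) without
#' disturbing the caller's stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a per-item seed from a root seed
#'
#' Deterministic function of (root, index) so each simulated image owns an
#' independent, order-independent stream. Kept below 2^31 - 1.
#' @keywords internal
derive_seed <- function(root, index) {
  as.integer((as.double(root) * 48271 + as.double(index) * 7919 + 1) %%
               2147483647)
}

#' Discretized unit-sum Gaussian kernel
#'
#' @param sigma kernel width in pixels; `sigma = 0` yields the 1x1 identity
#'   (delta) kernel.
#' @param truncation kernel half-width in multiples of `sigma`.
#' @return square matrix summing to one.
#' @export
gaussian_kernel <- function(sigma, truncation = 4) {
  stopifnot(sigma >= 0, truncation > 0)
  if (sigma == 0) {
    return(matrix(1, 1, 1))
  }
  h <- max(1L, as.integer(ceiling(truncation * sigma)))
  g <- stats::dnorm(-h:h, mean = 0, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Negated, zero-mean Laplacian-of-Gaussian kernel
#'
#' Scale-normalized (multiplied by sigma^2) so peak response is comparable
#' across scales; negated so a bright blob of matching size produces a
#' positive response maximum; mean-subtracted so a constant background maps
#' to zero response.
#' @keywords internal
log_kernel <- function(sigma, truncation = 4) {
  stopifnot(sigma > 0)
  h <- max(2L, as.integer(ceiling(truncation * sigma)))
  x <- -h:h
  r2 <- outer(x^2, x^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- -(r2 - 2 * sigma^2) / sigma^2 * g # sigma^2 * LoG, negated
  k - mean(k)
}

# Circular ("wrap-around") 2-D convolution of an image with a small centered
# kernel, via FFT. Mass-conserving: sum(result) == sum(mat) * sum(kernel).
conv2_circular <- function(mat, kernel) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  if (kr > nr || kc > nc) {
    stop("kernel larger than image")
  }
  hf <- matrix(0, nr, nc)
  ir <- ((-((kr - 1L) %/% 2L)):((kr - 1L) %/% 2L)) %% nr + 1L
  ic <- ((-((kc - 1L) %/% 2L)):((kc - 1L) %/% 2L)) %% nc + 1L
  hf[ir, ic] <- kernel[] # kernel center lands at (1, 1)
  Re(stats::fft(stats::fft(mat) * stats::fft(hf), inverse = TRUE)) / (nr * nc)
}

# Direct spatial-domain "same" convolution (small inputs only); used as an
# independent oracle in tests and for tiny kernels.
conv2_direct <- function(mat, kernel) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  kr <- nrow(kernel)
  kc <- ncol(kernel)
  hr <- (kr - 1L) %/% 2L
  hc <- (kc - 1L) %/% 2L
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      w <- kernel[a, b]
      if (w == 0) next
      sr <- a - 1L - hr
      sc <- b - 1L - hc
      rs <- max(1L, 1L + sr):min(nr, nr + sr)
      cs <- max(1L, 1L + sc):min(nc, nc + sc)
      out[rs, cs] <- out[rs, cs] + w * mat[rs - sr, cs - sc]
    }
  }
  out
}

# Shift a matrix so element (1,1) (zero lag of an FFT product) moves to the
# central position (floor(nr/2)+1, floor(nc/2)+1).
fftshift2 <- function(mat) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  ri <- c((nr - (nr %/% 2) + 1):nr, 1:(nr - nr %/% 2))
  ci <- c((nc - (nc %/% 2) + 1):nc, 1:(nc - nc %/% 2))
  mat[ri, ci, drop = FALSE]
}

# Per-point nearest-neighbor distances (compiled O(n^2) loop).
nn_distances <- function(coords) {
  nn_dist_cpp(coords)
}
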