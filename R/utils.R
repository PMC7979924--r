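# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded simulation inside the
#' package never disturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index; stays within 32-bit
# integer range.
derive_seed <- function(seed, index, stream = 0L) {
  (as.double(seed) * 69069 + index * 7919 + stream * 104729) %% 2147483629
}

# Bilinear interpolation of matrix `img` at continuous, 0-based pixel-center
# coordinates (rows r, cols c). Out-of-range coordinates are an error.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(r < 0 | r > nr - 1 | c < 0 | c > nc - 1))
    stop("interpolation coordinates outside the image")
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0 + 1, c0 + 1)]
  i01 <- img[cbind(r0 + 1, c0 + 2)]
  i10 <- img[cbind(r0 + 2, c0 + 1)]
  i11 <- img[cbind(r0 + 2, c0 + 2)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

# Centered moving average with window of `k` samples (odd); edges use the
# available part of the window.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- k %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Smooth standard-normal field along a 1-D sample grid: white noise convolved
# with a Gaussian kernel of scale `ell` samples, restandardized to unit sd.
smooth_gaussian_field <- function(n, ell) {
  z <- stats::rnorm(n + 8L * ceiling(ell))
  if (ell > 0) {
    half <- 4L * ceiling(ell)
    kern <- stats::dnorm(seq(-half, half), sd = ell)
    kern <- kern / sqrt(sum(kern^2))  # preserves unit variance of white noise
    z <- stats::convolve(z, kern, type = "filter")
  }
  z <- z[seq_len(n)]
  if (length(z) < n) stop("internal: field shorter than requested")
  z
}

# Arclength (in the same units as the coordinates) of a polyline given as a
# two-column matrix (row, col).
polyline_length <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(diff(v[, 1])^2 + diff(v[, 2])^2))
}

# Resample a polyline at regular arclength steps `ds`; returns positions,
# cumulative arclength and unit tangents (all in input units).
resample_polyline <- function(v, ds) {
  seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    v <- v[keep, , drop = FALSE]
    seg <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  }
  s_cum <- c(0, cumsum(seg))
  total <- s_cum[length(s_cum)]
  # uniform grid including both endpoints: symmetric under path reversal
  s <- seq(0, total, length.out = max(2L, ceiling(total / ds) + 1L))
  r <- stats::approx(s_cum, v[, 1], xout = s)$y
  c_ <- stats::approx(s_cum, v[, 2], xout = s)$y
  n <- length(s)
  tr <- c(r[2] - r[1], (r[3:n] - r[1:(n - 2)]) / 2, r[n] - r[n - 1])
  tc <- c(c_[2] - c_[1], (c_[3:n] - c_[1:(n - 2)]) / 2, c_[n] - c_[n - 1])
  nrm <- sqrt(tr^2 + tc^2)
  nrm[nrm == 0] <- 1
  list(s = s, r = r, c = c_, tr = tr / nrm, tc = tc / nrm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
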