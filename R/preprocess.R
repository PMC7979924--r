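# Spatial-frequency filtering and background removal applied before scoring.

#' Bandpass specification
#'
#' Structures larger than `large_cut_um` (shading, whole-cell gradients) and
#' smaller than `small_cut_px` (pixel noise) are removed; everything in
#' between — the microtubule-scale content — is preserved. Setting
#' `small_cut_px = 0` disables the small cut and reproduces a pure high-pass.
#'
#' @param large_cut_um remove structures larger than this, micrometres
#'   (default 5).
#' @param small_cut_px remove structures smaller than this, pixels
#'   (default 2; 0 disables).
#' @param taper raised-cosine transition width as a fraction of each cutoff
#'   frequency (default 0.1).
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(large_cut_um = 5, small_cut_px = 2, taper = 0.1) {
  if (large_cut_um <= 0) stop("`large_cut_um` must be > 0")
  if (small_cut_px < 0) stop("`small_cut_px` must be >= 0")
  if (taper <= 0 || taper >= 1) stop("`taper` must be in (0, 1)")
  structure(list(large_cut_um = large_cut_um, small_cut_px = small_cut_px,
                 taper = taper), class = "bandpass_spec")
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Mirror-extend a matrix to (P1, P2) by reflective tiling.
mirror_pad <- function(m, P1, P2) {
  refl <- function(n, P) {
    idx <- (seq_len(P) - 1L) %% (2L * n)
    ifelse(idx < n, idx + 1L, 2L * n - idx)
  }
  m[refl(nrow(m), P1), refl(ncol(m), P2), drop = FALSE]
}

# Radial raised-cosine annular gain on the DFT grid of a (P1, P2) image.
bandpass_mask <- function(P1, P2, f_lo, f_hi, taper) {
  f1 <- c(0:(P1 %/% 2), -((P1 - P1 %/% 2 - 1):1)) / P1
  f2 <- c(0:(P2 %/% 2), -((P2 - P2 %/% 2 - 1):1)) / P2
  fr <- sqrt(outer(f1^2, f2^2, "+"))
  gain <- matrix(1, P1, P2)
  if (!is.null(f_lo)) {  # high-pass edge: 0 below f_lo, 1 above f_lo*(1+taper)
    w <- taper * f_lo
    g <- (fr - f_lo) / w
    gain <- gain * ifelse(fr <= f_lo, 0,
                          ifelse(fr >= f_lo + w, 1,
                                 0.5 * (1 - cos(pi * g))))
  }
  if (!is.null(f_hi)) {  # low-pass edge: 1 below f_hi*(1-taper), 0 above f_hi
    w <- taper * f_hi
    g <- (f_hi - fr) / w
    gain <- gain * ifelse(fr >= f_hi, 0,
                          ifelse(fr <= f_hi - w, 1,
                                 0.5 * (1 - cos(pi * g))))
  }
  gain
}

#' FFT bandpass filter
#'
#' Removes spatial frequencies that are not relevant to microtubule-scale
#' structure: periods larger than `large_cut_um` (including the DC term) are
#' attenuated to below 5% and, unless disabled, periods smaller than
#' `small_cut_px` are removed as well. The image is mirror-padded to the next
#' power-of-two size to suppress wrap-around ringing, filtered with a
#' radially symmetric raised-cosine mask, and cropped back. Because the DC
#' term is removed the raw result is zero-mean; the original image mean is
#' added back so that typical intensities stay positive, and is recorded in
#' attribute `"offset"`.
#'
#' @param image a [channel_image()].
#' @param spec a [bandpass_spec()].
#' @return a filtered [channel_image()] (`filtered = TRUE`), with attributes
#'   `"offset"` (restored mean) on the pixel matrix.
#' @export
fft_bandpass <- function(image, spec = bandpass_spec()) {
  stopifnot(inherits(image, "channel_image"), inherits(spec, "bandpass_spec"))
  m <- image$pixels
  large_cut_px <- spec$large_cut_um / image$pixel_size_um
  if (spec$small_cut_px > 0 && large_cut_px <= spec$small_cut_px)
    stop("large_cut_um must exceed small_cut_px in pixel units")
  if (min(dim(m)) < 2 * large_cut_px)
    stop("image must be larger than twice the large cutoff")
  P1 <- next_pow2(2 * nrow(m)); P2 <- next_pow2(2 * ncol(m))
  pad <- mirror_pad(m, P1, P2)
  f_lo <- 1 / large_cut_px
  f_hi <- if (spec$small_cut_px > 0) 1 / spec$small_cut_px else NULL
  gain <- bandpass_mask(P1, P2, f_lo, f_hi, spec$taper)
  ft <- stats::fft(pad)
  filt <- Re(stats::fft(ft * gain, inverse = TRUE)) / (P1 * P2)
  out <- filt[seq_len(nrow(m)), seq_len(ncol(m))]
  offset <- mean(m)
  out <- out + offset
  attr(out, "offset") <- offset
  channel_image(out, image$pixel_size_um, image$channel, filtered = TRUE)
}

#' Morphological background subtraction
#'
#' Estimates the smooth background as a grey-scale opening with a disc
#' structuring element of the given radius (the rolling-ball idea), lightly
#' Gaussian-smoothed, clamped to never exceed the image, and subtracts it.
#' Features narrower than the radius — such as filaments — survive with
#' their amplitude essentially intact; broad background and residual shading
#' are removed. The output is never negative and never exceeds the input.
#'
#' @param image a [channel_image()]; negative values (from a signed filter)
#'   are clamped at zero before the morphology.
#' @param radius_um structuring-element radius in micrometres; must exceed
#'   the pixel size.
#' @return background-subtracted [channel_image()]; the background estimate
#'   is attached as attribute `"background"` on the pixel matrix.
#' @export
subtract_background <- function(image, radius_um = 2) {
  stopifnot(inherits(image, "channel_image"))
  if (!is.numeric(radius_um) || radius_um <= 0)
    stop("`radius_um` must be positive")
  if (radius_um <= image$pixel_size_um)
    stop("`radius_um` must exceed the pixel size")
  m <- pmax(image$pixels, 0)
  r_px <- max(1L, round(radius_um / image$pixel_size_um))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  # replicate-pad so the structuring element sees a full neighbourhood at
  # the borders (otherwise the estimate undershoots boundary maxima), and
  # rescale to [0, 1] because EBImage grayscale morphology clips there
  k <- 2L * r_px + 2L
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  mp <- m[ri, ci]
  mx <- max(m)
  if (mx == 0) mx <- 1
  bg <- EBImage::opening(mp / mx, brush) * mx
  bg <- EBImage::gblur(bg, sigma = max(1, r_px / 10))
  bg <- bg[k + seq_len(nrow(m)), k + seq_len(ncol(m))]
  bg <- pmin(pmax(bg, 0), m)
  out <- m - bg
  attr(out, "background") <- bg
  channel_image(out, image$pixel_size_um, image$channel,
                filtered = image$filtered)
}

#' Preprocess an image pair for scoring
#'
#' Applies the standard two-step cleanup to both channels: FFT bandpass,
#' then morphological background subtraction (skipped when `bg_radius_um`
#' is `NULL`).
#'
#' @param pair an [image_pair()].
#' @param spec a [bandpass_spec()].
#' @param bg_radius_um radius for [subtract_background()], or `NULL` to skip.
#' @return the preprocessed [image_pair()].
#' @export
preprocess_pair <- function(pair, spec = bandpass_spec(), bg_radius_um = 2) {
  stopifnot(inherits(pair, "image_pair"))
  f <- function(ch) {
    ch <- fft_bandpass(ch, spec)
    if (!is.null(bg_radius_um)) ch <- subtract_background(ch, bg_radius_um)
    ch
  }
  image_pair(f(pair$bait), f(pair$prey))
}
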