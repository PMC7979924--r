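#' Single-channel microscopy image
#'
#' A light container for one fluorescence channel: a numeric intensity matrix
#' plus the physical pixel size. Raw images must be finite and non-negative;
#' filtered images (e.g. after [fft_bandpass()]) may be signed, which is
#' tracked with the `filtered` flag.
#'
#' Coordinate convention throughout the package: matrix row/column indices
#' seen by the user are 0-based, pixel-center; arclengths and radii are in
#' micrometres.
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_size_um physical pixel size in micrometres (default 0.1).
#' @param channel channel label, `"bait"` (RFP-MBD fusion) or `"prey"` (GFP).
#' @param filtered logical; `TRUE` once a signed filter has been applied.
#' @return an object of class `channel_image`.
#' @export
channel_image <- function(pixels, pixel_size_um = 0.1,
                          channel = c("bait", "prey"), filtered = FALSE) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("`pixels` must be a finite numeric matrix")
  if (!filtered && any(pixels < 0))
    stop("raw channel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = channel, filtered = filtered),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %.3g um/px, range [%.4g, %.4g]%s\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels),
              if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' Aligned bait/prey image pair
#'
#' Bundles the red (bait) and green (prey) channels of one field of view.
#' Both channels must share shape and pixel size.
#'
#' @param bait,prey `channel_image` objects (or plain matrices, which are
#'   wrapped with the default pixel size).
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(bait, prey) {
  if (is.matrix(bait)) bait <- channel_image(bait, channel = "bait")
  if (is.matrix(prey)) prey <- channel_image(prey, channel = "prey")
  stopifnot(inherits(bait, "channel_image"), inherits(prey, "channel_image"))
  if (!identical(dim(bait$pixels), dim(prey$pixels)))
    stop("bait and prey images must have identical shape")
  if (abs(bait$pixel_size_um - prey$pixel_size_um) > 1e-12)
    stop("bait and prey images must share the pixel size")
  bait$channel <- "bait"; prey$channel <- "prey"
  structure(list(bait = bait, prey = prey), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d px at %.3g um/px\n",
              nrow(x$bait$pixels), ncol(x$bait$pixels), x$bait$pixel_size_um))
  invisible(x)
}

#' Traced filament path
#'
#' An ordered polyline along a microtubule (the in-silico equivalent of an
#' ImageJ freehand line of the stated thickness), in 0-based pixel-center
#' coordinates.
#'
#' @param vertices two-column numeric matrix `(row_px, col_px)`, at least two
#'   distinct consecutive vertices.
#' @param thickness_px width of the averaging line in pixels (default 4).
#' @param pixel_size_um pixel size in micrometres (default 0.1, i.e. 100 nm).
#' @return an object of class `path_trace`. Its arclength in micrometres is
#'   available via [path_length_um()].
#' @export
path_trace <- function(vertices, thickness_px = 4, pixel_size_um = 0.1) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("`vertices` must be a two-column matrix with >= 2 vertices")
  seg <- sqrt(diff(vertices[, 1])^2 + diff(vertices[, 2])^2)
  if (any(seg == 0)) stop("consecutive vertices must be distinct")
  if (thickness_px <= 0 || pixel_size_um <= 0)
    stop("`thickness_px` and `pixel_size_um` must be positive")
  structure(list(vertices = vertices, thickness_px = thickness_px,
                 pixel_size_um = pixel_size_um),
            class = "path_trace")
}

#' Arclength of a traced path in micrometres
#' @param path a `path_trace`.
#' @return numeric scalar, micrometres.
#' @export
path_length_um <- function(path) {
  stopifnot(inherits(path, "path_trace"))
  polyline_length(path$vertices) * path$pixel_size_um
}

#' @export
print.path_trace <- function(x, ...) {
  cat(sprintf("<path_trace> %d vertices, %.2f um, thickness %g px\n",
              nrow(x$vertices), path_length_um(x), x$thickness_px))
  invisible(x)
}
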