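# Reading and writing images, path tables and ground-truth sidecars.

#' Read a bait/prey image pair from TIFF
#'
#' Accepts either a single two-page TIFF (page 1 = bait, page 2 = prey) or
#' two single-channel TIFF files with matching shape. Intensities are
#' returned on the original 16-bit integer scale.
#'
#' @param path path to a two-page TIFF, or character vector of two paths
#'   (bait, prey).
#' @param pixel_size_um physical pixel size to attach (default 0.1).
#' @return an [image_pair()].
#' @export
read_image_pair <- function(path, pixel_size_um = 0.1) {
  read_one <- function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = FALSE)
    lapply(pages, function(m) round(m * 65535))
  }
  if (length(path) == 1L) {
    pages <- read_one(path)
    if (length(pages) != 2L)
      stop(sprintf("expected a two-page TIFF (bait, prey); '%s' has %d page(s)",
                   path, length(pages)))
    bait <- pages[[1]]; prey <- pages[[2]]
  } else if (length(path) == 2L) {
    b <- read_one(path[1]); p <- read_one(path[2])
    if (length(b) != 1L || length(p) != 1L)
      stop("when two files are given each must be single-page")
    bait <- b[[1]]; prey <- p[[1]]
  } else stop("`path` must be one two-page TIFF or two single-channel TIFFs")
  if (!identical(dim(bait), dim(prey)))
    stop("bait and prey images have mismatched shapes")
  image_pair(channel_image(bait, pixel_size_um, "bait"),
             channel_image(prey, pixel_size_um, "prey"))
}

#' Write a bait/prey image pair as a 16-bit two-page TIFF
#'
#' Intensities are clamped to `[0, 65535]` and rounded; write-then-read is
#' bit-exact for integer data.
#'
#' @param pair an [image_pair()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_pair <- function(pair, path) {
  stopifnot(inherits(pair, "image_pair"))
  enc <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(enc(pair$bait$pixels), enc(pair$prey$pixels)),
                  path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Write / read filament vertex tables
#'
#' CSV with columns `filament_id, vertex_index, row_px, col_px` (0-based
#' pixel-center coordinates), the exchange format between the scene
#' generator and the profiling stage.
#'
#' @param network list of [path_trace()] objects.
#' @param path CSV file path.
#' @return `write_paths`: `path` invisibly. `read_paths`: list of
#'   [path_trace()].
#' @export
write_paths <- function(network, path) {
  tabs <- lapply(seq_along(network), function(k) {
    v <- network[[k]]$vertices
    data.frame(filament_id = k, vertex_index = seq_len(nrow(v)) - 1L,
               row_px = v[, 1], col_px = v[, 2])
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_paths
#' @param thickness_px,pixel_size_um trace parameters to attach on read.
#' @export
read_paths <- function(path, thickness_px = 4, pixel_size_um = 0.1) {
  tab <- utils::read.csv(path)
  needed <- c("filament_id", "vertex_index", "row_px", "col_px")
  if (!all(needed %in% names(tab)))
    stop("path table must have columns: ", paste(needed, collapse = ", "))
  lapply(split(tab, tab$filament_id), function(d) {
    d <- d[order(d$vertex_index), ]
    path_trace(cbind(d$row_px, d$col_px), thickness_px = thickness_px,
               pixel_size_um = pixel_size_um)
  })
}

#' Write / read a ground-truth sidecar
#'
#' Serializes a `synthetic_ground_truth` object (filament vertices,
#' noise-free profiles, planted compartments, target correlation, noise
#' parameters, seed) to JSON at full precision; the round trip is lossless.
#'
#' @param truth a `synthetic_ground_truth` (from [render_scene()]).
#' @param path JSON file path.
#' @return `write_ground_truth`: `path` invisibly; `read_ground_truth`: the
#'   restored object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_ground_truth"))
  payload <- list(
    vertices = lapply(truth$network, function(p) unclass(p$vertices)),
    thickness_px = if (length(truth$network))
      truth$network[[1]]$thickness_px else 4,
    pixel_size_um = truth$config$pixel_size_um,
    profiles = truth$profiles,
    compartments = truth$compartments,
    coloc_rho = truth$coloc_rho,
    noise = truth$noise,
    seed = truth$seed)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  network <- lapply(p$vertices, function(v)
    path_trace(matrix(unlist(v), ncol = 2, byrow = TRUE),
               thickness_px = p$thickness_px,
               pixel_size_um = p$pixel_size_um))
  profiles <- lapply(p$profiles, function(q)
    list(s_um = unlist(q$s_um), a = unlist(q$a), b = unlist(q$b)))
  # data frames serialize as one object per row
  compartments <- if (length(p$compartments)) do.call(rbind, lapply(
    p$compartments, function(r)
      data.frame(filament_index = r$filament_index, start_um = r$start_um,
                 end_um = r$end_um, channel = r$channel,
                 fold_change = r$fold_change, mode = r$mode,
                 stringsAsFactors = FALSE)))
  else compartment_spec(1L, 0, 1)[0, ]
  structure(list(network = network, profiles = profiles,
                 compartments = compartments,
                 coloc_rho = p$coloc_rho,
                 noise = lapply(p$noise, unlist),
                 config = list(pixel_size_um = p$pixel_size_um),
                 seed = p$seed),
            class = "synthetic_ground_truth")
}
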