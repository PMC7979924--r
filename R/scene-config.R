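#' Configuration of a synthetic two-channel microscopy scene
#'
#' Collects every knob of the synthetic generator: image geometry, filament
#' network density, on-filament bait/prey intensity, the target rank
#' correlation between the two channels, diffuse background, large-scale
#' illumination shading, and camera noise. Identical config plus seed yields
#' a bit-identical scene.
#'
#' @param image_shape integer vector `(rows, cols)` in pixels.
#' @param pixel_size_um pixel size, micrometres per pixel (default 0.1).
#' @param n_filaments number of filaments to lay down.
#' @param filament_curvature dimensionless smoothness parameter: sd of the
#'   turning angle (radians) per 2-px step of the underlying random walk.
#' @param filament_len_um range (min, max) of filament lengths to draw, um.
#' @param bait_level mean bait intensity on filaments, photons/pixel.
#' @param prey_level mean prey intensity on filaments; defaults to
#'   `bait_level`.
#' @param coloc_rho target Spearman rank correlation between noise-free bait
#'   and prey intensities along filaments, in `[-1, 1]`. Induced through a
#'   Gaussian copula so the target is a rank (not Pearson) correlation.
#' @param intensity_cv lognormal sd (log scale) of the on-filament intensity
#'   texture shared structure; controls how variegated filaments look.
#' @param field_scale_px correlation length of that texture along the
#'   filament, in pixels.
#' @param psf_sigma_px Gaussian cross-section sd of rendered filaments, px.
#' @param background_level diffuse cytoplasmic intensity, photons/pixel.
#' @param shading_amplitude fraction of the background varying at > 5 um
#'   scale (low-order polynomial illumination surface).
#' @param poisson_noise logical, apply Poisson shot noise.
#' @param gaussian_sd camera read-noise standard deviation (photons).
#' @param seed integer seed; all per-scene randomness derives from it.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(512L, 512L),
                         pixel_size_um = 0.1,
                         n_filaments = 30L,
                         filament_curvature = 0.12,
                         filament_len_um = NULL,
                         bait_level = 200,
                         prey_level = NULL,
                         coloc_rho = 0.5,
                         intensity_cv = 0.5,
                         field_scale_px = 3,
                         psf_sigma_px = 1,
                         background_level = 30,
                         shading_amplitude = 0.2,
                         poisson_noise = TRUE,
                         gaussian_sd = 3,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape <= 0))
    stop("`image_shape` must be two positive integers (rows, cols)")
  if (coloc_rho < -1 || coloc_rho > 1) stop("`coloc_rho` must lie in [-1, 1]")
  prey_level <- prey_level %||% bait_level
  if (is.null(filament_len_um)) {
    diag_um <- sqrt(sum(image_shape^2)) * pixel_size_um
    filament_len_um <- c(0.5, 0.9) * diag_um
  }
  for (nm in c("pixel_size_um", "bait_level", "prey_level", "background_level",
               "shading_amplitude", "gaussian_sd", "intensity_cv",
               "field_scale_px", "psf_sigma_px"))
    if (get(nm) < 0 || !is.finite(get(nm)))
      stop(sprintf("`%s` must be finite and >= 0", nm))
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  if (n_filaments < 0) stop("`n_filaments` must be >= 0")
  structure(list(image_shape = image_shape, pixel_size_um = pixel_size_um,
                 n_filaments = as.integer(n_filaments),
                 filament_curvature = filament_curvature,
                 filament_len_um = filament_len_um,
                 bait_level = bait_level, prey_level = prey_level,
                 coloc_rho = coloc_rho, intensity_cv = intensity_cv,
                 field_scale_px = field_scale_px, psf_sigma_px = psf_sigma_px,
                 background_level = background_level,
                 shading_amplitude = shading_amplitude,
                 poisson_noise = isTRUE(poisson_noise),
                 gaussian_sd = gaussian_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(paste0("<scene_config> %dx%d px @ %.3g um/px, %d filaments, ",
                     "bait %g, prey %g, rho %.2f, bg %g, shading %.2f, ",
                     "poisson %s, read sd %g, seed %d\n"),
              x$image_shape[1], x$image_shape[2], x$pixel_size_um,
              x$n_filaments, x$bait_level, x$prey_level, x$coloc_rho,
              x$background_level, x$shading_amplitude, x$poisson_noise,
              x$gaussian_sd, x$seed))
  invisible(x)
}

#' Planted compartment specification
#'
#' Describes a contiguous demixed segment to plant on one filament: the
#' arclength interval, which channel is modified, and the multiplicative fold
#' change. `mode = "enrichment"` multiplies the named channel by
#' `fold_change`; `mode = "depletion-of-other"` divides the opposite channel
#' by it, so in both cases the named channel's relative ratio rises by the
#' same factor.
#'
#' @param filament_index 1-based index of the filament in the network.
#' @param start_um,end_um arclength interval along the filament, um.
#' @param channel `"bait"` or `"prey"`: the channel whose relative ratio is
#'   elevated.
#' @param fold_change multiplicative factor, must be > 1.
#' @param mode `"enrichment"` or `"depletion-of-other"`.
#' @return a one-row data frame; rows from several calls can be `rbind`-ed.
#' @export
compartment_spec <- function(filament_index, start_um, end_um,
                             channel = c("bait", "prey"), fold_change = 2,
                             mode = c("enrichment", "depletion-of-other")) {
  channel <- match.arg(channel); mode <- match.arg(mode)
  if (!(start_um >= 0 && start_um < end_um))
    stop("need 0 <= start_um < end_um")
  if (fold_change <= 1) stop("`fold_change` must be > 1")
  data.frame(filament_index = as.integer(filament_index),
             start_um = start_um, end_um = end_um, channel = channel,
             fold_change = fold_change, mode = mode,
             stringsAsFactors = FALSE)
}

validate_compartments <- function(compartments, network, pixel_size_um) {
  if (is.null(compartments) || nrow(compartments) == 0L)
    return(invisible(TRUE))
  needed <- c("filament_index", "start_um", "end_um", "channel",
              "fold_change", "mode")
  if (!all(needed %in% names(compartments)))
    stop("compartment table must have columns: ",
         paste(needed, collapse = ", "))
  for (i in seq_len(nrow(compartments))) {
    k <- compartments$filament_index[i]
    if (k < 1 || k > length(network))
      stop(sprintf("compartment %d references filament %d; network has %d",
                   i, k, length(network)))
    len <- path_length_um(network[[k]])
    if (compartments$end_um[i] > len + 1e-9)
      stop(sprintf(
        "compartment %d ends at %.2f um but filament %d is %.2f um long",
        i, compartments$end_um[i], k, len))
    if (compartments$fold_change[i] <= 1)
      stop("compartment fold_change must be > 1")
  }
  invisible(TRUE)
}
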