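# Synthetic two-channel microscopy scenes with known ground truth.

#' Generate a synthetic filament network
#'
#' Lays down `n_filaments` smooth curvilinear paths inside the image: each is
#' a random walk with Gaussian turning-angle increments (sd =
#' `filament_curvature` per 2-px step) that is steered away from the image
#' margin, then cubic-spline smoothed through every fourth walk vertex. This
#' emulates the appearance of an interphase microtubule array at ~100 nm/px
#' without modelling polymer mechanics.
#'
#' @param config a [scene_config()].
#' @return a list of [path_trace()] objects, with attribute
#'   `total_length_um` (sum of polyline arclengths in micrometres).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  shp <- config$image_shape
  if (any(shp < 16L)) stop("image too small to host filaments (need >= 16 px)")
  margin <- 6
  with_seed(derive_seed(config$seed, 0L, stream = 1L), {
    network <- vector("list", config$n_filaments)
    for (k in seq_len(config$n_filaments)) {
      len_um <- stats::runif(1, config$filament_len_um[1],
                             config$filament_len_um[2])
      step <- 2  # px
      n_steps <- max(8L, ceiling(len_um / config$pixel_size_um / step))
      r <- stats::runif(1, margin, shp[1] - 1 - margin)
      c_ <- stats::runif(1, margin, shp[2] - 1 - margin)
      theta <- stats::runif(1, 0, 2 * pi)
      dth <- stats::rnorm(n_steps, 0, config$filament_curvature)
      pr <- numeric(n_steps + 1L); pc <- numeric(n_steps + 1L)
      pr[1] <- r; pc[1] <- c_
      for (i in seq_len(n_steps)) {
        theta <- theta + dth[i]
        rn <- pr[i] + step * sin(theta)
        cn <- pc[i] + step * cos(theta)
        # steer back from the margin by reflecting the offending component
        if (rn < margin || rn > shp[1] - 1 - margin) {
          theta <- -theta
          rn <- pr[i] + step * sin(theta)
        }
        if (cn < margin || cn > shp[2] - 1 - margin) {
          theta <- pi - theta
          cn <- pc[i] + step * cos(theta)
        }
        pr[i + 1L] <- min(max(rn, margin), shp[1] - 1 - margin)
        pc[i + 1L] <- min(max(cn, margin), shp[2] - 1 - margin)
      }
      knots <- unique(c(seq(1L, n_steps + 1L, by = 4L), n_steps + 1L))
      t_knot <- seq_along(knots)
      t_fine <- seq(1, length(knots), by = 0.25)
      sr <- stats::spline(t_knot, pr[knots], xout = t_fine)$y
      sc <- stats::spline(t_knot, pc[knots], xout = t_fine)$y
      sr <- pmin(pmax(sr, margin), shp[1] - 1 - margin)
      sc <- pmin(pmax(sc, margin), shp[2] - 1 - margin)
      keep <- c(TRUE, sqrt(diff(sr)^2 + diff(sc)^2) > 1e-6)
      network[[k]] <- path_trace(cbind(sr[keep], sc[keep]),
                                 pixel_size_um = config$pixel_size_um)
    }
    attr(network, "total_length_um") <-
      sum(vapply(network, path_length_um, 0))
    network
  })
}

# Smooth correlated lognormal intensity fields for one filament: returns
# noise-free bait/prey intensities at arclength samples, with pointwise
# Gaussian-copula rank correlation coloc_rho between the two channels.
filament_fields <- function(n, config) {
  rho_z <- 2 * sin(pi * config$coloc_rho / 6)  # Spearman -> Gaussian rho
  if (abs(config$coloc_rho) >= 1) rho_z <- sign(config$coloc_rho)
  zb <- smooth_gaussian_field(n, config$field_scale_px * 2)  # samples at 0.5 px
  zi <- smooth_gaussian_field(n, config$field_scale_px * 2)
  zp <- rho_z * zb + sqrt(max(0, 1 - rho_z^2)) * zi
  cv <- config$intensity_cv
  a <- config$bait_level * exp(cv * zb - cv^2 / 2)
  b <- config$prey_level * exp(cv * zp - cv^2 / 2)
  list(a = a, b = b, zb = zb, zp = zp)
}

# Low-order 2-D polynomial illumination surface, normalized to peak
# absolute value 1. Coefficients are drawn from the scene RNG stream.
shading_surface <- function(shp) {
  u <- seq(-1, 1, length.out = shp[1])
  v <- seq(-1, 1, length.out = shp[2])
  U <- matrix(u, shp[1], shp[2]); V <- matrix(v, shp[1], shp[2], byrow = TRUE)
  co <- stats::rnorm(5)
  s <- co[1] * U + co[2] * V + co[3] * U * V + co[4] * (U^2 - 1 / 3) +
    co[5] * (V^2 - 1 / 3)
  s / max(abs(s))
}

# Rasterize one filament with a Gaussian cross-section: each pixel within
# 3*sigma of the path takes intensity(nearest arclength sample) *
# exp(-d^2 / (2 sigma^2)). Nearest-sample mapping keeps longitudinal
# structure (compartment boundaries) crisp.
rasterize_filament <- function(shp, rs, values, sigma) {
  support <- ceiling(3 * sigma)
  off <- expand.grid(dr = -support:support, dc = -support:support)
  n <- length(rs$s)
  pr <- round(rs$r); pc <- round(rs$c)
  cand_r <- rep(pr, each = nrow(off)) + off$dr
  cand_c <- rep(pc, each = nrow(off)) + off$dc
  samp <- rep(seq_len(n), each = nrow(off))
  ok <- cand_r >= 0 & cand_r <= shp[1] - 1 & cand_c >= 0 & cand_c <= shp[2] - 1
  cand_r <- cand_r[ok]; cand_c <- cand_c[ok]; samp <- samp[ok]
  d2 <- (cand_r - rs$r[samp])^2 + (cand_c - rs$c[samp])^2
  keep <- d2 <= (3 * sigma)^2
  cand_r <- cand_r[keep]; cand_c <- cand_c[keep]
  samp <- samp[keep]; d2 <- d2[keep]
  pix <- cand_r + shp[1] * cand_c  # 0-based linear index
  o <- order(pix, d2)
  first <- !duplicated(pix[o])
  pix <- pix[o][first]; samp <- samp[o][first]; d2 <- d2[o][first]
  img <- matrix(0, shp[1], shp[2])
  img[pix + 1L] <- values[samp] * exp(-d2 / (2 * sigma^2))
  img
}

#' Render a two-channel scene with planted ground truth
#'
#' Builds noise-free bait/prey intensity profiles along each filament (a
#' Gaussian copula ties the two channels at the configured rank
#' correlation), applies any planted compartments as multiplicative fold
#' changes on the profiles, rasterizes the filaments with a Gaussian
#' cross-section, adds diffuse background modulated by a low-order
#' polynomial shading surface, and finally applies Poisson shot noise and
#' Gaussian read noise. Filament contributions from overlapping paths add.
#'
#' @param network list of [path_trace()] as from [generate_network()]; if
#'   `NULL` it is generated from `config`.
#' @param config a [scene_config()].
#' @param compartments data frame of [compartment_spec()] rows (or `NULL`).
#' @return a list with elements `pair` (an [image_pair()]) and `truth`
#'   (class `synthetic_ground_truth`): filament vertex lists, the per-sample
#'   noise-free profiles `s`, `a`, `b` for each filament, the planted
#'   compartment table, `coloc_rho`, noise parameters and seed.
#' @export
render_scene <- function(network = NULL, config, compartments = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (prod(config$image_shape) == 0L) stop("zero-area image")
  if (is.null(network)) network <- generate_network(config)
  validate_compartments(compartments, network, config$pixel_size_um)
  shp <- config$image_shape
  ds <- 0.5  # px; profile sample spacing used for rendering
  bait_img <- matrix(0, shp[1], shp[2])
  prey_img <- matrix(0, shp[1], shp[2])
  profiles <- vector("list", length(network))
  with_seed(derive_seed(config$seed, 0L, stream = 2L), {
    for (k in seq_along(network)) {
      rs <- resample_polyline(network[[k]]$vertices, ds)
      ff <- filament_fields(length(rs$s), config)
      s_um <- rs$s * config$pixel_size_um
      if (!is.null(compartments) && nrow(compartments)) {
        for (i in which(compartments$filament_index == k)) {
          inside <- s_um >= compartments$start_um[i] &
            s_um <= compartments$end_um[i]
          f <- compartments$fold_change[i]
          enriched <- compartments$channel[i]
          if (compartments$mode[i] == "enrichment") {
            if (enriched == "bait") ff$a[inside] <- ff$a[inside] * f
            else ff$b[inside] <- ff$b[inside] * f
          } else {
            if (enriched == "bait") ff$b[inside] <- ff$b[inside] / f
            else ff$a[inside] <- ff$a[inside] / f
          }
        }
      }
      if (config$bait_level > 0)
        bait_img <- bait_img +
          rasterize_filament(shp, rs, ff$a, config$psf_sigma_px)
      if (config$prey_level > 0)
        prey_img <- prey_img +
          rasterize_filament(shp, rs, ff$b, config$psf_sigma_px)
      profiles[[k]] <- list(s_um = s_um, a = ff$a, b = ff$b)
    }
  })
  with_seed(derive_seed(config$seed, 0L, stream = 3L), {
    bg <- matrix(config$background_level, shp[1], shp[2])
    if (config$shading_amplitude > 0 && config$background_level > 0) {
      bg <- bg * (1 + config$shading_amplitude * shading_surface(shp))
    }
    bait_img <- bait_img + bg
    prey_img <- prey_img + bg
  })
  with_seed(derive_seed(config$seed, 0L, stream = 4L), {
    if (config$poisson_noise) {
      bait_img[] <- stats::rpois(length(bait_img), pmax(bait_img, 0))
      prey_img[] <- stats::rpois(length(prey_img), pmax(prey_img, 0))
    }
    if (config$gaussian_sd > 0) {
      bait_img <- bait_img + stats::rnorm(length(bait_img), 0, config$gaussian_sd)
      prey_img <- prey_img + stats::rnorm(length(prey_img), 0, config$gaussian_sd)
    }
  })
  bait_img <- pmax(bait_img, 0)
  prey_img <- pmax(prey_img, 0)
  pair <- image_pair(channel_image(bait_img, config$pixel_size_um, "bait"),
                     channel_image(prey_img, config$pixel_size_um, "prey"))
  truth <- structure(list(
    network = network,
    profiles = profiles,
    compartments = if (is.null(compartments))
      compartment_spec(1L, 0, 1)[0, ] else compartments,
    coloc_rho = config$coloc_rho,
    noise = list(poisson = config$poisson_noise,
                 gaussian_sd = config$gaussian_sd),
    config = config,
    seed = config$seed), class = "synthetic_ground_truth")
  list(pair = pair, truth = truth)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_ground_truth> %d filaments (%.1f um), %d planted compartments, rho %.2f, seed %d\n",
    length(x$network), sum(vapply(x$network, path_length_um, 0)),
    nrow(x$compartments), x$coloc_rho, x$seed))
  invisible(x)
}

#' Simulate a population of single cells for the colocalization assay
#'
#' Draws `n_cells` bait expression levels uniformly over `bait_range`
#' (arbitrary integrated-intensity units) and renders one scene per cell with
#' per-cell true rank correlation `score_true + slope_per_bait * bait_level`.
#' Per-cell seeds derive from `config$seed` by a fixed offset and are
#' recorded in each cell's ground truth.
#'
#' @param n_cells number of cells (>= 3).
#' @param score_true Spearman correlation at zero bait expression.
#' @param slope_per_bait change of the true correlation per bait unit.
#' @param config base [scene_config()]; per-pixel bait intensity is
#'   `config$bait_level * bait_level / mean(bait_range)` so the population
#'   brackets the configured brightness.
#' @param bait_range range of bait levels to draw (default `c(1, 20)` a.u.).
#' @param clip if `TRUE`, per-cell targets outside `[-1, 1]` are clipped;
#'   if `FALSE` (default) such a configuration is an error.
#' @return list of cells, each `list(pair, bait_level, rho_true, truth)`.
#' @export
generate_cell_population <- function(n_cells, score_true, slope_per_bait,
                                     config, bait_range = c(1, 20),
                                     clip = FALSE) {
  if (n_cells < 3) stop("`n_cells` must be >= 3")
  stopifnot(inherits(config, "scene_config"))
  extremes <- score_true + slope_per_bait * bait_range
  if (!clip && any(extremes < -1 | extremes > 1))
    stop("bait range drives the true correlation outside [-1, 1]; ",
         "set clip = TRUE to allow clipping")
  bait_levels <- with_seed(derive_seed(config$seed, 0L, stream = 5L),
                           stats::runif(n_cells, bait_range[1], bait_range[2]))
  lapply(seq_len(n_cells), function(i) {
    rho_i <- min(1, max(-1, score_true + slope_per_bait * bait_levels[i]))
    cfg_i <- config
    cfg_i$coloc_rho <- rho_i
    cfg_i$bait_level <- config$bait_level * bait_levels[i] / mean(bait_range)
    cfg_i$seed <- as.integer(derive_seed(config$seed, i, stream = 6L))
    sc <- render_scene(NULL, cfg_i)
    list(pair = sc$pair, bait_level = bait_levels[i], rho_true = rho_i,
         truth = sc$truth)
  })
}

#' Simulate per-cell colocalization records on a linear bait trend
#'
#' Record-level companion of [generate_cell_population()]: produces the
#' measured per-cell Spearman values directly as
#' `rho_cell = score_true + slope_per_bait * bait + N(0, rho_sd)`, without
#' image rendering. This is the generator used to study the sampling
#' behaviour of [interaction_score()] (confidence-interval coverage).
#'
#' @param n_cells number of cells.
#' @param score_true intercept (true interaction score).
#' @param slope_per_bait linear trend of rho with bait level.
#' @param rho_sd Gaussian measurement noise on rho_cell.
#' @param bait_range uniform range of bait levels.
#' @return data frame with columns `cell_id`, `bait_level`, `rho_cell`,
#'   `flagged` (all `FALSE`), compatible with [interaction_score()].
#' @export
simulate_coloc_records <- function(n_cells, score_true, slope_per_bait = 0,
                                   rho_sd = 0.05, bait_range = c(1, 20)) {
  bait <- stats::runif(n_cells, bait_range[1], bait_range[2])
  rho <- score_true + slope_per_bait * bait + stats::rnorm(n_cells, 0, rho_sd)
  data.frame(cell_id = seq_len(n_cells), bait_level = bait,
             rho_cell = pmin(1, pmax(-1, rho)), flagged = FALSE)
}

#' Render a stress-granule style foci scene
#'
#' Paints `n_foci` disc-shaped foci at `enrichment` times the cytoplasmic
#' level on a uniform cytoplasm, with optional Poisson noise, and returns the
#' image together with the foci and cytoplasm masks (the cytoplasm mask
#' excludes the foci and a one-pixel guard ring).
#'
#' @param shape image shape (rows, cols).
#' @param n_foci number of foci.
#' @param enrichment planted foci/cytoplasm intensity ratio (> 0).
#' @param cyto_level cytoplasm intensity, photons/pixel.
#' @param radius_px focus radius in pixels.
#' @param poisson_noise logical.
#' @param seed integer seed.
#' @return list with `image` ([channel_image()]), `foci_mask`, `cyto_mask`
#'   (logical matrices) and `enrichment_true`.
#' @export
render_foci_scene <- function(shape = c(128L, 128L), n_foci = 8,
                              enrichment = 3, cyto_level = 200,
                              radius_px = 4, poisson_noise = TRUE, seed = 1L) {
  if (enrichment <= 0) stop("`enrichment` must be > 0")
  with_seed(seed, {
    img <- matrix(cyto_level, shape[1], shape[2])
    foci <- matrix(FALSE, shape[1], shape[2])
    rr <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
    centers_r <- stats::runif(n_foci, radius_px + 2, shape[1] - radius_px - 3)
    centers_c <- stats::runif(n_foci, radius_px + 2, shape[2] - radius_px - 3)
    for (i in seq_len(n_foci))
      foci <- foci | ((rr - centers_r[i])^2 + (cc - centers_c[i])^2 <=
                        radius_px^2)
    img[foci] <- cyto_level * enrichment
    guard <- EBImage::dilate(foci * 1, EBImage::makeBrush(3, "box")) > 0
    if (poisson_noise) img[] <- stats::rpois(length(img), img)
    list(image = channel_image(img, channel = "prey"),
         foci_mask = foci, cyto_mask = !guard, enrichment_true = enrichment)
  })
}
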