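# Planted-truth validation benchmarks: the quantitative self-checks the
# synthetic generator makes possible.

#' Planted-compartment recovery benchmark
#'
#' Simulates scenes with fold-change compartments planted at known
#' positions, runs the scoring pipeline (optional preprocessing, profile
#' tracing along the true filament geometry, compartment detection), and
#' scores recovery against the ground truth. A detection counts as a
#' recovery of a plant when it lies on the planted filament, matches its
#' channel and overlaps its arclength interval. A detection counts as a
#' false call when its midpoint lies farther than `influence_px` (the
#' rendering cross-section support plus half the trace thickness) from
#' every planted compartment's image footprint — detections closer than
#' that sit on real enriched signal where another filament crosses a plant.
#'
#' @param n_scenes number of scenes to simulate.
#' @param seed integer seed.
#' @param noise simulate camera noise (Poisson + read noise) and diffuse
#'   background; `FALSE` gives pure noise-free filament scenes.
#' @param fold_change planted ratio fold change.
#' @param plant_len_um planted compartment length range (um).
#' @param plants_per_scene compartments planted per scene.
#' @param image_shape,n_filaments scene geometry.
#' @param smooth_um,min_len_um,signal_floor detector settings (see
#'   [detect_compartments()]).
#' @param influence_px image-space radius of a plant's rendered footprint.
#' @param avoid_crossings when `TRUE` (the noise-free default), candidate
#'   plants whose footprint passes within `influence_px` of another
#'   filament are rejected, so that recovered boundaries and enrichments
#'   are not confounded by overlapping filament signal — a limitation of
#'   the 2-D projection, not of the detector.
#' @return list: `recall`, `false_per_mm`, `total_mm`, `n_planted`,
#'   `n_recovered`, `n_false`, and for recovered plants the vectors
#'   `enrichment` and `length_error_um` (detected minus planted length).
#' @export
benchmark_planted_recovery <- function(n_scenes = 10L, seed = 1L,
                                       noise = TRUE, fold_change = 2,
                                       plant_len_um = c(1.5, 2.5),
                                       plants_per_scene = 12L,
                                       image_shape = c(512L, 512L),
                                       n_filaments = 30L,
                                       smooth_um = if (noise) 0.5 else 0,
                                       min_len_um = if (noise) 0.5 else 0.3,
                                       signal_floor = if (noise) 0.5 else 0,
                                       influence_px = 5,
                                       avoid_crossings = !noise) {
  n_rec <- 0L; n_planted <- 0L; n_false <- 0L; total_mm <- 0
  Es <- numeric(0); dLs <- numeric(0)
  for (sc_i in seq_len(n_scenes)) {
    seed_i <- as.integer(derive_seed(seed, sc_i, stream = 11L))
    cfg <- scene_config(image_shape = image_shape,
                        n_filaments = n_filaments, seed = seed_i,
                        coloc_rho = 1,
                        poisson_noise = noise,
                        gaussian_sd = if (noise) 3 else 0,
                        background_level = if (noise) 30 else 0,
                        shading_amplitude = if (noise) 0.2 else 0)
    net <- generate_network(cfg)
    lens <- vapply(net, path_length_um, 0)
    rs_all <- lapply(net, function(p) resample_polyline(p$vertices, 0.5))
    specs <- with_seed(derive_seed(seed_i, 1L, stream = 12L), {
      out <- NULL
      for (i in seq_len(plants_per_scene)) {
        fil <- 1L + (i - 1L) %% length(net)
        L <- stats::runif(1, plant_len_um[1], plant_len_um[2])
        if (lens[fil] < L + 2) next
        start <- stats::runif(1, 1, lens[fil] - L - 1)
        clash <- !is.null(out) &&
          any(out$filament_index == fil & out$start_um < start + L + 1 &
                out$end_um > start - 1)
        if (clash) next
        if (avoid_crossings) {
          rs <- rs_all[[fil]]
          s_um <- rs$s * cfg$pixel_size_um
          k <- s_um >= start & s_um <= start + L
          others <- do.call(rbind, lapply(rs_all[-fil], function(q)
            cbind(q$r, q$c)))
          if (!is.null(others) && length(which(k))) {
            dmin <- min(vapply(which(k), function(ii)
              min((others[, 1] - rs$r[ii])^2 + (others[, 2] - rs$c[ii])^2),
              0))
            if (sqrt(dmin) <= influence_px) next
          }
        }
        out <- rbind(out, compartment_spec(
          fil, start, start + L,
          channel = if (i %% 2L) "bait" else "prey",
          fold_change = fold_change))
      }
      out
    })
    rend <- render_scene(net, cfg, specs)
    pair <- if (noise) preprocess_pair(rend$pair) else rend$pair
    profiles <- lapply(net, function(p) trace_profile(pair, p))
    total_mm <- total_mm +
      sum(vapply(profiles, function(p) max(p$s), 0)) / 1000
    det <- do.call(rbind, lapply(seq_along(profiles), function(i) {
      d <- detect_compartments(profiles[[i]], smooth_um = smooth_um,
                               min_len_um = min_len_um,
                               signal_floor = signal_floor)
      if (nrow(d)) { d$path_id <- i; d } else NULL
    }))
    # image footprint of every plant, for the false-call distance rule
    foot_r <- numeric(0); foot_c <- numeric(0)
    for (j in seq_len(nrow(specs))) {
      rs <- resample_polyline(net[[specs$filament_index[j]]]$vertices, 0.5)
      s_um <- rs$s * cfg$pixel_size_um
      k <- s_um >= specs$start_um[j] & s_um <= specs$end_um[j]
      foot_r <- c(foot_r, rs$r[k]); foot_c <- c(foot_c, rs$c[k])
    }
    n_planted <- n_planted + nrow(specs)
    for (j in seq_len(nrow(specs))) {
      hit <- !is.null(det) &&
        any(det$path_id == specs$filament_index[j] &
              det$channel == specs$channel[j] &
              det$start_um < specs$end_um[j] &
              det$end_um > specs$start_um[j])
      if (hit) {
        n_rec <- n_rec + 1L
        w <- which(det$path_id == specs$filament_index[j] &
                     det$channel == specs$channel[j] &
                     det$start_um < specs$end_um[j] &
                     det$end_um > specs$start_um[j])[1]
        Es <- c(Es, det$enrichment[w])
        dLs <- c(dLs, det$length_um[w] -
                   (specs$end_um[j] - specs$start_um[j]))
      }
    }
    if (!is.null(det)) for (r in seq_len(nrow(det))) {
      rs <- resample_polyline(net[[det$path_id[r]]]$vertices, 0.5)
      mid_px <- (det$start_um[r] + det$end_um[r]) / 2 / cfg$pixel_size_um
      i <- which.min(abs(rs$s - mid_px))
      dmin <- sqrt(min((foot_r - rs$r[i])^2 + (foot_c - rs$c[i])^2))
      if (dmin > influence_px) n_false <- n_false + 1L
    }
  }
  list(recall = n_rec / n_planted, false_per_mm = n_false / total_mm,
       total_mm = total_mm, n_planted = n_planted, n_recovered = n_rec,
       n_false = n_false, enrichment = Es, length_error_um = dLs)
}

#' Coverage of the interaction-score confidence interval
#'
#' Simulates replicate cell populations on a linear bait trend with
#' Gaussian noise on the per-cell Spearman value, fits the zero-bait
#' extrapolation on each, and reports how often the 95% interval covers
#' the true intercept.
#'
#' @param n_rep number of replicate populations.
#' @param n_cells cells per population.
#' @param score_true true intercept.
#' @param slope_per_bait true trend.
#' @param rho_sd per-cell noise sd.
#' @param seed integer seed.
#' @return list: `coverage` (fraction), `n_rep`, mean `score` estimate.
#' @export
benchmark_score_coverage <- function(n_rep = 500L, n_cells = 20L,
                                     score_true = 0.3,
                                     slope_per_bait = 0.02, rho_sd = 0.05,
                                     seed = 1L) {
  with_seed(derive_seed(seed, 0L, stream = 13L), {
    cover <- logical(n_rep); est <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      rec <- simulate_coloc_records(n_cells, score_true, slope_per_bait,
                                    rho_sd)
      s <- interaction_score(rec)
      cover[i] <- s$ci_low <= score_true && score_true <= s$ci_high
      est[i] <- s$score
    }
    list(coverage = mean(cover), n_rep = n_rep, mean_score = mean(est))
  })
}

#' Type-I error calibration of the population tests
#'
#' Draws replicate pairs of same-distribution samples and reports the
#' rejection rates of the two-sample KS and Welch t tests at `alpha`.
#'
#' @param n_rep replicates.
#' @param n per-group sample size.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return list: `ks_rate`, `t_rate`, `n_rep`.
#' @export
benchmark_type1 <- function(n_rep = 1000L, n = 90L, alpha = 0.01,
                            seed = 1L) {
  with_seed(derive_seed(seed, 0L, stream = 14L), {
    ks_rej <- 0L; t_rej <- 0L
    for (i in seq_len(n_rep)) {
      x <- stats::rnorm(n, 1.5, 0.4)
      y <- stats::rnorm(n, 1.5, 0.4)
      if (suppressWarnings(stats::ks.test(x, y)$p.value) < alpha)
        ks_rej <- ks_rej + 1L
      if (stats::t.test(x, y)$p.value < alpha) t_rej <- t_rej + 1L
    }
    list(ks_rate = ks_rej / n_rep, t_rate = t_rej / n_rep, n_rep = n_rep)
  })
}
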