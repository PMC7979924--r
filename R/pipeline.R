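# End-to-end orchestration: simulate, preprocess, score, detect, test, report.

#' Pipeline run configuration
#'
#' Bundles every stage toggle and parameter of an end-to-end run. The
#' configuration (including the seed) is echoed into every report, and an
#' identical configuration yields a byte-identical report.
#'
#' @param seed top-level integer seed; every stage derives its own stream
#'   from it.
#' @param stages named logical list toggling `simulate`, `preprocess`,
#'   `coloc`, `compartments`, `stats`.
#' @param scene named list of [scene_config()] overrides shared by all
#'   simulated conditions (e.g. `image_shape`, `bait_level`).
#' @param conditions list of condition descriptors for the demixing arm;
#'   each is a list with `name`, `role` (`"mutant"` or `"control"`),
#'   `n_images`, `compartments_per_image`, `fold_range`, and optionally
#'   `channel` (`"bait"`, `"prey"` or `"alternate"`).
#' @param coloc list: `n_cells`, `score_true`, `slope_per_bait`,
#'   `roi_px` (ROI side), `bait_range`.
#' @param preprocess list: `large_cut_um`, `small_cut_px`, `taper`,
#'   `bg_radius_um`.
#' @param detect list: `threshold`, `thickness_px`, `min_len_um`,
#'   `merge_gap_um`, `smooth_um`.
#' @param stats list: `alpha`, `feature`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       stages = list(simulate = TRUE, preprocess = TRUE,
                                     coloc = TRUE, compartments = TRUE,
                                     stats = TRUE),
                       scene = list(),
                       conditions = default_conditions(),
                       coloc = list(n_cells = 8L, score_true = 0.5,
                                    slope_per_bait = 0, roi_px = 48L,
                                    bait_range = c(1, 20)),
                       preprocess = list(large_cut_um = 5, small_cut_px = 2,
                                         taper = 0.1, bg_radius_um = 2),
                       detect = list(threshold = 0.20, thickness_px = 4,
                                     min_len_um = 0.3, merge_gap_um = 0.2,
                                     smooth_um = 0.5),
                       stats = list(alpha = 0.01, feature = "enrichment")) {
  defaults <- formals(run_config)
  cfg <- list(seed = as.integer(seed),
              stages = utils::modifyList(eval(defaults$stages), stages),
              scene = scene,
              conditions = conditions,
              coloc = utils::modifyList(eval(defaults$coloc), coloc),
              preprocess = utils::modifyList(eval(defaults$preprocess),
                                             preprocess),
              detect = utils::modifyList(eval(defaults$detect), detect),
              stats = utils::modifyList(eval(defaults$stats), stats),
              version = as.character(utils::packageVersion("mtbench")))
  structure(cfg, class = "run_config")
}

#' Default demixing conditions: one mutant against four passive controls
#' @return list of condition descriptors (see [run_config()]).
#' @export
default_conditions <- function() {
  ctrl <- function(i) list(name = paste0("control", i), role = "control",
                           n_images = 3L, compartments_per_image = 4L,
                           fold_range = c(1.25, 1.45), channel = "alternate")
  c(list(list(name = "mutant", role = "mutant", n_images = 3L,
              compartments_per_image = 8L, fold_range = c(1.9, 2.4),
              channel = "alternate")),
    lapply(1:4, ctrl))
}

#' Serialize / restore a run configuration (YAML)
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config), precision = 15L), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(seed = raw$seed, stages = raw$stages,
                    scene = raw$scene %||% list(),
                    conditions = raw$conditions,
                    coloc = raw$coloc, preprocess = raw$preprocess,
                    detect = raw$detect, stats = raw$stats)
  cfg
}

scene_from_cfg <- function(config, seed, overrides = list()) {
  args <- utils::modifyList(config$scene, overrides)
  args$seed <- seed
  do.call(scene_config, args)
}

# Draw planted compartments for one image under a condition regime.
draw_condition_compartments <- function(network, cond, pixel_size_um) {
  specs <- NULL
  k <- cond$compartments_per_image
  if (k == 0L) return(NULL)
  lens <- vapply(network, path_length_um, 0)
  for (i in seq_len(k)) {
    for (try in 1:20) {
      fil <- sample.int(length(network), 1L)
      L <- stats::runif(1, 1.0, 3.0)
      if (lens[fil] < L + 1) next
      start <- stats::runif(1, 0.5, lens[fil] - L - 0.5)
      ch <- switch(cond$channel %||% "alternate",
                   alternate = if (i %% 2L) "bait" else "prey",
                   cond$channel)
      cand <- compartment_spec(fil, start, start + L, channel = ch,
                               fold_change = stats::runif(1,
                                                          cond$fold_range[1],
                                                          cond$fold_range[2]))
      clash <- !is.null(specs) &&
        any(specs$filament_index == fil &
              specs$start_um < cand$end_um + 0.5 &
              specs$end_um > cand$start_um - 0.5)
      if (!clash) { specs <- rbind(specs, cand); break }
    }
  }
  specs
}

#' Run the full microtubule-bench pipeline
#'
#' Simulates (or would load) the per-condition scenes, preprocesses them,
#' scores colocalization on a simulated cell population, detects and pools
#' compartments per condition, compares the mutant condition against every
#' control and classifies its demixing. All stage outputs are returned and,
#' when `out_dir` is given, written as CSV tables plus a plain-text report
#' that embeds the configuration and seed. The report is a pure function of
#' (config, seed): identical inputs give byte-identical files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created); `NULL` returns results only.
#' @param quiet suppress per-stage progress messages.
#' @return object of class `run_report` (list with `config`, `populations`,
#'   `summaries`, `interaction`, `comparisons`, `classification`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(stage, t0) if (!quiet)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(Sys.time()) - t0))
  res <- list(config = config, populations = list(), summaries = NULL,
              interaction = NULL, comparisons = NULL, classification = NULL)
  st <- config$stages
  bp <- bandpass_spec(config$preprocess$large_cut_um,
                      config$preprocess$small_cut_px,
                      config$preprocess$taper)

  if (st$simulate && st$compartments) {
    t0 <- as.numeric(Sys.time())
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[[ci]]
      profiles <- list()
      for (im in seq_len(cond$n_images)) {
        seed_i <- as.integer(derive_seed(config$seed, ci * 100L + im))
        cfg_i <- scene_from_cfg(config, seed_i,
                                list(coloc_rho = 1))
        net <- generate_network(cfg_i)
        plant <- with_seed(derive_seed(seed_i, 1L, stream = 7L),
                           draw_condition_compartments(net, cond,
                                                       cfg_i$pixel_size_um))
        sc <- tryCatch(render_scene(net, cfg_i, plant),
                       error = function(e)
                         stop("stage simulate failed on condition '",
                              cond$name, "' image ", im, ": ",
                              conditionMessage(e)))
        pair <- if (st$preprocess)
          preprocess_pair(sc$pair, bp, config$preprocess$bg_radius_um)
        else sc$pair
        for (p in net) {
          p$thickness_px <- config$detect$thickness_px
          profiles[[length(profiles) + 1L]] <- tryCatch(
            trace_profile(pair, p),
            error = function(e)
              stop("stage compartments failed on condition '", cond$name,
                   "': ", conditionMessage(e)))
        }
      }
      res$populations[[cond$name]] <- aggregate_population(
        profiles, condition = cond$name,
        threshold = config$detect$threshold,
        min_len_um = config$detect$min_len_um,
        merge_gap_um = config$detect$merge_gap_um,
        smooth_um = config$detect$smooth_um)
    }
    res$summaries <- do.call(rbind, lapply(res$populations, summary))
    rownames(res$summaries) <- NULL
    say("simulate+compartments", t0)
  }

  if (st$simulate && st$coloc) {
    t0 <- as.numeric(Sys.time())
    cc <- config$coloc
    cfg_c <- scene_from_cfg(config,
                            as.integer(derive_seed(config$seed, 31L)))
    cells <- generate_cell_population(cc$n_cells, cc$score_true,
                                      cc$slope_per_bait, cfg_c,
                                      bait_range = cc$bait_range)
    records <- do.call(rbind, lapply(seq_along(cells), function(i) {
      pair <- if (st$preprocess) preprocess_pair(cells[[i]]$pair, bp,
                                                 config$preprocess$bg_radius_um)
      else cells[[i]]$pair
      rois <- place_rois(pair, 3L, cc$roi_px, cc$roi_px)
      rec <- measure_cell(pair, rois, cell_id = i)
      rec$bait_level <- cells[[i]]$bait_level
      rec
    }))
    res$coloc_records <- records
    res$interaction <- tryCatch(interaction_score(records),
                                error = function(e) NULL)
    say("coloc", t0)
  }

  if (st$stats && length(res$populations) > 1L) {
    t0 <- as.numeric(Sys.time())
    roles <- vapply(config$conditions, `[[`, "", "role")
    names(roles) <- vapply(config$conditions, `[[`, "", "name")
    mutants <- names(roles)[roles == "mutant"]
    controls <- names(roles)[roles == "control"]
    comps <- list(); cls <- list()
    for (m in mutants) {
      per_ctrl <- do.call(rbind, lapply(controls, function(ctl)
        compare_populations(res$populations[[m]],
                            res$populations[[ctl]],
                            feature = config$stats$feature)))
      comps[[m]] <- per_ctrl
      cls[[m]] <- classify_demixing(per_ctrl, alpha = config$stats$alpha,
                                    mutant = m)
    }
    res$comparisons <- do.call(rbind, comps)
    rownames(res$comparisons) <- NULL
    res$classification <- do.call(rbind, cls)
    rownames(res$classification) <- NULL
    say("stats", t0)
  }

  report <- structure(res, class = "run_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

num_fmt <- function(x) {
  if (is.numeric(x)) sprintf("%.6g", x) else as.character(x)
}

write_table_det <- function(d, path) {
  d2 <- as.data.frame(lapply(d, function(col)
    if (is.numeric(col)) sprintf("%.10g", col) else col))
  names(d2) <- names(d)
  utils::write.csv(d2, path, row.names = FALSE, quote = FALSE)
}

#' Write a pipeline report to disk
#'
#' Produces `config.yaml`, `tables/*.csv` and `report.txt` under `out_dir`.
#' Content contains no timestamps or absolute paths, so identical runs give
#' byte-identical files.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(file.path(out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  write_run_config(report$config, file.path(out_dir, "config.yaml"))
  lines <- c("# mtbench run report", "",
             paste0("seed: ", report$config$seed),
             paste0("version: ", report$config$version), "")
  if (!is.null(report$summaries)) {
    write_table_det(report$summaries,
                    file.path(out_dir, "tables", "population_summary.csv"))
    pooled <- do.call(rbind, lapply(report$populations, function(p) {
      cc <- p$compartments
      if (nrow(cc)) cbind(condition = p$condition, cc) else NULL
    }))
    if (!is.null(pooled))
      write_table_det(pooled,
                      file.path(out_dir, "tables", "compartments.csv"))
    lines <- c(lines, "## Compartment populations",
               utils::capture.output(print(format(report$summaries,
                                                  digits = 6))), "")
  }
  if (!is.null(report$coloc_records)) {
    write_table_det(report$coloc_records,
                    file.path(out_dir, "tables", "coloc_records.csv"))
  }
  if (!is.null(report$interaction)) {
    s <- report$interaction
    write_table_det(data.frame(score = s$score, ci_low = s$ci_low,
                               ci_high = s$ci_high, slope = s$slope,
                               n_cells = s$n_cells,
                               n_excluded = s$n_excluded),
                    file.path(out_dir, "tables", "interaction_score.csv"))
    lines <- c(lines, "## Interaction score",
               sprintf("score %.6g [%.6g, %.6g], slope %.6g, n = %d",
                       s$score, s$ci_low, s$ci_high, s$slope, s$n_cells), "")
  }
  if (!is.null(report$comparisons)) {
    write_table_det(report$comparisons,
                    file.path(out_dir, "tables", "comparisons.csv"))
    write_table_det(report$classification,
                    file.path(out_dir, "tables", "classification.csv"))
    lines <- c(lines, "## Demixing classification (no multiple-testing correction)",
               utils::capture.output(print(format(report$classification,
                                                  digits = 6))), "")
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (!is.null(x$summaries)) print(x$summaries, digits = 4)
  if (!is.null(x$interaction)) print(x$interaction)
  if (!is.null(x$classification)) print(x$classification, digits = 4)
  invisible(x)
}
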