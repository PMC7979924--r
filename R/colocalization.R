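# Per-cell Spearman colocalization and the zero-bait interaction score.

#' Rectangular region of interest
#'
#' ROIs have a fixed area within one analysis to avoid biasing the
#' correlation by the surface considered; [measure_cell()] enforces this.
#'
#' @param row,col top-left corner, 0-based pixel indices.
#' @param height,width extent in pixels.
#' @return object of class `roi`.
#' @export
roi <- function(row, col, height = 100L, width = 100L) {
  if (height < 1 || width < 1) stop("ROI must have positive extent")
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

roi_pixels <- function(img, r) {
  nr <- nrow(img); nc <- ncol(img)
  if (r$row < 0 || r$col < 0 || r$row + r$height > nr || r$col + r$width > nc)
    stop("ROI extends outside the image")
  img[r$row + seq_len(r$height), r$col + seq_len(r$width), drop = FALSE]
}

#' Spearman colocalization within one ROI
#'
#' Rank correlation (average ranks for ties) of paired bait/prey pixel
#' intensities inside the ROI. The rank correlation is preferred over
#' Pearson because fluorescence may grow nonlinearly with the number of
#' molecules; any strictly increasing transform of either channel leaves it
#' unchanged. The pair is expected to be bandpass-filtered first (see
#' [preprocess_pair()]).
#'
#' @param pair an [image_pair()].
#' @param roi an [roi()] of at least 25 px².
#' @return the Spearman coefficient, or `NA` with attribute
#'   `"constant_channel"` naming the degenerate channel(s) when the
#'   correlation is undefined (a constant channel is flagged, never silently
#'   scored 0).
#' @export
spearman_roi <- function(pair, roi) {
  stopifnot(inherits(pair, "image_pair"), inherits(roi, "roi"))
  if (roi$height * roi$width < 25) stop("ROI smaller than 25 px^2")
  x <- as.vector(roi_pixels(pair$bait$pixels, roi))
  y <- as.vector(roi_pixels(pair$prey$pixels, roi))
  const <- c(bait = length(unique(x)) == 1L, prey = length(unique(y)) == 1L)
  if (any(const)) {
    out <- NA_real_
    attr(out, "constant_channel") <- names(const)[const]
    return(out)
  }
  stats::cor(x, y, method = "spearman")
}

#' Place fixed-area ROIs on microtubule-rich regions
#'
#' Mimics the manual choice of regions "where microtubules are clearly
#' observed in the bait image": slides a window over the bait channel and
#' greedily picks the `n` non-overlapping windows with the highest mean bait
#' intensity. Deterministic.
#'
#' @param pair an [image_pair()].
#' @param n number of ROIs (default 3).
#' @param height,width ROI extent in pixels (fixed area; default 100 x 100).
#' @param stride sliding step in pixels.
#' @return list of [roi()].
#' @export
place_rois <- function(pair, n = 3L, height = 100L, width = 100L,
                       stride = 8L) {
  stopifnot(inherits(pair, "image_pair"))
  img <- pair$bait$pixels
  nr <- nrow(img); nc <- ncol(img)
  if (nr < height || nc < width) stop("image smaller than the ROI")
  cs <- apply(apply(img, 2, cumsum), 1, cumsum)  # transposed integral image
  boxmean <- function(r0, c0) {  # 0-based top-left
    r1 <- r0 + height; c1 <- c0 + width
    tot <- cs[c1, r1] - (if (c0 > 0) cs[c0, r1] else 0) -
      (if (r0 > 0) cs[c1, r0] else 0) +
      (if (r0 > 0 && c0 > 0) cs[c0, r0] else 0)
    tot / (height * width)
  }
  rows <- seq(0L, nr - height, by = stride)
  cols <- seq(0L, nc - width, by = stride)
  grid <- expand.grid(r = rows, c = cols)
  grid$score <- mapply(boxmean, grid$r, grid$c)
  grid <- grid[order(-grid$score, grid$r, grid$c), ]
  chosen <- list()
  for (i in seq_len(nrow(grid))) {
    if (length(chosen) == n) break
    cand <- grid[i, ]
    overlap <- any(vapply(chosen, function(r)
      cand$r < r$row + height && cand$r + height > r$row &&
        cand$c < r$col + width && cand$c + width > r$col, TRUE))
    if (!overlap)
      chosen[[length(chosen) + 1L]] <- roi(cand$r, cand$c, height, width)
  }
  if (length(chosen) < n) stop("could not place ", n, " disjoint ROIs")
  chosen
}

#' Measure one cell: per-ROI Spearman, cell mean, and bait expression
#'
#' Scores the three fixed-area ROIs of one cell and integrates the bait
#' intensity over the cell mask as the expression proxy. A cell with any
#' undefined ROI correlation is flagged (and later excluded from the
#' extrapolation fit).
#'
#' @param pair a preprocessed [image_pair()].
#' @param rois list of exactly 3 disjoint [roi()] (default per-analysis).
#' @param cell_mask logical matrix delimiting the cell; default whole image.
#' @param cell_id identifier stored in the record.
#' @return one-row data frame: `cell_id`, `rho_1..rho_3`, `rho_cell`,
#'   `bait_level`, `flagged`.
#' @export
measure_cell <- function(pair, rois, cell_mask = NULL, cell_id = 1L) {
  stopifnot(inherits(pair, "image_pair"))
  if (length(rois) != 3L) stop("exactly 3 ROIs are required per cell")
  areas <- vapply(rois, function(r) r$height * r$width, 0)
  if (length(unique(areas)) != 1L)
    stop("all ROIs must have the same fixed area")
  for (i in 1:2) for (j in (i + 1):3) {
    a <- rois[[i]]; b <- rois[[j]]
    if (a$row < b$row + b$height && a$row + a$height > b$row &&
        a$col < b$col + b$width && a$col + a$width > b$col)
      stop("ROIs must be disjoint")
  }
  if (is.null(cell_mask))
    cell_mask <- matrix(TRUE, nrow(pair$bait$pixels), ncol(pair$bait$pixels))
  rho <- vapply(rois, function(r) as.numeric(spearman_roi(pair, r)), 0)
  flagged <- any(is.na(rho))
  data.frame(cell_id = cell_id, rho_1 = rho[1], rho_2 = rho[2],
             rho_3 = rho[3],
             rho_cell = if (flagged) NA_real_ else mean(rho),
             bait_level = sum(pair$bait$pixels[cell_mask]),
             flagged = flagged)
}

#' Interaction score: Spearman extrapolated to zero bait expression
#'
#' Fits ordinary least squares of the per-cell Spearman coefficient against
#' bait expression and reports the intercept — the colocalization expected
#' at vanishing bait level, where confinement artefacts are minimal — with
#' its 95% confidence bounds (t distribution, n - 2 df). The slope is kept
#' for diagnostics. Flagged cells (undefined rho) are excluded and counted.
#'
#' @param records data frame with columns `rho_cell`, `bait_level` and
#'   optionally `flagged` (rows from [measure_cell()] or
#'   [simulate_coloc_records()]).
#' @param conf confidence level (default 0.95).
#' @return object of class `interaction_score`: `score`, `ci_low`,
#'   `ci_high`, `slope`, `n_cells`, `n_excluded`.
#' @export
interaction_score <- function(records, conf = 0.95) {
  stopifnot(is.data.frame(records),
            all(c("rho_cell", "bait_level") %in% names(records)))
  excl <- if ("flagged" %in% names(records)) records$flagged else FALSE
  excl <- excl | is.na(records$rho_cell)
  d <- records[!excl, ]
  if (nrow(d) < 5) stop("need >= 5 usable cells for the extrapolation")
  if (length(unique(d$bait_level)) == 1L)
    stop("all bait levels equal; extrapolation impossible")
  fit <- stats::lm(rho_cell ~ bait_level, data = d)
  co <- stats::coef(fit)
  # a perfect fit legitimately yields a zero-width interval
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  tq <- stats::qt(1 - (1 - conf) / 2, df = nrow(d) - 2L)
  structure(list(score = unname(co[1]),
                 ci_low = unname(co[1] - tq * se[1]),
                 ci_high = unname(co[1] + tq * se[1]),
                 slope = unname(co[2]),
                 n_cells = nrow(d), n_excluded = sum(excl),
                 conf = conf),
            class = "interaction_score")
}

#' @export
print.interaction_score <- function(x, ...) {
  cat(sprintf(
    "Interaction score: %.3f  [%.3f, %.3f] %g%% CI  (slope %.4g, n = %d%s)\n",
    x$score, x$ci_low, x$ci_high, 100 * x$conf, x$slope, x$n_cells,
    if (x$n_excluded > 0) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}
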