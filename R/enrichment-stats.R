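# Population comparisons, demixing classification, foci enrichment, slopes.

#' Compare a compartment feature between two populations
#'
#' Two-tailed Welch t test and two-sample Kolmogorov-Smirnov test on the
#' chosen per-compartment feature (`stats::ks.test` uses the exact null
#' distribution for small tie-free samples and the asymptotic one
#' otherwise). For `count_per_mm` the feature vectors are the per-path
#' compartment densities.
#'
#' @param a,b `compartment_population` objects.
#' @param feature `"enrichment"`, `"length_um"`, or `"count_per_mm"`.
#' @param pooled_variance if `TRUE`, use the pooled-variance Student t
#'   instead of Welch.
#' @return data frame: `condition_a`, `condition_b`, `feature`, `t_p`,
#'   `ks_p`, `ks_stat`, `n_a`, `n_b`, `t_flagged` (TRUE when the t test is
#'   undefined for degenerate zero-variance data).
#' @export
compare_populations <- function(a, b,
                                feature = c("enrichment", "length_um",
                                            "count_per_mm"),
                                pooled_variance = FALSE) {
  stopifnot(inherits(a, "compartment_population"),
            inherits(b, "compartment_population"))
  feature <- match.arg(feature)
  fv <- function(p) {
    if (feature == "count_per_mm") {
      counts <- tabulate(
        factor(p$compartments$path_id,
               levels = seq_along(p$path_lengths_um)),
        nbins = length(p$path_lengths_um))
      counts / (p$path_lengths_um / 1000)
    } else p$compartments[[feature]]
  }
  x <- fv(a); y <- fv(b)
  if (!length(x) || !length(y)) stop("empty feature vector")
  if (feature != "count_per_mm" && (length(x) < 3 || length(y) < 3))
    stop("need >= 3 compartments per population for feature '", feature, "'")
  t_flagged <- stats::var(x) == 0 && stats::var(y) == 0
  t_p <- if (t_flagged) NA_real_ else
    stats::t.test(x, y, alternative = "two.sided",
                  var.equal = pooled_variance)$p.value
  ks <- suppressWarnings(stats::ks.test(x, y))
  data.frame(condition_a = a$condition, condition_b = b$condition,
             feature = feature, t_p = t_p, ks_p = ks$p.value,
             ks_stat = unname(ks$statistic),
             n_a = length(x), n_b = length(y), t_flagged = t_flagged,
             stringsAsFactors = FALSE)
}

#' Classify a mutant's demixing against multiple controls
#'
#' Counts how many control comparisons are significant at `alpha` using the
#' KS p-value as the primary criterion (the more reliable of the two tests
#' for these populations) and maps the count to a class: `>= 4` significant
#' controls gives `"significant-4plus"`, `>= 2` gives
#' `"significant-2plus"`, anything less is `"not-significant"`. The t-test
#' count is reported alongside for transparency. No multiple-testing
#' correction is applied across mutants; downstream reports note this.
#'
#' @param comparisons data frame of rows from [compare_populations()], one
#'   per control, for a single mutant.
#' @param alpha significance level (default 0.01).
#' @param mutant label stored in the result.
#' @return data frame: `mutant`, `n_controls`, `n_significant_ks`,
#'   `n_significant_t`, `class`.
#' @export
classify_demixing <- function(comparisons, alpha = 0.01, mutant = "mutant") {
  stopifnot(is.data.frame(comparisons), "ks_p" %in% names(comparisons))
  if (nrow(comparisons) < 4)
    stop("need >= 4 control comparisons for the >=2/>=4 classification")
  n_ks <- sum(comparisons$ks_p < alpha, na.rm = TRUE)
  n_t <- sum(comparisons$t_p < alpha, na.rm = TRUE)
  cls <- if (n_ks >= 4) "significant-4plus"
  else if (n_ks >= 2) "significant-2plus"
  else "not-significant"
  data.frame(mutant = mutant, n_controls = nrow(comparisons),
             n_significant_ks = n_ks, n_significant_t = n_t, class = cls,
             stringsAsFactors = FALSE)
}

#' Foci enrichment of a channel
#'
#' Mean intensity over the foci mask divided by the mean over the
#' cytoplasm mask — the per-cell enrichment of a protein in stress
#' granules (or any foci) relative to its overall cytoplasmic level.
#'
#' @param image a [channel_image()].
#' @param foci_mask,cyto_mask logical matrices of the image shape; the
#'   cytoplasm mask must exclude the foci.
#' @return the enrichment ratio (scalar).
#' @export
foci_enrichment <- function(image, foci_mask, cyto_mask) {
  stopifnot(inherits(image, "channel_image"))
  if (!identical(dim(foci_mask), dim(image$pixels)) ||
      !identical(dim(cyto_mask), dim(image$pixels)))
    stop("masks must match the image shape")
  if (!any(foci_mask)) stop("empty foci mask")
  if (!any(cyto_mask)) stop("empty cytoplasm mask")
  if (any(foci_mask & cyto_mask))
    stop("cytoplasm mask must exclude the foci")
  mean(image$pixels[foci_mask]) / mean(image$pixels[cyto_mask])
}

#' Least-squares slope with 95% confidence bounds
#'
#' Ordinary least squares of `y` on `x`; the slope's confidence interval
#' uses the t distribution with n - 2 degrees of freedom. Serves the
#' enrichment-versus-expression fits (foci enrichment of one marker versus
#' another, prey-versus-bait intensity, signal-versus-expression scatters).
#'
#' @param x,y numeric vectors of equal length (>= 3 points); or `x` a
#'   two-column data frame / matrix of (x, y).
#' @param conf confidence level (default 0.95).
#' @return object of class `slope_fit`: `slope`, `intercept`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
fit_slope <- function(x, y = NULL, conf = 0.95) {
  if (is.null(y)) {
    stopifnot(NCOL(x) == 2)
    y <- x[, 2]; x <- x[, 1]
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need >= 3 points")
  if (length(unique(x)) == 1L) stop("all x equal; slope undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  # a perfect fit legitimately yields a zero-width interval
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  tq <- stats::qt(1 - (1 - conf) / 2, df = length(x) - 2L)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 ci_low = unname(co[2] - tq * se[2]),
                 ci_high = unname(co[2] + tq * se[2]),
                 n = length(x), conf = conf),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Slope: %.4g  [%.4g, %.4g] %g%% CI  (intercept %.4g, n = %d)\n",
              x$slope, x$ci_low, x$ci_high, 100 * x$conf, x$intercept, x$n))
  invisible(x)
}

#' Fraction of values above a threshold
#'
#' Scatter/threshold utility for fraction-positive readouts (e.g.
#' label-positive cells versus expression level).
#'
#' @param values numeric vector.
#' @param threshold positivity cutoff (strictly greater than).
#' @return fraction in `[0, 1]`.
#' @export
fraction_positive <- function(values, threshold) {
  if (!length(values)) stop("empty input")
  mean(values > threshold)
}
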