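# Ratio profiling along traced filaments and the mixing/demixing detector.

#' Extract a two-channel intensity profile along a traced path
#'
#' Resamples the polyline at `step_px` arclength steps and, at each sample,
#' averages each channel over `thickness_px` bilinear samples placed
#' symmetrically along the local normal (the equivalent of a thick ImageJ
#' line profile). The normalized log-ratio
#' `lam(s) = log(a(s) / mean(a)) - log(b(s) / mean(b))`
#' compares the bait's local share of its own signal to the prey's;
#' `lam = 0` means perfectly mixed. Intensities below `1e-3` times the
#' channel mean are floored before the logs.
#'
#' @param pair an [image_pair()] (typically preprocessed).
#' @param path a [path_trace()]; every thickness sample must fall inside the
#'   image.
#' @param step_px arclength sampling step in pixels (default 1).
#' @return object of class `ratio_profile`: `s` (arclength, um), `a`, `b`
#'   (mean bait/prey intensity across the thickness), `lam`, plus the
#'   trace metadata.
#' @export
trace_profile <- function(pair, path, step_px = 1) {
  stopifnot(inherits(pair, "image_pair"), inherits(path, "path_trace"))
  img_b <- pair$bait$pixels; img_p <- pair$prey$pixels
  rs <- resample_polyline(path$vertices, step_px)
  t_px <- path$thickness_px
  offsets <- seq(-(t_px - 1) / 2, (t_px - 1) / 2, length.out = t_px)
  n <- length(rs$s)
  # normals: rotate unit tangents by 90 degrees
  nr_ <- -rs$tc; nc_ <- rs$tr
  R <- outer(rs$r, rep(1, t_px)) + outer(nr_, offsets)
  C <- outer(rs$c, rep(1, t_px)) + outer(nc_, offsets)
  bad <- R < 0 | R > nrow(img_b) - 1 | C < 0 | C > ncol(img_b) - 1
  if (any(bad)) {
    first <- which(rowSums(bad) > 0)[1]
    stop(sprintf(
      "path leaves the image at arclength sample %d (%.1f, %.1f) px",
      first, rs$r[first], rs$c[first]))
  }
  a <- rowMeans(matrix(bilinear(img_b, as.vector(R), as.vector(C)), n, t_px))
  b <- rowMeans(matrix(bilinear(img_p, as.vector(R), as.vector(C)), n, t_px))
  ratio_profile(s = rs$s * path$pixel_size_um, a = a, b = b,
                pixel_size_um = path$pixel_size_um)
}

#' Construct a ratio profile from arclength-sampled intensities
#'
#' @param s arclength samples in micrometres, strictly increasing.
#' @param a,b mean bait / prey intensities at each sample (>= 0).
#' @param pixel_size_um pixel size metadata.
#' @param path_id identifier carried into compartment tables.
#' @param eps_frac flooring fraction: intensities below `eps_frac * mean`
#'   are floored before taking logs (default 1e-3).
#' @return object of class `ratio_profile`.
#' @export
ratio_profile <- function(s, a, b, pixel_size_um = 0.1, path_id = 1L,
                          eps_frac = 1e-3) {
  if (length(s) < 2L || any(diff(s) <= 0))
    stop("`s` must be strictly increasing with >= 2 samples")
  if (length(a) != length(s) || length(b) != length(s))
    stop("`a`, `b` must match `s` in length")
  if (mean(a) <= 0 || mean(b) <= 0)
    stop("channel means must be positive to form the ratio")
  af <- pmax(a, eps_frac * mean(a))
  bf <- pmax(b, eps_frac * mean(b))
  lam <- log(af / mean(af)) - log(bf / mean(bf))
  structure(list(s = s, a = af, b = bf, lam = lam,
                 pixel_size_um = pixel_size_um, path_id = path_id),
            class = "ratio_profile")
}

#' @export
print.ratio_profile <- function(x, ...) {
  cat(sprintf("<ratio_profile> path %s, %d samples over %.2f um, |lam| max %.3f\n",
              x$path_id, length(x$s), max(x$s) - min(x$s), max(abs(x$lam))))
  invisible(x)
}

#' Detect demixed compartments along one profile
#'
#' A compartment is a maximal run of consecutive samples whose normalized
#' log-ratio magnitude exceeds the threshold: `|lam(s)| > log(1 + threshold)`
#' (strict; a ratio sitting exactly at the threshold is not a compartment).
#' The sign of `lam` at the run's extremum fixes the enriched channel. Runs
#' shorter than `min_len_um` are dropped, then surviving runs of the same
#' sign separated by less than `merge_gap_um` are merged. The reported
#' enrichment is the maximal ratio over the run, renormalized to the
#' baseline outside all detected runs (so a clean planted fold change is
#' recovered exactly); the global-mean-normalized value `exp(max |lam|)` is
#' kept alongside as `enrichment_global`.
#'
#' @param profile a [ratio_profile()].
#' @param threshold ratio-fluctuation threshold (default 0.20, i.e. 20%).
#' @param min_len_um minimum compartment length (default 0.3 um).
#' @param merge_gap_um same-sign runs closer than this are merged
#'   (default 0.2 um).
#' @param smooth_um optional moving-average window applied to `lam` before
#'   thresholding, micrometres (default 0 = none).
#' @param signal_floor samples where either channel falls below
#'   `signal_floor` times its median along the trace are ineligible to form
#'   compartments: with too little signal in both channels the ratio is
#'   dominated by noise (the assay's equivalent of only tracing clearly
#'   visible microtubules). Default 0.5; 0 disables the gate.
#' @return data frame with one row per compartment: `path_id`, `start_um`,
#'   `end_um`, `length_um`, `enrichment`, `enrichment_global`, `channel`,
#'   `peak_s_um`. Compartments are disjoint and ordered along the path.
#' @export
detect_compartments <- function(profile, threshold = 0.20, min_len_um = 0.3,
                                merge_gap_um = 0.2, smooth_um = 0,
                                signal_floor = 0.5) {
  stopifnot(inherits(profile, "ratio_profile"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  lam <- profile$lam
  s <- profile$s
  if (smooth_um > 0) {
    step <- mean(diff(s))
    k <- 2L * floor(smooth_um / step / 2) + 1L
    lam <- moving_average(lam, k)
  }
  thr <- log(1 + threshold)
  eligible <- if (signal_floor > 0)
    profile$a >= signal_floor * stats::median(profile$a) &
      profile$b >= signal_floor * stats::median(profile$b)
  else rep(TRUE, length(lam))
  scan <- function(v) {
    runs <- rle(abs(v) > thr & eligible)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    if (!length(idx)) return(NULL)
    data.frame(i0 = starts[idx], i1 = ends[idx])
  }
  # two-pass baseline correction: compartments inflate the global channel
  # means, shifting lam everywhere along the path; recompute the means over
  # the samples outside first-pass runs and rescan.
  seg1 <- scan(lam)
  if (!is.null(seg1)) {
    out1 <- rep(TRUE, length(lam))
    for (j in seq_len(nrow(seg1))) out1[seg1$i0[j]:seg1$i1[j]] <- FALSE
    if (any(out1)) {
      shift <- (log(mean(profile$a[out1])) - log(mean(profile$a))) -
        (log(mean(profile$b[out1])) - log(mean(profile$b)))
      lam <- lam - shift
    }
  }
  seg <- scan(lam)
  if (is.null(seg)) return(empty_compartments(profile$path_id))
  seg$peak <- mapply(function(i0, i1) {
    w <- i0:i1; w[which.max(abs(lam[w]))]
  }, seg$i0, seg$i1)
  seg$sign <- sign(lam[seg$peak])
  # drop runs shorter than min_len_um, then merge same-sign near neighbours
  seg <- seg[s[seg$i1] - s[seg$i0] >= min_len_um - 1e-9, , drop = FALSE]
  if (!nrow(seg)) return(empty_compartments(profile$path_id))
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) for (j in 2:nrow(seg)) {
    last <- nrow(merged)
    if (seg$sign[j] == merged$sign[last] &&
        s[seg$i0[j]] - s[merged$i1[last]] < merge_gap_um) {
      merged$i1[last] <- seg$i1[j]
      w <- merged$i0[last]:merged$i1[last]
      merged$peak[last] <- w[which.max(abs(lam[w]))]
    } else merged <- rbind(merged, seg[j, ])
  }
  inside <- rep(FALSE, length(s))
  for (j in seq_len(nrow(merged))) inside[merged$i0[j]:merged$i1[j]] <- TRUE
  # baseline ratio outside detected runs, for baseline-normalized enrichment
  base_ratio <- if (any(!inside))
    mean(profile$a[!inside]) / mean(profile$b[!inside])
  else mean(profile$a) / mean(profile$b)
  raw_ratio <- profile$a / profile$b
  out <- data.frame(
    path_id = profile$path_id,
    start_um = s[merged$i0],
    end_um = s[merged$i1],
    length_um = s[merged$i1] - s[merged$i0],
    enrichment = NA_real_,
    enrichment_global = exp(vapply(seq_len(nrow(merged)), function(j)
      max(abs(lam[merged$i0[j]:merged$i1[j]])), 0)),
    channel = ifelse(merged$sign > 0, "bait", "prey"),
    peak_s_um = s[merged$peak],
    stringsAsFactors = FALSE)
  out$enrichment <- vapply(seq_len(nrow(merged)), function(j) {
    w <- merged$i0[j]:merged$i1[j]
    if (merged$sign[j] > 0) max(raw_ratio[w]) / base_ratio
    else base_ratio / min(raw_ratio[w])
  }, 0)
  out
}

empty_compartments <- function(path_id) {
  data.frame(path_id = rep(path_id, 0L), start_um = numeric(0),
             end_um = numeric(0), length_um = numeric(0),
             enrichment = numeric(0), enrichment_global = numeric(0),
             channel = character(0), peak_s_um = numeric(0),
             stringsAsFactors = FALSE)
}

#' Attribute a compartment to channel gain or to the other channel's absence
#'
#' At the arclength where the enriched/other ratio is maximal, the Boolean
#' test `log(I_enr / mean(I_enr)) - log(I_oth / mean(I_oth)) > 0` is
#' evaluated (recorded as `boolean`). The attribution refines it: whichever
#' signed log term deviates more from zero decides, so the compartment is an
#' `"enriched-channel-gain"` only when the enriched channel's own term is
#' positive and at least as large in magnitude as the other channel's;
#' otherwise (including the degenerate both-zero tie) it is
#' `"other-channel-absence"`.
#'
#' @param profile the [ratio_profile()] the compartment came from.
#' @param comp one row of the [detect_compartments()] table.
#' @return list with `attribution` (factor level) and `boolean`.
#' @export
attribute_compartment <- function(profile, comp) {
  stopifnot(inherits(profile, "ratio_profile"))
  if (comp$end_um < min(profile$s) || comp$start_um > max(profile$s))
    stop("compartment does not overlap the profile")
  i <- which.min(abs(profile$s - comp$peak_s_um))
  term_a <- log(profile$a[i] / mean(profile$a))
  term_b <- log(profile$b[i] / mean(profile$b))
  if (comp$channel == "bait") {
    own <- term_a; oth <- term_b
  } else {
    own <- term_b; oth <- term_a
  }
  boolean <- (own - oth) > 0
  attribution <- if (own > 0 && abs(own) >= abs(oth))
    "enriched-channel-gain" else "other-channel-absence"
  list(attribution = attribution, boolean = boolean)
}

#' Pool compartments across profiles into a condition population
#'
#' Detects (or accepts pre-detected) compartments for every profile,
#' attributes each one, and pools them with the total analyzed arclength.
#' The assay targets around 10 mm of microtubule network per condition; a
#' population below 7 mm is flagged as under-sampled.
#'
#' @param profiles list of [ratio_profile()].
#' @param condition condition label.
#' @param ... passed on to [detect_compartments()].
#' @return object of class `compartment_population`: `condition`,
#'   `compartments` (pooled data frame with `attribution` and `boolean`
#'   columns), `total_length_um`, `path_lengths_um`, `under_sampled`.
#' @export
aggregate_population <- function(profiles, condition = "condition", ...) {
  if (!length(profiles)) stop("need >= 1 profile")
  comps <- vector("list", length(profiles))
  lens <- numeric(length(profiles))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    stopifnot(inherits(pr, "ratio_profile"))
    if (identical(pr$path_id, 1L)) pr$path_id <- i
    lens[i] <- max(pr$s) - min(pr$s)
    cc <- detect_compartments(pr, ...)
    if (nrow(cc)) {
      att <- lapply(seq_len(nrow(cc)), function(j)
        attribute_compartment(pr, cc[j, ]))
      cc$attribution <- vapply(att, `[[`, "", "attribution")
      cc$boolean <- vapply(att, `[[`, TRUE, "boolean")
    } else {
      cc$attribution <- character(0); cc$boolean <- logical(0)
    }
    comps[[i]] <- cc
  }
  pooled <- do.call(rbind, comps)
  total <- sum(lens)
  structure(list(condition = condition, compartments = pooled,
                 total_length_um = total, path_lengths_um = lens,
                 under_sampled = total < 7000),
            class = "compartment_population")
}

#' @export
print.compartment_population <- function(x, ...) {
  n <- nrow(x$compartments)
  cat(sprintf(
    "<compartment_population> '%s': %d compartments over %.2f mm%s\n",
    x$condition, n, x$total_length_um / 1000,
    if (x$under_sampled) " [under-sampled: < 7 mm]" else ""))
  if (n) {
    cat(sprintf("  bait: %d, prey: %d; mean L %.2f um, mean E %.2f\n",
                sum(x$compartments$channel == "bait"),
                sum(x$compartments$channel == "prey"),
                mean(x$compartments$length_um),
                mean(x$compartments$enrichment)))
  }
  invisible(x)
}

#' Summary statistics of a compartment population
#' @param object a `compartment_population`.
#' @param ... unused.
#' @return data frame with per-channel counts, count per mm, mean/median
#'   length and enrichment.
#' @export
summary.compartment_population <- function(object, ...) {
  cc <- object$compartments
  per_mm <- nrow(cc) / (object$total_length_um / 1000)
  data.frame(condition = object$condition,
             n_compartments = nrow(cc),
             n_bait = sum(cc$channel == "bait"),
             n_prey = sum(cc$channel == "prey"),
             count_per_mm = per_mm,
             mean_length_um = if (nrow(cc)) mean(cc$length_um) else NA_real_,
             median_length_um = if (nrow(cc)) stats::median(cc$length_um) else NA_real_,
             mean_enrichment = if (nrow(cc)) mean(cc$enrichment) else NA_real_,
             total_length_mm = object$total_length_um / 1000,
             under_sampled = object$under_sampled)
}
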