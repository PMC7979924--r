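# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (and stats::cor/ks.test where they are the
# thing under test).

# Average ranks by explicit counting: rank(x_i) = #(x_j < x_i) + (#(x_j ==
# x_i) + 1) / 2.
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# Spearman via Pearson product-moment formula on explicit average ranks.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive threshold-run scan over a ratio profile: a plain double loop
# re-implementing the detection definition (smoothing, signal gate,
# two-pass baseline, strict threshold, drop-short-then-merge) sample by
# sample. Returns start/end/length/E/channel like detect_compartments.
oracle_detect <- function(profile, threshold = 0.20, min_len_um = 0.3,
                          merge_gap_um = 0.2, smooth_um = 0,
                          signal_floor = 0.5) {
  s <- profile$s; a <- profile$a; b <- profile$b
  n <- length(s)
  lam <- log(a / mean(a)) - log(b / mean(b))
  if (smooth_um > 0) {
    step <- mean(diff(s))
    k <- 2L * floor(smooth_um / step / 2) + 1L
    h <- k %/% 2L
    sm <- numeric(n)
    for (i in seq_len(n)) {
      w <- max(1, i - h):min(n, i + h)
      sm[i] <- mean(lam[w])
    }
    lam <- sm
  }
  thr <- log(1 + threshold)
  elig <- rep(TRUE, n)
  if (signal_floor > 0)
    for (i in seq_len(n))
      elig[i] <- a[i] >= signal_floor * median(a) &&
        b[i] >= signal_floor * median(b)
  find_runs <- function(lamv) {
    runs <- list(); open <- FALSE
    for (i in seq_len(n)) {
      hit <- abs(lamv[i]) > thr && elig[i]
      if (hit && !open) { i0 <- i; open <- TRUE }
      if (!hit && open) {
        runs[[length(runs) + 1L]] <- c(i0, i - 1L); open <- FALSE
      }
    }
    if (open) runs[[length(runs) + 1L]] <- c(i0, n)
    runs
  }
  runs1 <- find_runs(lam)
  if (length(runs1)) {
    outside <- rep(TRUE, n)
    for (r in runs1) outside[r[1]:r[2]] <- FALSE
    if (any(outside)) {
      shift <- (log(mean(a[outside])) - log(mean(a))) -
        (log(mean(b[outside])) - log(mean(b)))
      lam <- lam - shift
    }
  }
  runs <- find_runs(lam)
  if (!length(runs)) return(NULL)
  info <- do.call(rbind, lapply(runs, function(r) {
    w <- r[1]:r[2]
    pk <- w[which.max(abs(lam[w]))]
    data.frame(i0 = r[1], i1 = r[2], peak = pk, sign = sign(lam[pk]))
  }))
  info <- info[s[info$i1] - s[info$i0] >= min_len_um - 1e-9, , drop = FALSE]
  if (!nrow(info)) return(NULL)
  merged <- info[1, , drop = FALSE]
  if (nrow(info) > 1) for (j in 2:nrow(info)) {
    lastk <- nrow(merged)
    if (info$sign[j] == merged$sign[lastk] &&
        s[info$i0[j]] - s[merged$i1[lastk]] < merge_gap_um) {
      merged$i1[lastk] <- info$i1[j]
      w <- merged$i0[lastk]:merged$i1[lastk]
      merged$peak[lastk] <- w[which.max(abs(lam[w]))]
    } else merged <- rbind(merged, info[j, ])
  }
  inside <- rep(FALSE, n)
  for (j in seq_len(nrow(merged))) inside[merged$i0[j]:merged$i1[j]] <- TRUE
  base <- if (any(!inside)) mean(a[!inside]) / mean(b[!inside])
  else mean(a) / mean(b)
  out <- NULL
  for (j in seq_len(nrow(merged))) {
    w <- merged$i0[j]:merged$i1[j]
    E <- if (merged$sign[j] > 0) max(a[w] / b[w]) / base
    else base / min(a[w] / b[w])
    out <- rbind(out, data.frame(
      start_um = s[merged$i0[j]], end_um = s[merged$i1[j]],
      length_um = s[merged$i1[j]] - s[merged$i0[j]],
      enrichment = E,
      channel = if (merged$sign[j] > 0) "bait" else "prey"))
  }
  out
}

# Exact two-sample KS null probability P(D >= d_obs) for small n, m with no
# ties, by dynamic programming over lattice paths (each path equally
# likely): counts orderings whose running ECDF difference stays strictly
# below d_obs.
oracle_ks_pvalue <- function(n, m, d_obs) {
  cnt <- matrix(0, n + 1, m + 1)
  cnt[1, 1] <- 1
  for (i in 0:n) for (j in 0:m) {
    if (i == 0 && j == 0) next
    if (abs(i / n - j / m) >= d_obs - 1e-12) { cnt[i + 1, j + 1] <- 0; next }
    up <- if (i > 0) cnt[i, j + 1] else 0
    left <- if (j > 0) cnt[i + 1, j] else 0
    cnt[i + 1, j + 1] <- up + left
  }
  1 - cnt[n + 1, m + 1] / choose(n + m, n)
}

# Random ratio profile for oracle-equivalence tests: lognormal texture with
# occasional planted fold-change steps in either channel.
random_profile <- function(n, seed) {
  set.seed(seed)
  s <- seq(0, by = 0.1, length.out = n)
  a <- exp(rnorm(n, log(100), 0.3))
  b <- exp(rnorm(n, log(100), 0.3))
  for (k in seq_len(rpois(1, 2))) {
    w <- sort(sample.int(n, 2))
    f <- runif(1, 1.3, 2.5)
    if (runif(1) < 0.5) a[w[1]:w[2]] <- a[w[1]:w[2]] * f
    else b[w[1]:w[2]] <- b[w[1]:w[2]] * f
  }
  ratio_profile(s, a, b)
}

# Small deterministic scene shared by several tests.
demo_scene <- function(seed = 42L, compartments = TRUE, noise = FALSE,
                       background = TRUE) {
  cfg <- scene_config(image_shape = c(256L, 256L), n_filaments = 12L,
                      seed = seed, coloc_rho = 1,
                      poisson_noise = noise,
                      gaussian_sd = if (noise) 3 else 0,
                      background_level = if (background) 30 else 0,
                      shading_amplitude = if (background) 0.2 else 0)
  net <- generate_network(cfg)
  comp <- if (compartments)
    rbind(compartment_spec(1, 3, 5, "bait", 2.0),
          compartment_spec(2, 4, 6, "prey", 2.0))
  else NULL
  sc <- render_scene(net, cfg, comp)
  list(cfg = cfg, net = net, comp = comp, pair = sc$pair, truth = sc$truth)
}
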