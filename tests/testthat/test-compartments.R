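# Profile tracing and the ratio-fluctuation compartment detector.

test_that("trace_profile averages across the line thickness correctly", {
  # image whose columns hold known values: a horizontal path reads the
  # 4-row column means computed by hand
  vals <- seq(10, 100, length.out = 64)
  img <- matrix(rep(vals, each = 64), 64, 64)
  pair <- image_pair(img, img * 2)
  path <- path_trace(cbind(rep(32, 2), c(8, 55)), thickness_px = 4)
  pr <- trace_profile(pair, path)
  expect_equal(pr$a, vals[9:56], tolerance = 1e-9)
  expect_equal(pr$b, 2 * vals[9:56], tolerance = 1e-9)
  # constant image: flat profile, lam identically zero
  flatp <- trace_profile(image_pair(matrix(3, 64, 64), matrix(9, 64, 64)),
                         path)
  expect_true(all(flatp$lam == 0))
  expect_equal(max(flatp$s) - min(flatp$s), 47 * 0.1, tolerance = 1e-9)
})

test_that("reversing the trace reverses the profile", {
  sc <- demo_scene(noise = FALSE)
  p <- sc$net[[3]]
  fwd <- trace_profile(sc$pair, p)
  rev_p <- path_trace(p$vertices[nrow(p$vertices):1, ],
                      p$thickness_px, p$pixel_size_um)
  bwd <- trace_profile(sc$pair, rev_p)
  expect_equal(sort(fwd$lam), sort(bwd$lam), tolerance = 1e-9)
  expect_equal(fwd$a, rev(bwd$a), tolerance = 1e-9)
})

test_that("paths leaving the image are reported with the offending sample", {
  img <- matrix(1, 32, 32)
  pair <- image_pair(img, img)
  path <- path_trace(cbind(c(16, 16), c(5, 40)))
  expect_error(trace_profile(pair, path), "leaves the image at")
})

test_that("flat and boundary-level profiles yield no compartments", {
  n <- 200
  s <- seq(0, by = 0.1, length.out = n)
  flat <- ratio_profile(s, rep(100, n), rep(50, n))
  expect_identical(nrow(detect_compartments(flat)), 0L)
  # strict inequality at the threshold: a run sitting exactly at the
  # detection ratio is not a compartment
  a <- rep(100, n); a[80:120] <- 180
  pr <- ratio_profile(s, a, rep(100, n))
  M <- max(abs(pr$lam))
  at <- detect_compartments(pr, threshold = exp(M) - 1, signal_floor = 0)
  below <- detect_compartments(pr, threshold = exp(M * 0.99) - 1,
                               signal_floor = 0)
  expect_identical(nrow(at), 0L)
  expect_identical(nrow(below), 1L)
  expect_error(detect_compartments(pr, threshold = 0), "threshold")
})

test_that("a planted step is recovered with exact E and boundaries", {
  n <- 500
  s <- seq(0, by = 0.1, length.out = n)
  a <- rep(100, n); a[201:220] <- 200      # fold 2.0 over 2.0 um
  pr <- ratio_profile(s, a, rep(100, n))
  d <- detect_compartments(pr)
  expect_identical(nrow(d), 1L)
  expect_equal(d$channel, "bait")
  expect_equal(d$enrichment, 2.0, tolerance = 1e-9)
  expect_equal(d$start_um, s[201], tolerance = 0.1 + 1e-9)
  expect_equal(d$end_um, s[220], tolerance = 0.1 + 1e-9)
  expect_equal(d$length_um, 1.9, tolerance = 0.1 + 1e-9)
  # prey-side plant is symmetric
  b <- rep(100, n); b[101:130] <- 200
  d2 <- detect_compartments(ratio_profile(s, rep(100, n), b))
  expect_equal(d2$channel, "prey")
  expect_equal(d2$enrichment, 2.0, tolerance = 1e-9)
})

test_that("detection is invariant to channel-wide gain", {
  set.seed(10)
  for (i in 1:20) {
    pr <- random_profile(400, seed = 100 + i)
    d0 <- detect_compartments(pr, smooth_um = 0.3)
    pr_scaled <- ratio_profile(pr$s, pr$a * 7.3, pr$b * 0.21)
    d1 <- detect_compartments(pr_scaled, smooth_um = 0.3)
    expect_equal(d0$start_um, d1$start_um)
    expect_equal(d0$enrichment, d1$enrichment, tolerance = 1e-9)
    expect_equal(d0$channel, d1$channel)
  }
})

test_that("compartments are disjoint, ordered, and shorter than the path", {
  for (i in 1:30) {
    pr <- random_profile(600, seed = 200 + i)
    d <- detect_compartments(pr, smooth_um = 0.3)
    if (!nrow(d)) next
    expect_true(all(diff(d$start_um) > 0))
    if (nrow(d) > 1)
      expect_true(all(d$start_um[-1] >= d$end_um[-nrow(d)]))
    expect_lte(sum(d$length_um), max(pr$s) - min(pr$s))
    expect_true(all(d$enrichment_global > 1.2))
  }
})

test_that("detector equals the exhaustive brute-force scan on random profiles", {
  params <- list(list(smooth_um = 0, signal_floor = 0),
                 list(smooth_um = 0.3, signal_floor = 0.5),
                 list(smooth_um = 0.5, signal_floor = 0.5))
  for (i in 1:60) {
    pr <- random_profile(sample(50:800, 1), seed = 300 + i)
    p <- params[[1 + i %% 3]]
    d <- detect_compartments(pr, smooth_um = p$smooth_um,
                             signal_floor = p$signal_floor)
    o <- oracle_detect(pr, smooth_um = p$smooth_um,
                       signal_floor = p$signal_floor)
    if (is.null(o)) {
      expect_identical(nrow(d), 0L)
    } else {
      expect_equal(d$start_um, o$start_um)
      expect_equal(d$end_um, o$end_um)
      expect_equal(d$enrichment, o$enrichment, tolerance = 1e-12)
      expect_equal(d$channel, o$channel)
    }
  }
})

test_that("attribution separates channel gain from the other channel's absence", {
  n <- 300
  s <- seq(0, by = 0.1, length.out = n)
  base <- rep(100, n)
  # bait elevated 2x, prey at its mean at the peak: gain
  a <- base; a[141:160] <- 200
  pr <- ratio_profile(s, a, base)
  d <- detect_compartments(pr)
  att <- attribute_compartment(pr, d[1, ])
  expect_true(att$boolean)
  expect_equal(att$attribution, "enriched-channel-gain")
  # bait at its mean, prey halved: Boolean still true, but the bait term is
  # ~0, so the compartment reflects prey absence
  b2 <- base; b2[141:160] <- 50
  pr2 <- ratio_profile(s, base, b2)
  d2 <- detect_compartments(pr2)
  expect_equal(d2$channel, "bait")
  att2 <- attribute_compartment(pr2, d2[1, ])
  expect_true(att2$boolean)
  expect_equal(att2$attribution, "other-channel-absence")
  # degenerate tie: both terms zero at the evaluated point
  prf <- ratio_profile(s, base, base)
  fake <- data.frame(path_id = 1L, start_um = 5, end_um = 6, length_um = 1,
                     enrichment = 1, enrichment_global = 1,
                     channel = "bait", peak_s_um = 5.5)
  att3 <- attribute_compartment(prf, fake)
  expect_false(att3$boolean)
  expect_equal(att3$attribution, "other-channel-absence")
  expect_error(
    attribute_compartment(pr, transform(fake, start_um = 900, end_um = 901)),
    "overlap")
})

test_that("populations pool compartments and track analyzed arclength", {
  n <- 400
  s <- seq(0, by = 0.1, length.out = n)
  a <- rep(100, n); a[101:130] <- 220
  p1 <- ratio_profile(s, a, rep(100, n))
  p2 <- ratio_profile(s, rep(100, n), rep(60, n))
  pop <- aggregate_population(list(p1, p2), condition = "demo")
  expect_equal(pop$total_length_um, 2 * (n - 1) * 0.1, tolerance = 1e-9)
  expect_identical(nrow(pop$compartments), 1L)
  expect_true(pop$under_sampled)   # far below the 7 mm target
  expect_true(all(c("attribution", "boolean") %in%
                    names(pop$compartments)))
  sm <- summary(pop)
  expect_equal(sm$n_compartments, 1L)
  expect_equal(sm$count_per_mm, 1 / (pop$total_length_um / 1000))
  # single clean profile: population with zero compartments
  pop0 <- aggregate_population(list(p2), condition = "clean")
  expect_identical(nrow(pop0$compartments), 0L)
  expect_equal(pop0$total_length_um, (n - 1) * 0.1, tolerance = 1e-9)
})
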