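# Population tests, demixing classification, foci enrichment, slope fits.

make_pop <- function(E, L = NULL, condition = "pop") {
  n <- length(E)
  if (is.null(L)) L <- rep(1, n)
  structure(list(condition = condition,
                 compartments = data.frame(
                   path_id = seq_len(n), start_um = 0, end_um = L,
                   length_um = L, enrichment = E, enrichment_global = E,
                   channel = "bait", peak_s_um = 0),
                 total_length_um = 1000 * n,
                 path_lengths_um = rep(1000, n),
                 under_sampled = FALSE),
            class = "compartment_population")
}

test_that("identical populations compare as indistinguishable", {
  x <- make_pop(c(1.3, 1.5, 1.7, 2.0, 2.2))
  cmp <- compare_populations(x, x, "enrichment")
  expect_equal(cmp$ks_stat, 0)
  expect_equal(cmp$ks_p, 1)
  empty <- make_pop(c(1, 2, 3))
  empty$compartments <- empty$compartments[0, ]
  expect_error(compare_populations(x, empty, "enrichment"), "empty|>= 3")
})

test_that("disjoint supports reach the exact enumeration p-value", {
  a <- make_pop(seq(1.21, 1.40, length.out = 10), condition = "a")
  b <- make_pop(seq(2.01, 2.30, length.out = 10), condition = "b")
  cmp <- compare_populations(a, b, "enrichment")
  expect_equal(cmp$ks_stat, 1)
  # exact small-sample null probability by lattice-path enumeration
  expect_equal(cmp$ks_p, oracle_ks_pvalue(10, 10, 1), tolerance = 1e-9)
  expect_equal(oracle_ks_pvalue(10, 10, 1), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_lt(cmp$t_p, 1e-6)
})

test_that("ks comparison matches the enumeration oracle on random samples", {
  set.seed(5)
  for (i in 1:10) {
    ea <- round(runif(8, 1.3, 2.5), 3)
    eb <- round(runif(9, 1.3, 3.0), 3)
    if (anyDuplicated(c(ea, eb))) next
    cmp <- compare_populations(make_pop(ea), make_pop(eb), "enrichment")
    expect_equal(cmp$ks_p, oracle_ks_pvalue(8, 9, cmp$ks_stat),
                 tolerance = 1e-9)
  }
})

test_that("ks p-values are invariant under a common monotone transform", {
  set.seed(7)
  ea <- runif(12, 1.2, 2); eb <- runif(15, 1.4, 2.6)
  c0 <- compare_populations(make_pop(ea), make_pop(eb), "enrichment")
  c1 <- compare_populations(make_pop(exp(ea)), make_pop(exp(eb)),
                            "enrichment")
  expect_equal(c0$ks_p, c1$ks_p, tolerance = 1e-12)
  expect_equal(c0$ks_stat, c1$ks_stat, tolerance = 1e-12)
})

test_that("count_per_mm compares per-path compartment densities", {
  a <- make_pop(c(1.5, 1.6, 1.8))
  cmp <- compare_populations(a, make_pop(c(1.4, 1.5, 1.9, 2.0)),
                             "count_per_mm")
  expect_equal(cmp$n_a, 3L)
  expect_true(cmp$ks_p >= 0 && cmp$ks_p <= 1)
})

test_that("demixing classification applies the >=2 / >=4 controls rule", {
  mk <- function(p) data.frame(ks_p = p, t_p = p)
  expect_equal(classify_demixing(mk(c(0.5, 0.3, 0.7, 0.9)))$class,
               "not-significant")
  expect_equal(classify_demixing(mk(c(0.001, 0.004, 0.2, 0.6)))$class,
               "significant-2plus")
  expect_equal(classify_demixing(mk(c(0.001, 0.002, 0.003, 0.004)))$class,
               "significant-4plus")
  # order independence: a pure function of the p-value multiset
  p <- c(0.002, 0.3, 0.004, 0.8, 0.009)
  expect_equal(classify_demixing(mk(p))$class,
               classify_demixing(mk(rev(p)))$class)
  expect_equal(classify_demixing(mk(p))$n_significant_ks, 3L)
  expect_error(classify_demixing(mk(c(0.1, 0.2, 0.3))), ">= 4")
})

test_that("foci enrichment is the foci/cytoplasm mean ratio", {
  img <- matrix(10, 32, 32)
  foci <- matrix(FALSE, 32, 32); foci[5:8, 5:8] <- TRUE
  cyto <- !foci
  expect_equal(foci_enrichment(channel_image(img, channel = "prey"),
                               foci, cyto), 1)
  img[foci] <- 30
  expect_equal(foci_enrichment(channel_image(img, channel = "prey"),
                               foci, cyto), 3)
  expect_error(foci_enrichment(channel_image(img, channel = "prey"),
                               matrix(FALSE, 32, 32), cyto), "empty")
  expect_error(foci_enrichment(channel_image(img, channel = "prey"),
                               foci, foci), "exclude")
})

test_that("planted granule enrichments are recovered under shot noise", {
  set.seed(12)
  planted <- runif(20, 1.5, 4)
  rel_err <- vapply(seq_along(planted), function(i) {
    sc <- render_foci_scene(enrichment = planted[i], seed = 500L + i)
    est <- foci_enrichment(sc$image, sc$foci_mask, sc$cyto_mask)
    (est - planted[i]) / planted[i]
  }, 0)
  expect_lt(sqrt(mean(rel_err^2)), 0.05)
})

test_that("slope fits are exact on clean data and equivariant in scale", {
  x <- 1:10
  s <- fit_slope(x, 2 * x)
  expect_equal(s$slope, 2, tolerance = 1e-12)
  expect_equal(s$intercept, 0, tolerance = 1e-12)
  expect_equal(s$ci_high - s$ci_low, 0, tolerance = 1e-9)
  expect_equal(fit_slope(x, rep(3.5, 10))$slope, 0, tolerance = 1e-12)
  set.seed(13)
  y <- 1.5 * x + rnorm(10, 0, 0.3)
  f0 <- fit_slope(x, y)
  f1 <- fit_slope(x, 10 * y)
  expect_equal(f1$slope, 10 * f0$slope, tolerance = 1e-10)
  expect_equal(f1$ci_low, 10 * f0$ci_low, tolerance = 1e-10)
  expect_error(fit_slope(rep(2, 5), 1:5), "all x equal")
  expect_error(fit_slope(1:2, 1:2), ">= 3")
  expect_equal(fraction_positive(c(1, 2, 3, 4), 2.5), 0.5)
})
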