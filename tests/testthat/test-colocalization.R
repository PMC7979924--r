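# Spearman scoring, cell records, and the zero-bait interaction score.

test_that("spearman_roi is exact under identity, monotone transform, reversal", {
  set.seed(2)
  bait <- matrix(runif(100, 1, 10), 10)
  r <- roi(0, 0, 10, 10)
  expect_equal(spearman_roi(image_pair(bait, bait), r), 1)
  expect_equal(spearman_roi(image_pair(bait, bait^2), r), 1)
  expect_equal(spearman_roi(image_pair(bait, exp(bait)), r), 1)
  expect_equal(spearman_roi(image_pair(bait, max(bait) - bait + 1), r), -1)
})

test_that("spearman_roi matches the explicit rank-formula oracle with ties", {
  set.seed(3)
  r <- roi(0, 0, 5, 5)
  for (i in 1:50) {
    bait <- matrix(sample(1:6, 25, TRUE), 5)   # guaranteed ties
    prey <- matrix(sample(1:6, 25, TRUE), 5)
    if (length(unique(as.vector(bait))) == 1L ||
        length(unique(as.vector(prey))) == 1L) next
    pair <- image_pair(bait, prey)
    expect_error(spearman_roi(pair, roi(0, 0, 6, 6)), "outside")
    expect_equal(spearman_roi(pair, r),
                 oracle_spearman(as.vector(bait), as.vector(prey)),
                 tolerance = 1e-12)
  }
})

test_that("constant channels are flagged, never silently scored", {
  bait <- matrix(5, 12, 12)
  prey <- matrix(runif(144), 12)
  out <- spearman_roi(image_pair(bait, prey), roi(0, 0, 12, 12))
  expect_true(is.na(out))
  expect_equal(attr(out, "constant_channel"), "bait")
  rec <- measure_cell(image_pair(bait, prey),
                      list(roi(0, 0, 3, 12), roi(4, 0, 3, 12),
                           roi(8, 0, 3, 12)))
  expect_true(rec$flagged)
  expect_true(is.na(rec$rho_cell))
})

test_that("measure_cell enforces the fixed-area, disjoint-ROI protocol", {
  sc <- demo_scene(compartments = FALSE, noise = FALSE)
  rois <- list(roi(10, 10, 40, 40), roi(60, 60, 40, 40), roi(110, 110, 40, 40))
  rec <- measure_cell(sc$pair, rois)
  # rho = 1 scene: prey proportional to bait, every ROI scores 1
  expect_equal(rec$rho_cell, 1)
  expect_equal(rec$bait_level, sum(sc$pair$bait$pixels))
  expect_error(measure_cell(sc$pair, rois[1:2]), "exactly 3")
  expect_error(
    measure_cell(sc$pair, list(roi(10, 10, 40, 40), roi(30, 30, 40, 40),
                               roi(110, 110, 40, 40))), "disjoint")
  expect_error(
    measure_cell(sc$pair, list(roi(10, 10, 40, 40), roi(60, 60, 40, 40),
                               roi(110, 110, 20, 40))), "same fixed area")
})

test_that("preprocessing preserves a perfect colocalization score", {
  sc <- demo_scene(compartments = FALSE, noise = FALSE)
  pp <- preprocess_pair(sc$pair)
  rois <- place_rois(pp, 3L, 64L, 64L)
  rec <- measure_cell(pp, rois)
  expect_equal(rec$rho_cell, 1, tolerance = 1e-9)
})

test_that("place_rois returns disjoint fixed-size windows on bright regions", {
  sc <- demo_scene(compartments = FALSE)
  rois <- place_rois(sc$pair, 3L, 50L, 50L)
  expect_length(rois, 3L)
  rois2 <- place_rois(sc$pair, 3L, 50L, 50L)
  expect_identical(rois, rois2)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- rois[[i]]; b <- rois[[j]]
    expect_false(a$row < b$row + b$height && a$row + a$height > b$row &&
                   a$col < b$col + b$width && a$col + a$width > b$col)
  }
})

test_that("interaction score recovers exact linear and constant records", {
  const <- data.frame(cell_id = 1:8, bait_level = 1:8, rho_cell = 0.7)
  s <- interaction_score(const)
  expect_equal(s$score, 0.7)
  expect_equal(s$slope, 0)
  lin <- data.frame(cell_id = 1:10, bait_level = seq(2, 20, by = 2),
                    rho_cell = 0.1 + 0.02 * seq(2, 20, by = 2))
  s2 <- interaction_score(lin)
  expect_equal(s2$score, 0.1, tolerance = 1e-12)
  expect_equal(s2$slope, 0.02, tolerance = 1e-12)
  expect_true(s2$ci_low <= s2$score && s2$score <= s2$ci_high)
  expect_error(interaction_score(
    data.frame(cell_id = 1:6, bait_level = 5, rho_cell = runif(6))),
    "bait levels equal")
  expect_error(interaction_score(const[1:4, ]), ">= 5")
})

test_that("interaction score is equivariant under a constant rho shift", {
  set.seed(6)
  rec <- simulate_coloc_records(20, 0.3, 0.02, rho_sd = 0.05)
  s0 <- interaction_score(rec)
  rec2 <- rec; rec2$rho_cell <- rec2$rho_cell + 0.1
  s1 <- interaction_score(rec2)
  expect_equal(s1$score, s0$score + 0.1, tolerance = 1e-10)
  expect_equal(s1$slope, s0$slope, tolerance = 1e-10)
  expect_equal(s1$ci_high - s1$ci_low, s0$ci_high - s0$ci_low,
               tolerance = 1e-10)
})
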