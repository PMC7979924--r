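# Scene generator: determinism, geometry, planted structure, noise.

test_that("network generation is deterministic, bounded, and additive in length", {
  cfg <- scene_config(image_shape = c(256L, 256L), n_filaments = 50L,
                      seed = 3L)
  net1 <- generate_network(cfg)
  net2 <- generate_network(cfg)
  expect_identical(net1, net2)
  expect_length(net1, 50L)
  for (p in net1) {
    v <- p$vertices
    expect_true(all(v[, 1] >= 0 & v[, 1] <= 255 &
                      v[, 2] >= 0 & v[, 2] <= 255))
    # independent brute-force segment-length sum
    manual <- 0
    for (i in 2:nrow(v))
      manual <- manual + sqrt(sum((v[i, ] - v[i - 1, ])^2))
    expect_equal(path_length_um(p), manual * cfg$pixel_size_um,
                 tolerance = 1e-12)
  }
  expect_equal(attr(net1, "total_length_um"),
               sum(vapply(net1, path_length_um, 0)))
})

test_that("degenerate network configs are handled", {
  cfg0 <- scene_config(image_shape = c(128L, 128L), n_filaments = 0L)
  net <- generate_network(cfg0)
  expect_length(net, 0L)
  expect_equal(attr(net, "total_length_um"), 0)
  expect_error(scene_config(image_shape = c(0L, 128L)), "positive")
  expect_error(scene_config(coloc_rho = 1.5), "\\[-1, 1\\]")
})

test_that("rendering is bit-identical under a fixed seed and conserves components", {
  sc1 <- demo_scene(noise = TRUE)
  sc2 <- demo_scene(noise = TRUE)
  expect_identical(sc1$pair, sc2$pair)
  expect_identical(sc1$truth$profiles, sc2$truth$profiles)
  # noise-free scene decomposes into filament + background contributions
  full <- demo_scene(noise = FALSE, background = TRUE)
  fil_only <- {
    cfg <- full$cfg; cfg$background_level <- 0; cfg$shading_amplitude <- 0
    render_scene(full$net, cfg, full$comp)
  }
  bg_only <- {
    cfg <- full$cfg; cfg$bait_level <- 0; cfg$prey_level <- 0
    render_scene(full$net, cfg, full$comp)
  }
  expect_equal(full$pair$bait$pixels,
               fil_only$pair$bait$pixels + bg_only$pair$bait$pixels,
               tolerance = 1e-10)
  expect_equal(full$pair$prey$pixels,
               fil_only$pair$prey$pixels + bg_only$pair$prey$pixels,
               tolerance = 1e-10)
})

test_that("planted rank correlation of on-filament intensities matches the target", {
  # the intensity fields are autocorrelated along the filament, so several
  # scenes are pooled to average over an adequate number of independent
  # texture patches
  for (rho in c(-0.4, 0.5)) {
    ab <- lapply(1:4, function(i) {
      cfg <- scene_config(image_shape = c(512L, 512L), n_filaments = 30L,
                          seed = 11L + i, coloc_rho = rho,
                          poisson_noise = FALSE, gaussian_sd = 0)
      sc <- render_scene(NULL, cfg)
      cbind(unlist(lapply(sc$truth$profiles, `[[`, "a")),
            unlist(lapply(sc$truth$profiles, `[[`, "b")))
    })
    ab <- do.call(rbind, ab)
    expect_gt(nrow(ab), 1e4)
    expect_equal(cor(ab[, 1], ab[, 2], method = "spearman"), rho,
                 tolerance = 0.02)
  }
})

test_that("perfect colocalization makes prey a monotone transform of bait", {
  sc <- demo_scene(compartments = FALSE, noise = FALSE)
  # noise-free, rho = 1, equal levels: the two channels are proportional
  expect_equal(cor(as.vector(sc$pair$bait$pixels),
                   as.vector(sc$pair$prey$pixels), method = "spearman"),
               1, tolerance = 1e-12)
})

test_that("poisson shot noise preserves the mean intensity of a flat field", {
  cfg <- scene_config(image_shape = c(512L, 512L), n_filaments = 0L,
                      background_level = 100, shading_amplitude = 0,
                      poisson_noise = TRUE, gaussian_sd = 0, seed = 9L)
  sc <- render_scene(NULL, cfg)
  expect_equal(mean(sc$pair$bait$pixels), 100, tolerance = 0.01)
})

test_that("planted compartments shape the ground-truth ratio profile exactly", {
  sc <- demo_scene(compartments = TRUE, noise = FALSE, background = FALSE)
  pr <- sc$truth$profiles[[1]]
  ratio <- pr$a / pr$b   # independent per-sample recomputation
  inside <- pr$s_um >= 3 & pr$s_um <= 5
  base <- ratio[!inside][1]
  expect_equal(ratio[inside] / base, rep(2, sum(inside)), tolerance = 1e-9)
  expect_equal(ratio[!inside] / base, rep(1, sum(!inside)), tolerance = 1e-9)
  # prey-channel compartment on filament 2 halves the bait/prey ratio
  pr2 <- sc$truth$profiles[[2]]
  inside2 <- pr2$s_um >= 4 & pr2$s_um <= 6
  base2 <- (pr2$a / pr2$b)[!inside2][1]
  expect_equal(pr2$a[inside2] / pr2$b[inside2] / base2,
               rep(0.5, sum(inside2)), tolerance = 1e-9)
})

test_that("compartments hanging off their filament are rejected", {
  sc <- demo_scene(compartments = FALSE)
  len1 <- path_length_um(sc$net[[1]])
  bad <- compartment_spec(1, len1 - 1, len1 + 2, "bait", 2)
  expect_error(render_scene(sc$net, sc$cfg, bad), "ends at")
  expect_error(render_scene(sc$net, sc$cfg,
                            compartment_spec(99, 0, 1, "bait", 2)),
               "references filament")
  expect_error(compartment_spec(1, 2, 1), "start_um")
  expect_error(compartment_spec(1, 0, 1, fold_change = 1), "fold_change")
})

test_that("cell population carries the planted linear colocalization trend", {
  cfg <- scene_config(image_shape = c(96L, 96L), n_filaments = 6L, seed = 2L)
  cells <- generate_cell_population(20L, score_true = 0.3,
                                    slope_per_bait = 0.02, cfg)
  expect_length(cells, 20L)
  bait <- vapply(cells, `[[`, 0, "bait_level")
  expect_true(all(bait >= 1 & bait <= 20))
  for (cell in cells)
    expect_equal(cell$rho_true, 0.3 + 0.02 * cell$bait_level,
                 tolerance = 1e-12)
  # flat trend: every cell shares the intercept correlation
  flat <- generate_cell_population(3L, 0.4, 0, cfg)
  expect_true(all(vapply(flat, `[[`, 0, "rho_true") == 0.4))
  expect_error(generate_cell_population(5L, 0.9, 0.02, cfg),
               "outside \\[-1, 1\\]")
  expect_error(generate_cell_population(2L, 0.3, 0, cfg), ">= 3")
})
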