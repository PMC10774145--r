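test_that("generated populations have the requested structure", {
  cfg <- generator_config(n_cells_per_plane = 600, n_planes = 3, seed = 3)
  cells <- generate_fov(cfg)
  expect_equal(nrow(cells), 1800)
  expect_true(all(cells$x >= 0 & cells$x <= 800))
  expect_true(all(cells$z == cells$plane * 30))
  expect_setequal(unique(cells$po), c(0, 45, 90, 135))
  # same seed reproduces the identical table
  expect_identical(cells, generate_fov(cfg))
  # salt-and-pepper map: orientation preference independent of location
  quad <- paste(cells$x > 400, cells$y > 400)
  p <- suppressWarnings(chisq.test(table(quad, cells$po))$p.value)
  expect_gt(p, 0.01)
  # the tuning curves encode exactly the drawn OSI
  tcm <- tuning_matrix(cells)
  i <- c(1, 500, 1234)
  for (j in i) {
    f <- fold_directions(tcm[j, ])
    expect_equal(osi_from_folded(f$folded, f$orientations)$osi, cells$osi[j],
                 tolerance = 1e-9)
  }
})

test_that("ground-truth responses follow the configured profile", {
  cfg <- generator_config(n_cells_per_plane = 150, seed = 5)
  cells <- generate_fov(cfg)
  eg <- generate_ensembles(cells, cfg)
  tg <- eg$targets[eg$targets$ensemble_id == 1, ]
  resp <- generate_ground_truth_response(cells, tg, eg$ensembles$ensemble_po[1],
                                         cfg)
  md <- min_target_distance(cbind(cells$x, cells$y, cells$z),
                            cbind(tg$x, tg$y, tg$z))
  off <- off_target_mask(cells, tg, target_ids = tg$cell_id)
  # outside the off-target zone the response is exactly the profile
  tr <- cfg$truth
  expect_equal(resp[!off], dog_profile(md[!off], tr$A1, tr$sigma1, tr$A2,
                                       tr$sigma2),
               tolerance = 1e-12)
  # targets respond at the direct amplitude; off-target cells positively
  expect_true(all(resp[cells$cell_id %in% tg$cell_id] == cfg$direct_amp))
  expect_true(all(resp[off] >= 0))
  # zero-amplitude profile: all nontarget responses vanish
  cfg0 <- generator_config(n_cells_per_plane = 150, seed = 5,
                           truth = list(A1 = 0, sigma1 = 20, A2 = 0,
                                        sigma2 = 150,
                                        tuning_weights = c("0" = 1, "45" = 1,
                                                           "90" = 1)))
  r0 <- generate_ground_truth_response(cells, tg, 0, cfg0)
  expect_equal(max(abs(r0[!off])), 0)
  # feature-blind weights give iso and ortho cells identical expectations
  # at matched distances by construction; a tuned weight vector separates
  cfg_t <- generator_config(n_cells_per_plane = 150, seed = 5,
                            truth = list(A1 = 0.2, sigma1 = 20, A2 = 0,
                                         sigma2 = 150,
                                         tuning_weights = c("0" = 2, "45" = 1,
                                                            "90" = 0.5)))
  rt <- generate_ground_truth_response(cells, tg, 0, cfg_t)
  lab <- relative_tuning_split(cells$po, 0, osi = cells$osi,
                               p_visual = cells$p_visual)
  base <- dog_profile(md, 0.2, 20, 0, 150)
  sel <- !off & lab == "0" & base > 1e-6
  expect_equal(rt[sel] / base[sel], rep(2, sum(sel)), tolerance = 1e-9)
})

test_that("recordings are seeded and exclusion rates match their knobs", {
  cfg <- tiny_sim_config(seed = 9)
  sim1 <- simulate_experiment(cfg)
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim1$trials, sim2$trials)
  expect_identical(sim1$F, sim2$F)
  # configured 10% running rate shows up in the trial table (binomial 3 sd)
  frac <- mean(sim1$trials$run_speed > 6)
  n <- nrow(sim1$trials)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / n) + 1e-9)
})

test_that("noiseless recordings round-trip through the analysis", {
  cfg <- tiny_sim_config(seed = 13, snr = 1e6, n_trials = 10,
                         run_fast_fraction = 0, shift_fail_fraction = 0,
                         artifact_fraction = 0, unmatched_fraction = 0)
  sim <- simulate_experiment(cfg)
  ds <- extract_responses(sim, analysis_config(f0_stride = 10))
  # measured per-trial responses equal expectations (kernel-calibrated)
  tr <- sim$trials
  resp <- ds$responses
  ens_of <- tr$ensemble_id[match(resp$trial_id, tr$trial_id)]
  ci <- match(resp$cell_id, sim$cells$cell_id)
  expected <- sim$truth[cbind(ci, match(ens_of, sim$ensembles$ensemble_id))]
  err <- abs(resp$response - expected)
  expect_lt(stats::quantile(err, 0.95, names = FALSE), 0.02)
})

test_that("generator-labeled cotuned ensembles classify as cotuned", {
  cfg <- generator_config(n_cells_per_plane = 400, n_ensembles = 10,
                          tuning_modes = "cotuned", seed = 21,
                          spread_range = c(100, 180))
  cells <- generate_fov(cfg)
  eg <- generate_ensembles(cells, cfg)
  # recompute ensemble metrics from the member tuning curves (analysis side)
  ok <- vapply(seq_len(nrow(eg$ensembles)), function(e) {
    ids <- eg$targets$cell_id[eg$targets$ensemble_id ==
                                eg$ensembles$ensemble_id[e]]
    eo <- ensemble_osi(tuning_matrix(cells[match(ids, cells$cell_id), ]))
    cls <- classify_ensemble(
      mean_pairwise_spread(cells[match(ids, cells$cell_id), c("x", "y", "z")]),
      eo$ensemble_osi, eo$mean_osi)
    cls$tuning_class == "cotuned"
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
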