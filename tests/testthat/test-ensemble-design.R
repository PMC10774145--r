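test_that("mean pairwise spread matches hand geometry", {
  expect_equal(mean_pairwise_spread(rbind(c(0, 0, 0), c(100, 0, 0))), 100)
  expect_equal(mean_pairwise_spread(rbind(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5))), 0)
  # equilateral triangle of side 60: all three pairs equal
  tri <- rbind(c(0, 0, 0), c(60, 0, 0), c(30, 30 * sqrt(3), 0))
  expect_equal(mean_pairwise_spread(tri), 60, tolerance = 1e-12)
  expect_error(mean_pairwise_spread(rbind(c(0, 0, 0))), "at least 2")
})

test_that("ensemble OSI is the OSI of the mean curve", {
  dirs <- seq(0, 315, by = 45)
  curve_for <- function(po, peak = 1, ortho = 0.5) {
    dth <- fold_orientation(dirs - po)
    ortho + (peak - ortho) * (dth == 0)
  }
  # identical members: ensemble OSI equals the member OSI
  same <- rbind(curve_for(0), curve_for(0), curve_for(0))
  eo <- ensemble_osi(same)
  expect_equal(eo$ensemble_osi, (1 - 0.5) / (1 + 0.5), tolerance = 1e-12)
  expect_equal(eo$mean_osi, eo$ensemble_osi, tolerance = 1e-12)
  expect_equal(eo$ensemble_po, 0)
  # two perfectly tuned members at orthogonal orientations: flat mean curve
  perp <- rbind(curve_for(0, 1, 0), curve_for(90, 1, 0))
  eo2 <- ensemble_osi(perp)
  expect_equal(eo2$ensemble_osi, 0, tolerance = 1e-12)
  expect_equal(eo2$mean_osi, 1, tolerance = 1e-12)
  # folded (1.0, 0.5) at (pref, ortho) -> OSI 1/3
  third <- rbind(curve_for(45))
  expect_equal(ensemble_osi(third)$ensemble_osi, 1 / 3, tolerance = 1e-12)
})

test_that("ensemble classification uses the published thresholds", {
  c1 <- classify_ensemble(150, 0.8, 0.6)
  expect_equal(c(c1$spatial_class, c1$tuning_class), c("compact", "cotuned"))
  c2 <- classify_ensemble(250, 0.2, 0.3)
  expect_equal(c(c2$spatial_class, c2$tuning_class), c("diffuse", "untuned"))
  # ensemble OSI between the windows is mixed regardless of mean OSI
  expect_equal(classify_ensemble(100, 0.5, 0.9)$tuning_class, "mixed")
  expect_equal(classify_ensemble(100, 0.5, 0.1)$tuning_class, "mixed")
  # cotuned also requires high mean OSI
  expect_equal(classify_ensemble(100, 0.8, 0.4)$tuning_class, "mixed")
})

make_pool <- function(n, seed = 11) {
  cfg <- generator_config(n_cells_per_plane = ceiling(n / 3), n_planes = 3,
                          seed = seed)
  cells <- generate_fov(cfg)
  cells[seq_len(n), ]
}

test_that("optimizer respects the hard spacing constraint and is seeded", {
  pool <- make_pool(240)
  spec <- ensemble_spec(n_ensembles = 3, ensemble_size = 8,
                        spread_window = c(100, 200), n_restarts = 4,
                        max_iter = 1500, seed = 42)
  out1 <- optimize_ensembles(pool, spec)
  expect_length(out1, 3)
  for (e in out1) {
    expect_gte(min(dist(e$target_xyz)), 30)
    expect_length(e$target_ids, 8)
  }
  # determinism: same pool and seed reproduce the same design
  out2 <- optimize_ensembles(pool, spec)
  expect_identical(lapply(out1, `[[`, "target_ids"),
                   lapply(out2, `[[`, "target_ids"))
  # accepted-cost sequence is monotone non-increasing
  expect_true(all(diff(attr(out1, "cost_trace")) <= 0))
})

test_that("optimizer hits feasible windows and is stable across seeds", {
  pool <- make_pool(500)
  out <- optimize_ensembles(pool,
    ensemble_spec(n_ensembles = 3, ensemble_size = 10,
                  spread_window = c(120, 200),
                  ensemble_osi_window = c(0.7, 1),
                  mean_osi_window = c(0.5, 1),
                  seed = 1))
  # requested windows satisfied on this (feasible) pool
  for (e in out) {
    expect_gte(e$spread, 100)
    expect_lte(e$spread, 220)
  }
  # compact cotuned request: most returned ensembles classify as requested
  spec_cc <- ensemble_spec(n_ensembles = 3, ensemble_size = 8,
                           spread_window = c(80, 180),
                           ensemble_osi_window = c(0.75, 1),
                           mean_osi_window = c(0.6, 1),
                           n_restarts = 6, max_iter = 2500, seed = 2)
  cc <- optimize_ensembles(pool, spec_cc)
  cls <- vapply(cc, function(e) {
    paste(e$spatial_class, e$tuning_class)
  }, character(1))
  expect_gte(mean(cls == "compact cotuned"), 0.9)
  # costs from different seeds agree within 10% (500-cell pool)
  mk <- function(seed) {
    ensemble_spec(n_ensembles = 3, ensemble_size = 10,
                  spread_window = c(120, 200), seed = seed)
  }
  c1 <- attr(optimize_ensembles(pool, mk(1)), "cost")
  c2 <- attr(optimize_ensembles(pool, mk(99)), "cost")
  expect_lt(abs(c1 - c2) / max(c1, c2, 1e-9), 0.10)
})

test_that("infeasible spacing constraints raise an informative error", {
  pool <- make_pool(12)
  pool$x <- runif(12, 0, 10); pool$y <- runif(12, 0, 10); pool$z <- 0
  spec <- ensemble_spec(n_ensembles = 1, ensemble_size = 10,
                        n_restarts = 1, seed = 1)
  expect_error(optimize_ensembles(pool, spec), "infeasible")
})
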