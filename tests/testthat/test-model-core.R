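test_that("connectivity operators have the requested total gain", {
  cfg <- tiny_model()
  ops <- build_connectivity(cfg)
  # the zero-frequency Fourier coefficient is the discrete kernel sum
  expect_equal(Re(ops$W_ee$spec[1, 1, 1]), cfg$w_ee, tolerance = 1e-9)
  expect_equal(Re(ops$W_ie$spec[1, 1, 1]), sqrt(cfg$w_eie), tolerance = 1e-9)
  expect_equal(Re(ops$W_ei$spec[1, 1, 1]), -sqrt(cfg$w_eie), tolerance = 1e-9)
  expect_equal(sum(ops$W_ee$kernel) * cfg$grid_spacing^2, cfg$w_ee,
               tolerance = 1e-9)
  # separability: kernel is an outer product of a spatial and a feature part
  k <- ops$W_ee$kernel
  expect_equal(k[, , 2] / k[, , 1],
               matrix((k[1, 1, 2] / k[1, 1, 1]), cfg$n_nodes, cfg$n_nodes),
               tolerance = 1e-9)
})

test_that("grid coarser than the narrow scale is flagged", {
  expect_warning(model_config(domain_size = 100, grid_spacing = 20,
                              sigma_e_narrow = 15),
                 "under-resolved")
  expect_error(model_config(domain_size = 100, grid_spacing = 7),
               "divide")
})

test_that("stim_field conserves mass and snaps to the nearest node", {
  cfg <- tiny_model()
  one <- stim_field(data.frame(x = 80, y = 80, theta = 0), cfg)
  expect_equal(field_mass(one), 10)
  ten <- stim_field(data.frame(x = runif(10, 0, 150), y = runif(10, 0, 150)),
                    cfg)
  expect_equal(field_mass(ten), 100)
  # snapping: (3, 3) rounds down to node (0, 0), (6, 6) up to node (10, 10)
  snap <- stim_field(data.frame(x = 3, y = 3, theta = 0), cfg)
  expect_equal(snap$values[1, 1, 1] * cfg$grid_spacing^2, 10)
  snap2 <- stim_field(data.frame(x = 6, y = 6, theta = 0), cfg)
  expect_equal(snap2$values[2, 2, 1] * cfg$grid_spacing^2, 10)
  # coincident targets accumulate
  twice <- stim_field(data.frame(x = c(80, 80), y = c(80, 80)), cfg)
  expect_equal(max(twice$values), 2 * 10 / cfg$grid_spacing^2)
  empty <- stim_field(data.frame(x = numeric(0), y = numeric(0)), cfg)
  expect_equal(field_mass(empty), 0)
})

test_that("Fourier solution matches the dense real-space oracle", {
  cfg <- suppressWarnings(model_config(
    domain_size = 160, grid_spacing = 10, n_orientations = 4,
    w_ee = 0.3, w_eie = 0.5, sigma_e_broad = 40, sigma_i_broad = 30,
    sigma_e_narrow = 12, kappa_e = 0.3,
    feature_ee = feature_params(0.5, 0.5, 30),
    feature_ei = feature_params(0.1, 0.9, 30),
    feature_ie = feature_params(0.1, 0.9, 30), mode = "exact"))
  ops <- build_connectivity(cfg)
  s <- stim_field(data.frame(x = c(80, 40), y = c(80, 120),
                             theta = c(0, 45)), cfg)
  fast <- solve_linear_response(ops, s, cfg)
  slow <- dense_solve(cfg, s)
  expect_lt(max(abs(fast$values - slow)) / max(abs(slow)), 1e-6)
})

test_that("response is linear and translation-equivariant", {
  cfg <- tiny_model(mode = "exact")
  ops <- build_connectivity(cfg)
  s1 <- stim_field(data.frame(x = 80, y = 80, theta = 0), cfg)
  s2 <- stim_field(data.frame(x = 40, y = 120, theta = 45), cfg)
  r1 <- solve_linear_response(ops, s1, cfg)
  r2 <- solve_linear_response(ops, s2, cfg)
  s12 <- field_state(s1$values + 2 * s2$values, cfg)
  r12 <- solve_linear_response(ops, s12, cfg)
  expect_lt(max(abs(r12$values - r1$values - 2 * r2$values)), 1e-10)
  # zero stimulation gives an identically zero response
  r0 <- solve_linear_response(ops, stim_field(data.frame(x = numeric(0),
                                                         y = numeric(0)), cfg),
                              cfg)
  expect_equal(max(abs(r0$values)), 0)
  # shifting the target by a lattice vector shifts the response identically
  sh <- stim_field(data.frame(x = 80 + 30, y = 80 + 20, theta = 0), cfg)
  rsh <- solve_linear_response(ops, sh, cfg)
  expect_equal(rsh$values[(1:16 - 1 + 3) %% 16 + 1, (1:16 - 1 + 2) %% 16 + 1, ],
               r1$values, tolerance = 1e-12)
})

test_that("untuned wiring makes the response independent of orientation", {
  cfg <- tiny_model(tuned = FALSE, mode = "exact")
  ops <- build_connectivity(cfg)
  s <- stim_field(data.frame(x = 80, y = 80, theta = 0), cfg)
  r <- solve_linear_response(ops, s, cfg)
  # away from the stimulated (x, y, theta) node the response cannot depend
  # on theta; compare the three non-stimulated orientation slices
  expect_equal(r$values[, , 2], r$values[, , 3], tolerance = 1e-12)
  expect_equal(r$values[, , 2], r$values[, , 4], tolerance = 1e-12)
})

test_that("pathway decomposition sums to the truncated response", {
  cfg <- tiny_model(mode = "expansion")
  ops <- build_connectivity(cfg)
  s <- stim_field(data.frame(x = 80, y = 80, theta = 0), cfg)
  pw <- decompose_pathways(ops, s, cfg)
  exp2 <- solve_linear_response(ops, s, cfg, mode = "expansion")
  expect_equal(pw$total$values,
               pw$mono_ee$values + pw$di_eee$values + pw$di_eie$values,
               tolerance = 1e-14)
  expect_equal(pw$total$values, exp2$values, tolerance = 1e-12)
  # the disynaptic inhibitory pathway is non-positive
  expect_true(all(pw$di_eie$values <= 1e-15))
  # switching off the inhibitory loop removes di_eie entirely
  cfg0 <- tiny_model(mode = "expansion")
  cfg0$w_eie <- 0
  pw0 <- decompose_pathways(build_connectivity(cfg0), s, cfg0)
  expect_equal(max(abs(pw0$di_eie$values)), 0)
  # with kappa = 0 and untuned wiring, the monosynaptic profile of a point
  # stimulus is proportional to the broad Gaussian around the target
  cfgb <- tiny_model(kappa_e = 0, tuned = FALSE)
  opsb <- build_connectivity(cfgb)
  pwb <- decompose_pathways(opsb, stim_field(data.frame(x = 80, y = 80), cfgb),
                            cfgb)
  prof <- pwb$mono_ee$values[, 9, 1]      # slice through the target row
  dx <- cfgb$grid_spacing * pmin(abs(0:15 - 8), 16 - abs(0:15 - 8))
  ref <- exp(-dx^2 / (2 * cfgb$sigma_e_broad^2))
  expect_equal(prof / prof[9], ref / ref[9], tolerance = 1e-6)
})

test_that("expansion error shrinks linearly with the effective weights", {
  base <- tiny_model(mode = "exact")
  rel_err <- sapply(c(1, 0.5, 0.25, 0.125), function(eps) {
    cfg <- tiny_model(mode = "exact")
    cfg$w_ee <- base$w_ee * eps
    cfg$w_eie <- base$w_eie * eps
    ops <- build_connectivity(cfg)
    s <- stim_field(data.frame(x = 80, y = 80, theta = 0), cfg)
    ex <- solve_linear_response(ops, s, cfg, mode = "exact")
    ap <- solve_linear_response(ops, s, cfg, mode = "expansion")
    sqrt(sum((ex$values - ap$values)^2) / sum(ex$values^2))
  })
  # halving the weights should at least halve the relative error
  expect_true(all(rel_err[-1] / rel_err[-4] < 0.6))
})

test_that("unstable weights are rejected in exact mode with mode report", {
  cfg <- tiny_model(mode = "exact")
  cfg$w_ee <- 2.5       # pushes the uniform mode's eigenvalue above 1
  ops <- build_connectivity(cfg)
  s <- stim_field(data.frame(x = 80, y = 80, theta = 0), cfg)
  expect_error(solve_linear_response(ops, s, cfg, mode = "exact"),
               "spectral radius")
  expect_warning(solve_linear_response(ops, s, cfg, mode = "expansion"),
                 "spectral radius")
})

test_that("cell-level predictions sample the field correctly", {
  cfg <- tiny_model(tuned = FALSE, domain = 1400, spacing = 4,
                    n_orientations = 4)
  tg <- data.frame(x = c(350, 450), y = c(400, 400), theta = 0)
  cells <- data.frame(x = c(350, 450, 200, 600), y = c(400, 400, 200, 600),
                      po = c(0, 90, 45, 135))
  pr <- predict_cell_responses(cells, tg, cfg)
  # untuned model: predictions do not depend on the cells' po
  cells2 <- cells
  cells2$po <- (cells2$po + 45) %% 180
  expect_equal(predict_cell_responses(cells2, tg, cfg), pr, tolerance = 1e-12)
  # cells sitting on targets get the largest responses
  expect_true(min(pr[1:2]) > max(pr[3:4]))
  expect_error(predict_cell_responses(data.frame(x = -5, y = 10, po = 0),
                                      tg, cfg), "FOV")
})
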