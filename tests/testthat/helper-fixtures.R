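# Shared fixtures for the test suite. Everything is generated in code.

# Small periodic model used wherever the full 1400/4 grid would be overkill.
tiny_model <- function(n_orientations = 4, mode = "exact", w_ee = 0.3,
                       kappa_e = 0.3, tuned = TRUE, domain = 160,
                       spacing = 10) {
  suppressWarnings(model_config(
    domain_size = domain, grid_spacing = spacing,
    n_orientations = n_orientations,
    w_ee = w_ee, w_eie = 0.5,
    sigma_e_broad = 40, sigma_i_broad = 30, sigma_e_narrow = 12,
    kappa_e = kappa_e, kappa_i = 0,
    feature_ee = if (tuned) feature_params(0.5, 0.5, 30) else untuned_features(),
    feature_ei = if (tuned) feature_params(0.1, 0.9, 30) else untuned_features(),
    feature_ie = if (tuned) feature_params(0.1, 0.9, 30) else untuned_features(),
    mode = mode))
}

# Brute-force dense operator built from first principles (periodic distances,
# folded orientation differences, discrete normalization), independent of the
# package's FFT representation.
dense_operator <- function(w, sigma_b, sigma_n, kappa, feature, config) {
  n <- config$n_nodes
  nt <- config$n_orientations
  sp <- config$grid_spacing
  N <- n * n * nt
  idx <- 0:(n - 1)
  pd <- sp * pmin(idx, n - idx)
  step <- 180 / nt
  K <- array(0, c(n, n, nt))
  for (i in seq_len(n)) for (j in seq_len(n)) for (t in seq_len(nt)) {
    r <- sqrt(pd[i]^2 + pd[j]^2)
    dth <- fold_orientation((t - 1) * step)
    K[i, j, t] <- spatial_kernel(r, sigma_b, sigma_n, kappa) *
      feature_kernel(dth, feature)
  }
  z <- sum(K) * sp^2
  K <- w * K / z
  A <- matrix(0, N, N)
  lin <- function(i, j, t) (t - 1) * n * n + (j - 1) * n + i
  for (t2 in seq_len(nt)) for (j2 in seq_len(n)) for (i2 in seq_len(n)) {
    col <- lin(i2, j2, t2)
    for (t1 in seq_len(nt)) for (j1 in seq_len(n)) for (i1 in seq_len(n)) {
      A[lin(i1, j1, t1), col] <-
        K[((i1 - i2) %% n) + 1, ((j1 - j2) %% n) + 1, ((t1 - t2) %% nt) + 1] * sp^2
    }
  }
  A
}

# Dense two-population steady-state solve (the oracle for the FFT solver).
dense_solve <- function(config, stim) {
  n <- config$n_nodes
  nt <- config$n_orientations
  N <- n * n * nt
  Aee <- dense_operator(config$w_ee, config$sigma_e_broad,
                        config$sigma_e_narrow, config$kappa_e,
                        config$feature_ee, config)
  Aei <- dense_operator(-sqrt(config$w_eie), config$sigma_i_broad,
                        config$sigma_i_narrow, config$kappa_i,
                        config$feature_ei, config)
  Aie <- dense_operator(sqrt(config$w_eie), config$sigma_e_broad,
                        config$sigma_e_narrow, config$kappa_e,
                        config$feature_ie, config)
  W <- rbind(cbind(Aee, Aei), cbind(Aie, matrix(0, N, N)))
  sv <- c(as.vector(stim$values), rep(0, N))
  x <- solve(diag(2 * N) - W, W %*% sv)
  array(x[1:N], dim = c(n, n, nt))
}

# Hand-assembled dataset with one known violation of every exclusion rule.
# Geometry and counts are chosen so each removal is attributable by hand.
exclusion_fixture <- function() {
  mk_cells <- function(fov, n, x = NULL) {
    data.frame(
      cell_id = seq_len(n) + fov * 10000L, fov_id = fov,
      plane = 0L, x = if (is.null(x)) seq(100, 700, length.out = n) else x,
      y = 400, z = 0,
      opsin = TRUE, power = 50, matched = TRUE, artifact = FALSE,
      visually_responsive = TRUE, p_visual = 0.01, po = 0, osi = 0.5)
  }
  # FOV 1: healthy. FOV 2: only 2% visually responsive. FOV 3: mostly
  # running. FOV 4: too few cells.
  # 30 x 10 grid with >15 um spacing so only targets fall in off-target zones
  c1 <- mk_cells(1, 300)
  c1$x <- rep(seq(30, 770, length.out = 30), 10)
  c1$y <- rep(seq(40, 760, length.out = 10), each = 30)
  c2 <- mk_cells(2, 300); c2$visually_responsive <- rep(c(TRUE, FALSE), c(6, 294))
  c3 <- mk_cells(3, 300)
  c4 <- mk_cells(4, 100)
  cells <- rbind(c1, c2, c3, c4)

  ens <- data.frame(
    ensemble_id = 1:6,
    fov_id = c(1, 1, 1, 2, 3, 4),
    spread = 150, ensemble_osi = 0.8, mean_osi = 0.6, ensemble_po = 0)
  # ensembles: 1 healthy; 2 has 2/5 targets undetected (40% > 33%);
  # 3 will fall below 10 surviving repetitions; 4-6 die with their FOVs
  tg <- function(e, ids, detected = TRUE) {
    data.frame(ensemble_id = e, cell_id = ids,
               x = cells$x[match(ids, cells$cell_id)],
               y = cells$y[match(ids, cells$cell_id)],
               z = 0, plane = 0L, detected = detected)
  }
  targets <- rbind(
    tg(1, c1$cell_id[c(1, 10, 20, 30, 40)]),
    tg(2, c1$cell_id[c(2, 12, 22, 32, 42)], detected = c(TRUE, TRUE, TRUE, FALSE, FALSE)),
    tg(3, c1$cell_id[c(3, 13, 23, 33, 43)]),
    tg(4, c2$cell_id[1:5]), tg(5, c3$cell_id[1:5]), tg(6, c4$cell_id[1:5]))

  # FOV1 trials: ensemble 1 gets 12 clean trials plus one of each trial-level
  # violation; ensemble 2 gets 12 clean; ensemble 3 gets 9 clean + 3 bad.
  mk_tr <- function(id, fov, e, ord, run = 1, shift = 1, nsucc = 5) {
    data.frame(trial_id = id, fov_id = fov, ensemble_id = e,
               trial_order = ord, run_speed = run, reg_shift = shift,
               n_targets = 5, n_success = nsucc)
  }
  trials <- rbind(
    do.call(rbind, lapply(1:12, function(i) mk_tr(i, 1, 1, i))),
    mk_tr(13, 1, 1, 13, run = 7),             # running trial
    mk_tr(14, 1, 1, 14, nsucc = 2),           # >= 50% targets failed
    mk_tr(15, 1, 1, 15, shift = 5),           # registration shift
    do.call(rbind, lapply(16:27, function(i) mk_tr(i, 1, 2, i))),
    do.call(rbind, lapply(28:36, function(i) mk_tr(i, 1, 3, i))),
    mk_tr(37, 1, 3, 37, run = 8), mk_tr(38, 1, 3, 38, run = 8),
    mk_tr(39, 1, 3, 39, shift = 6),
    do.call(rbind, lapply(40:51, function(i) mk_tr(i, 2, 4, i))),
    do.call(rbind, lapply(52:63, function(i) mk_tr(i, 3, 5, i, run = 7))),
    do.call(rbind, lapply(64:75, function(i) mk_tr(i, 4, 6, i))))

  # responses only for the cells we reason about explicitly
  resp <- expand.grid(trial_id = trials$trial_id[trials$fov_id == 1],
                      cell_id = c1$cell_id[1:50])
  resp$response <- 0.1
  stim_dataset(cells = cells, ensembles = ens, targets = targets,
               trials = trials, responses = resp)
}

# Tiny simulated experiment reused by generator/pipeline tests.
tiny_sim_config <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_cells_per_plane = 100, n_planes = 3, n_ensembles = 4,
         ensemble_size = 8, n_trials = 12, seed = seed),
    list(...))
  do.call(generator_config, args)
}
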