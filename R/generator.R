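#' Configuration of the synthetic two-photon experiment generator
#'
#' Describes the emulated preparation: a multi-plane field of view with a
#' salt-and-pepper orientation map, opsin expression, a ground-truth
#' center-surround influence profile, a photostimulation trial plan, and
#' trace noise/behavior statistics. All stochastic draws descend from
#' `seed` through named substreams (positions/tuning, ensembles, behavior,
#' noise), so a configuration is a complete, reproducible description of an
#' experiment.
#'
#' @param n_cells_per_plane Cells per imaging plane (default 500).
#' @param n_planes Imaging planes (default 3, spaced `plane_spacing` um).
#' @param fov_size FOV side, um (default 800).
#' @param plane_spacing Axial plane spacing, um (default 30).
#' @param opsin_fraction Fraction of opsin-positive (targetable) cells.
#' @param visual_fraction Fraction of visually responsive cells.
#' @param unmatched_fraction Fraction of cells not recovered by source
#'   extraction.
#' @param artifact_fraction Fraction of cells occluded by the stimulation
#'   artifact.
#' @param osi_shape1,osi_shape2 Beta-distribution parameters for cell OSIs.
#' @param truth Ground-truth nontarget influence profile: list with `A1`,
#'   `sigma1`, `A2`, `sigma2` (see [dog_profile()]) and `tuning_weights`, a
#'   named length-3 vector (`"0"`, `"45"`, `"90"`) of relative modulation
#'   for iso/oblique/ortho tuned cells (all 1 = feature-blind influence).
#' @param n_ensembles,ensemble_size Trial plan: how many ensembles of how
#'   many targets.
#' @param spread_range Range of target ensemble spreads, um.
#' @param tuning_modes Ensemble tuning modes cycled across ensembles:
#'   subset of `c("random", "cotuned", "untuned")`.
#' @param n_trials Stimulation repetitions per ensemble.
#' @param trial_period_s,stim_duration_s Trial spacing and stimulation
#'   duration, s (stimulation is delivered as 10 pulses at 10 Hz within
#'   `stim_duration_s`).
#' @param frame_rate Imaging rate, Hz (default 6).
#' @param calcium_tau Single-exponential indicator decay, s (default 1.5,
#'   GCaMP6s-like; rise is neglected at 6 Hz).
#' @param snr Trace signal-to-noise: per-frame dF/F noise SD equals
#'   `noise_ref / snr`.
#' @param noise_ref Reference evoked amplitude for the SNR definition
#'   (default 0.2 dF/F, a typical nearby nontarget response).
#' @param direct_amp Direct (target) response amplitude, dF/F.
#' @param ppsf_hwhm_radial,ppsf_hwhm_axial Off-target direct-activation
#'   falloff (half-width half-maximum), um.
#' @param neuropil_c Neuropil contamination coefficient used to build the
#'   measured trace (the analysis-side default subtracts the same value).
#' @param run_fast_fraction Fraction of trials with running above 6 cm/s.
#' @param shift_fail_fraction Fraction of trials with registration shift
#'   above 4.7 um.
#' @param target_success_rate Per-target per-trial stimulation success
#'   probability.
#' @param seed Root RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cells_per_plane = 500,
                             n_planes = 3,
                             fov_size = 800,
                             plane_spacing = 30,
                             opsin_fraction = 0.35,
                             visual_fraction = 0.5,
                             unmatched_fraction = 0.05,
                             artifact_fraction = 0.02,
                             osi_shape1 = 1.2,
                             osi_shape2 = 1.2,
                             truth = list(A1 = 0.2, sigma1 = 20,
                                          A2 = -0.02, sigma2 = 150,
                                          tuning_weights = c("0" = 1, "45" = 1,
                                                             "90" = 1)),
                             n_ensembles = 20,
                             ensemble_size = 10,
                             spread_range = c(100, 400),
                             tuning_modes = c("random", "cotuned", "untuned"),
                             n_trials = 15,
                             trial_period_s = 5,
                             stim_duration_s = 1,
                             frame_rate = 6,
                             calcium_tau = 1.5,
                             snr = 5,
                             noise_ref = 0.2,
                             direct_amp = 1,
                             ppsf_hwhm_radial = 8,
                             ppsf_hwhm_axial = 18,
                             neuropil_c = 0.7,
                             run_fast_fraction = 0.1,
                             shift_fail_fraction = 0.05,
                             target_success_rate = 0.92,
                             seed = 1L) {
  stopifnot(opsin_fraction >= 0, opsin_fraction <= 1,
            visual_fraction >= 0, visual_fraction <= 1,
            snr > 0, n_planes >= 1, ensemble_size >= 3)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

# Named substreams off the root seed (kept below 2^31).
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}

#' Generate a synthetic multi-plane cell population
#'
#' Positions are uniform within each plane; preferred orientations are
#' drawn uniformly from \{0, 45, 90, 135\} independently of position
#' (salt-and-pepper map); OSIs follow the configured Beta distribution.
#' Tuning curves are built so that the cell's folded orientation curve has
#' exactly the drawn OSI, with a modest direction bias that folding
#' removes. Deterministic per seed.
#'
#' @param config A [generator_config()].
#' @param fov_id FOV identifier (also offsets the position substream so
#'   FOVs differ).
#' @return Cell table (see [stim_dataset()]) with tuning-curve columns
#'   `tc_1..tc_8`.
#' @export
generate_fov <- function(config, fov_id = 1L) {
  n <- config$n_cells_per_plane * config$n_planes
  cells <- NULL
  with_local_seed(substream(config$seed, 11 + fov_id), {
    plane <- rep(seq_len(config$n_planes) - 1L, each = config$n_cells_per_plane)
    po <- sample(c(0, 45, 90, 135), n, replace = TRUE)
    osi <- stats::rbeta(n, config$osi_shape1, config$osi_shape2)
    amp <- stats::rlnorm(n, log(0.3), 0.4)
    dirbias <- stats::runif(n, 0, 0.3)
    vis <- stats::runif(n) < config$visual_fraction
    cells <- data.frame(
      cell_id = seq_len(n) + 100000L * fov_id,
      fov_id = fov_id,
      plane = plane,
      x = stats::runif(n, 0, config$fov_size),
      y = stats::runif(n, 0, config$fov_size),
      z = plane * config$plane_spacing,
      opsin = stats::runif(n) < config$opsin_fraction,
      power = stats::runif(n, 20, 90),
      matched = stats::runif(n) > config$unmatched_fraction,
      artifact = stats::runif(n) < config$artifact_fraction,
      visually_responsive = vis,
      p_visual = ifelse(vis, stats::runif(n, 0, 0.049),
                        stats::runif(n, 0.05, 1)),
      po = po,
      osi = osi)
    dirs <- seq(0, 315, by = 45)
    tc <- matrix(0, n, 8)
    # orientation shape: Gaussian falloff renormalized to hit exactly 0 at
    # 90 degrees, so the folded curve reproduces the drawn OSI
    oshape <- function(dth) {
      (exp(-dth^2 / (2 * 30^2)) - exp(-90^2 / (2 * 30^2))) /
        (1 - exp(-90^2 / (2 * 30^2)))
    }
    for (j in seq_along(dirs)) {
      dth <- fold_orientation(dirs[j] - po)
      ortho <- amp * (1 - osi) / (1 + osi)
      orient_resp <- ortho + (amp - ortho) * oshape(dth)
      sgn <- ifelse(((dirs[j] - po) %% 360) < 180, 1, -1)
      tc[, j] <- orient_resp * (1 + sgn * dirbias)
    }
    colnames(tc) <- paste0("tc_", 1:8)
    cells <- cbind(cells, as.data.frame(tc))
  })
  cells
}

#' Generate target ensembles with prescribed spreads and tuning modes
#'
#' Draws ensembles of opsin-positive cells inside discs whose radius is set
#' from the requested mean pairwise spread (for 10 points uniform in a disc
#' of radius R the expected spread is about 0.905 R), enforcing the 30 um
#' within-ensemble spacing rule, and restricting candidates by tuning mode
#' (`cotuned`: one orientation, OSI > 0.6; `untuned`: OSI < 0.4, mixed
#' orientations; `random`: no restriction).
#'
#' @param cells A cell table from [generate_fov()].
#' @param config A [generator_config()].
#' @return List with `ensembles` and `targets` data frames (see
#'   [stim_dataset()]).
#' @export
generate_ensembles <- function(cells, config) {
  m <- config$n_ensembles
  k <- config$ensemble_size
  modes <- rep(config$tuning_modes, length.out = m)
  spreads <- seq(config$spread_range[1], config$spread_range[2],
                 length.out = m)
  ens_rows <- list()
  tgt_rows <- list()
  with_local_seed(substream(config$seed, 23), {
    spreads <- sample(spreads)
    pool <- cells[cells$opsin, ]
    for (e in seq_len(m)) {
      R0 <- max(spreads[e] / 0.905, 40)
      picked <- NULL
      for (try in 1:100) {
        # widen the candidate disc (and, late, relax the tuning filter)
        # gradually so small pools still yield feasible ensembles
        R <- R0 * (1 + 0.04 * (try - 1))
        cx <- stats::runif(1, min(R, 400), config$fov_size - min(R, 400))
        cy <- stats::runif(1, min(R, 400), config$fov_size - min(R, 400))
        cand <- pool[(pool$x - cx)^2 + (pool$y - cy)^2 < R^2, ]
        if (modes[e] == "cotuned") {
          th <- sample(c(0, 45, 90, 135), 1)
          cand <- cand[cand$po == th & cand$osi > (if (try > 50) 0.45 else 0.6), ]
        } else if (modes[e] == "untuned") {
          cand <- cand[cand$osi < (if (try > 50) 0.6 else 0.4), ]
        }
        if (nrow(cand) < k) next
        # greedy feasible pick under the 30 um spacing rule
        ord <- sample.int(nrow(cand))
        idx <- ord[1]
        for (c2 in ord[-1]) {
          if (length(idx) == k) break
          d <- sqrt((cand$x[idx] - cand$x[c2])^2 +
                      (cand$y[idx] - cand$y[c2])^2 +
                      (cand$z[idx] - cand$z[c2])^2)
          if (all(d >= 30)) idx <- c(idx, c2)
        }
        if (length(idx) == k) { picked <- cand[idx, ]; break }
      }
      if (is.null(picked)) {
        stop("could not place ensemble ", e, " (spread ", round(spreads[e]),
             " um, mode ", modes[e], ")")
      }
      eo <- ensemble_osi(tuning_matrix(picked))
      spread <- mean_pairwise_spread(picked[, c("x", "y", "z")])
      cls <- classify_ensemble(spread, eo$ensemble_osi, eo$mean_osi)
      ens_rows[[e]] <- data.frame(
        ensemble_id = e, fov_id = picked$fov_id[1], mode = modes[e],
        spread = spread, ensemble_osi = eo$ensemble_osi,
        mean_osi = eo$mean_osi, ensemble_po = eo$ensemble_po,
        spatial_class = cls$spatial_class, tuning_class = cls$tuning_class)
      tgt_rows[[e]] <- data.frame(
        ensemble_id = e, cell_id = picked$cell_id,
        x = picked$x, y = picked$y, z = picked$z, plane = picked$plane,
        detected = picked$matched)
    }
  })
  list(ensembles = do.call(rbind, ens_rows),
       targets = do.call(rbind, tgt_rows))
}

#' Ground-truth expected responses of every cell to one ensemble
#'
#' Nontarget cells follow the configured center-surround profile of the
#' minimal 3D target distance, scaled by the feature-modulation weight for
#' the cell's relative tuning (applied to tuned, visually responsive cells
#' when the ensemble itself is tuned). Targets respond with `direct_amp`;
#' cells inside the off-target zone receive a direct-activation surrogate
#' with a PPSF-shaped falloff, so that the off-target exclusion logic has
#' real work to do.
#'
#' @param cells Cell table.
#' @param targets Target rows of one ensemble.
#' @param ensemble_po Preferred orientation of the ensemble (degrees), used
#'   for feature modulation.
#' @param config A [generator_config()].
#' @return Numeric vector of expected dF/F responses, one per cell.
#' @export
generate_ground_truth_response <- function(cells, targets, ensemble_po,
                                           config) {
  tr <- config$truth
  md <- min_target_distance(cbind(cells$x, cells$y, cells$z),
                            cbind(targets$x, targets$y, targets$z))
  resp <- dog_profile(md, tr$A1, tr$sigma1, tr$A2, tr$sigma2)
  tw <- tr$tuning_weights
  if (!is.null(tw) && !all(tw == tw[1])) {
    lab <- relative_tuning_split(cells$po, ensemble_po, osi = cells$osi,
                                 p_visual = cells$p_visual)
    wvec <- ifelse(lab == "untuned", 1, tw[as.character(lab)])
    resp <- resp * wvec
  }
  # direct-activation surrogate in the off-target zone and at targets
  sr <- config$ppsf_hwhm_radial / sqrt(2 * log(2))
  sz <- config$ppsf_hwhm_axial / sqrt(2 * log(2))
  direct <- rep(0, nrow(cells))
  for (j in seq_len(nrow(targets))) {
    r2 <- (cells$x - targets$x[j])^2 + (cells$y - targets$y[j])^2
    dz2 <- (cells$z - targets$z[j])^2
    direct <- pmax(direct,
                   config$direct_amp * exp(-r2 / (2 * sr^2) - dz2 / (2 * sz^2)))
  }
  off <- off_target_mask(cells, targets, target_ids = targets$cell_id)
  resp[off] <- direct[off]
  resp[cells$cell_id %in% targets$cell_id] <- config$direct_amp
  resp
}

#' Synthesize a recording: trial table plus fluorescence traces
#'
#' Lays trials out in a shuffled block design (each ensemble stimulated
#' `n_trials` times), draws running speed, registration shift and
#' per-target success flags at the configured rates, and renders per-cell
#' fluorescence: the expected response enters as a calcium transient
#' (plateau during the 1 s stimulation, single-exponential decay after,
#' scaled so that the analysis-window mean of the noiseless transient
#' equals the expected response, i.e. ground truth is expressed in
#' measured-response units), on top of a slowly drifting baseline, with
#' per-frame Gaussian dF/F noise of SD `noise_ref / snr` and a contaminated
#' neuropil channel.
#'
#' @param cells Cell table.
#' @param ensembles,targets From [generate_ensembles()].
#' @param truth Cells-by-ensembles matrix of expected responses (from
#'   [generate_ground_truth_response()]).
#' @param config A [generator_config()].
#' @return List: `trials` (trial table with stim frame ranges), `F`,
#'   `Fneu` (cells x frames matrices), `frame_rate`.
#' @export
generate_recording <- function(cells, ensembles, targets, truth, config) {
  m <- nrow(ensembles)
  n_tr <- m * config$n_trials
  fpt <- round(config$trial_period_s * config$frame_rate)       # frames/trial
  stim_len <- round(config$stim_duration_s * config$frame_rate)
  stim_off <- 10L                                               # within trial
  n_frames <- n_tr * fpt
  nc <- nrow(cells)
  tau_f <- config$calcium_tau * config$frame_rate

  with_local_seed(substream(config$seed, 37), {
    ens_seq <- sample(rep(ensembles$ensemble_id, config$n_trials))
    run_fast <- stats::runif(n_tr) < config$run_fast_fraction
    run_speed <- ifelse(run_fast, stats::runif(n_tr, 6.5, 12),
                        stats::runif(n_tr, 0, 4))
    shift_bad <- stats::runif(n_tr) < config$shift_fail_fraction
    reg_shift <- ifelse(shift_bad, stats::runif(n_tr, 5, 8),
                        stats::runif(n_tr, 0, 4))
    k <- config$ensemble_size
    succ <- matrix(stats::runif(n_tr * k) < config$target_success_rate,
                   n_tr, k)
    trials <- data.frame(
      trial_id = seq_len(n_tr),
      fov_id = cells$fov_id[1],
      ensemble_id = ens_seq,
      trial_order = seq_len(n_tr),
      run_speed = run_speed,
      reg_shift = reg_shift,
      n_targets = k,
      n_success = rowSums(succ),
      frame_start = (seq_len(n_tr) - 1L) * fpt + stim_off + 1L,
      frame_end = (seq_len(n_tr) - 1L) * fpt + stim_off + stim_len)
  })

  # noiseless transient shape sampled on the frame grid, calibrated so the
  # analysis-window mean (stim frames + 1) is exactly 1
  shape <- numeric(fpt - stim_off)
  shape[seq_len(stim_len)] <- 1
  post <- (stim_len + 1):length(shape)
  shape[post] <- exp(-(seq_along(post)) / tau_f)
  shape <- shape / mean(shape[seq_len(stim_len + 1)])

  dff_sig <- matrix(0, nc, n_frames)
  for (t in seq_len(nrow(trials))) {
    amp <- truth[, match(trials$ensemble_id[t], ensembles$ensemble_id)]
    fr <- (trials$frame_start[t]):min(n_frames,
                                      trials$frame_start[t] + length(shape) - 1)
    dff_sig[, fr] <- dff_sig[, fr] +
      outer(amp, shape[seq_along(fr)])
  }

  with_local_seed(substream(config$seed, 53), {
    noise_sd <- config$noise_ref / config$snr
    f0 <- stats::runif(nc, 80, 120)
    tgrid <- seq_len(n_frames)
    drift <- 1 + 0.1 * sin(2 * pi * tgrid / 3000)
    neuro_scale <- stats::runif(nc, 0.8, 1.2)
    bg <- 30 * (1 + 0.05 * sin(2 * pi * tgrid / 2000))
    Fneu <- outer(neuro_scale, bg) +
      matrix(stats::rnorm(nc * n_frames, 0, 0.5), nc)
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(nc * n_frames, 0, noise_sd), nc)
    } else 0
    Fmat <- (f0 %o% drift) * (1 + dff_sig + noise) + config$neuropil_c * Fneu
  })
  list(trials = trials, F = Fmat, Fneu = Fneu, frame_rate = config$frame_rate)
}

#' Simulate a complete synthetic photostimulation experiment
#'
#' Population, ensembles, ground-truth responses and traces, bundled with
#' the configuration. Deterministic per `config$seed`.
#'
#' @param config A [generator_config()].
#' @return A `sim_experiment` list: `cells`, `ensembles`, `targets`,
#'   `trials`, `truth` (cells x ensembles matrix), `F`, `Fneu`,
#'   `frame_rate`, `config`.
#' @export
simulate_experiment <- function(config) {
  cells <- generate_fov(config)
  eg <- generate_ensembles(cells, config)
  truth <- vapply(seq_len(nrow(eg$ensembles)), function(e) {
    tg <- eg$targets[eg$targets$ensemble_id == eg$ensembles$ensemble_id[e], ]
    generate_ground_truth_response(cells, tg, eg$ensembles$ensemble_po[e],
                                   config)
  }, numeric(nrow(cells)))
  rec <- generate_recording(cells, eg$ensembles, eg$targets, truth, config)
  structure(list(cells = cells, ensembles = eg$ensembles,
                 targets = eg$targets, trials = rec$trials, truth = truth,
                 F = rec$F, Fneu = rec$Fneu, frame_rate = rec$frame_rate,
                 config = config),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d cells, %d ensembles, %d trials, %d frames at %g Hz\n",
              nrow(x$cells), nrow(x$ensembles), nrow(x$trials),
              ncol(x$F), x$frame_rate))
  invisible(x)
}
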