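#' Radial response profile to a single stimulated point
#'
#' Stimulates one location in an (untuned by default) model, and averages
#' the excitatory response over thin annuli of distance from the target.
#'
#' @param config A [model_config()].
#' @param ops Optional precomputed operators.
#' @param bin Annulus width, um (default 2).
#' @param theta Orientation level of the stimulated point (default first).
#' @return Data frame `distance`, `response` (orientation-summed response).
#' @export
point_stim_profile <- function(config, ops = NULL, bin = 2, theta = 0) {
  if (is.null(ops)) ops <- build_connectivity(config)
  ctr <- config$domain_size / 2
  s <- stim_field(data.frame(x = ctr, y = ctr, theta = theta), config)
  r <- solve_linear_response(ops, s, config)
  n <- config$n_nodes
  sp <- config$grid_spacing
  idx <- 0:(n - 1)
  ic <- round(ctr / sp) + 1
  dx <- sp * pmin(abs(idx + 1 - ic), n - abs(idx + 1 - ic))
  D <- sqrt(outer(dx^2, dx^2, "+"))
  v <- apply(r$values, c(1, 2), sum)          # sum over orientation levels
  b <- floor(as.vector(D) / bin)
  m <- tapply(as.vector(v), b, mean)
  d <- (as.numeric(names(m)) + 0.5) * bin
  data.frame(distance = d, response = as.numeric(m))
}

#' Zero crossing and activation/suppression ratio of a model profile
#'
#' @param profile Data frame `distance`, `response` (e.g. from
#'   [point_stim_profile()]).
#' @param d_max Restrict the summary to distances below this, um.
#' @return List `zero_crossing` (first positive-to-negative sign change,
#'   linearly interpolated; `NA` if none) and `act_supp_ratio`
#'   (`max / |min|`; `NA` if the profile never goes negative).
#' @export
profile_summary <- function(profile, d_max = 700) {
  keep <- profile$distance <= d_max
  d <- profile$distance[keep]
  v <- profile$response[keep]
  zc <- NA_real_
  s <- which(v[-length(v)] > 0 & v[-1] <= 0)
  if (length(s)) {
    i <- s[1]
    zc <- d[i] + (d[i + 1] - d[i]) * v[i] / (v[i] - v[i + 1])
  }
  ratio <- if (min(v) < 0) max(v) / abs(min(v)) else NA_real_
  list(zero_crossing = zc, act_supp_ratio = ratio)
}

#' Sweep recurrent strength and narrow-scale weight against a regime box
#'
#' For every `(w_ee, kappa)` grid point, computes the point-stimulation
#' response profile of the (untuned, spatial) model and summarizes it by
#' its zero crossing and activation/suppression ratio, flagging whether the
#' summary falls inside the supplied regime box. Parameter sets whose
#' weights exceed the stability bound are skipped with a log entry.
#'
#' @param w_ee_values,kappa_values Sweep grids.
#' @param box A [regime_box()] (e.g. centered on the reference fit summary).
#' @param config Base [model_config()] (feature kernels are forced untuned,
#'   orientation collapsed to one level for speed).
#' @return Data frame: `w_ee`, `kappa`, `zero_crossing`, `act_supp_ratio`,
#'   `in_box`, `stable`.
#' @export
sweep_regime <- function(w_ee_values = seq(0.05, 0.6, length.out = 12),
                         kappa_values = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                         box = NULL,
                         config = model_config()) {
  rows <- list()
  for (k in kappa_values) {
    cfg <- model_config(domain_size = config$domain_size,
                        grid_spacing = config$grid_spacing,
                        n_orientations = 1,
                        w_ee = 0, w_eie = config$w_eie,
                        sigma_e_broad = config$sigma_e_broad,
                        sigma_i_broad = config$sigma_i_broad,
                        sigma_e_narrow = config$sigma_e_narrow,
                        sigma_i_narrow = config$sigma_i_narrow,
                        kappa_e = k, kappa_i = config$kappa_i,
                        feature_ee = untuned_features(),
                        feature_ei = untuned_features(),
                        feature_ie = untuned_features(),
                        stim_amplitude = config$stim_amplitude,
                        mode = "expansion")
    for (w in w_ee_values) {
      cfg$w_ee <- w
      stable <- TRUE
      summ <- tryCatch({
        ops <- build_connectivity(cfg)
        prof <- withCallingHandlers(
          point_stim_profile(cfg, ops),
          warning = function(cond) {
            if (grepl("spectral radius", conditionMessage(cond))) {
              stable <<- FALSE
              invokeRestart("muffleWarning")
            }
          })
        profile_summary(prof)
      }, error = function(e) list(zero_crossing = NA_real_,
                                  act_supp_ratio = NA_real_))
      rows[[length(rows) + 1]] <- data.frame(
        w_ee = w, kappa = k,
        zero_crossing = summ$zero_crossing,
        act_supp_ratio = summ$act_supp_ratio,
        in_box = if (is.null(box)) NA else
          in_regime_box(box, summ$zero_crossing, summ$act_supp_ratio),
        stable = stable)
    }
  }
  do.call(rbind, rows)
}

#' Place targets with a prescribed mean pairwise spread
#'
#' Samples points uniformly in a disc, recenters them, and rescales so the
#' realized mean pairwise distance equals the requested spread exactly.
#'
#' @param spread Desired mean pairwise distance, um.
#' @param n_targets Number of targets (default 10).
#' @param center Length-2 center of the ensemble, um.
#' @param seed Seed for the placement.
#' @return Data frame `x`, `y`.
#' @export
spread_targets <- function(spread, n_targets = 10, center = c(700, 700),
                           seed = 1L) {
  out <- NULL
  with_local_seed(seed, {
    ang <- stats::runif(n_targets, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_targets))
    x <- rad * cos(ang); y <- rad * sin(ang)
    x <- x - mean(x); y <- y - mean(y)
    s0 <- mean(stats::dist(cbind(x, y)))
    out <- data.frame(x = center[1] + x * spread / s0,
                      y = center[2] + y * spread / s0)
  })
  out
}

#' Sweep ensemble spread: surround suppression and pathway recruitment
#'
#' Stimulates 10-target ensembles of decreasing spatial spread in the
#' (untuned) model and measures (i) the mean response over grid locations
#' 50-150 um from the nearest target - the surround-suppression readout -
#' and (ii) the spatial L2 magnitude of each synaptic pathway. The model
#' prediction is that compact ensembles recruit more suppression, and that
#' the inhibitory pathway magnitude grows faster than the summed excitatory
#' pathways as spread shrinks.
#'
#' @param spreads Ensemble spreads to test, um.
#' @param config Base [model_config()]; defaults to the data-regime spatial
#'   parameterization `w_ee = 0.2`, `kappa = 0.2` (see the methods
#'   vignette).
#' @param n_targets Targets per ensemble (default 10).
#' @param annulus Distance range of the suppression readout, um.
#' @param seed Placement seed.
#' @return Data frame: `spread`, `suppression_50_150`, `mag_mono_ee`,
#'   `mag_di_eee`, `mag_di_eie`, `mag_exc` (mono + di_eee).
#' @export
sweep_spread <- function(spreads = c(50, 100, 150, 200, 300, 400),
                         config = model_config(w_ee = 0.2, kappa_e = 0.2,
                                               n_orientations = 1,
                                               feature_ee = untuned_features(),
                                               feature_ei = untuned_features(),
                                               feature_ie = untuned_features()),
                         n_targets = 10, annulus = c(50, 150), seed = 42L) {
  ops <- build_connectivity(config)
  n <- config$n_nodes
  sp <- config$grid_spacing
  gx <- (0:(n - 1)) * sp
  L <- config$domain_size
  ctr <- c(L / 2, L / 2)
  l2 <- function(f) sqrt(sum(f$values^2) * sp^2)
  rows <- lapply(seq_along(spreads), function(i) {
    tg <- spread_targets(spreads[i], n_targets, ctr, seed = seed)
    s <- stim_field(tg, config)
    pw <- decompose_pathways(ops, s, config)
    D <- matrix(Inf, n, n)
    for (j in seq_len(n_targets)) {
      dx <- pmin(abs(gx - tg$x[j]), L - abs(gx - tg$x[j]))
      dy <- pmin(abs(gx - tg$y[j]), L - abs(gx - tg$y[j]))
      D <- pmin(D, sqrt(outer(dx^2, dy^2, "+")))
    }
    tot <- apply(pw$total$values, c(1, 2), sum)
    ann <- D >= annulus[1] & D <= annulus[2]
    data.frame(spread = spreads[i],
               suppression_50_150 = mean(tot[ann]),
               mag_mono_ee = l2(pw$mono_ee),
               mag_di_eee = l2(pw$di_eee),
               mag_di_eie = l2(pw$di_eie),
               mag_exc = l2(pw$mono_ee) + l2(pw$di_eee))
  })
  do.call(rbind, rows)
}

#' Iso/ortho distance curves with and without tuned inhibitory wiring
#'
#' Stimulates a cotuned 10-target ensemble and compares the
#' distance-resolved predicted responses of iso- and ortho-preferring
#' cells between a model whose only orientation-specific wiring is
#' recurrent excitation (`E-E` tuned, `E-I`/`I-E` untuned) and the full
#' model with like-to-like inhibitory wiring.
#'
#' @param config Base [model_config()] (the tuned feature kernels are taken
#'   from here).
#' @param spread Ensemble spread, um (default 150, compact).
#' @param bin_width Distance-bin width, um.
#' @param d_max Curve range, um (default 250, the experimental analysis
#'   range).
#' @param grid_step Readout-cell grid step within the FOV, um.
#' @param seed Target-placement seed.
#' @return Data frame: `model` (`"ee_tuned"` or `"full_tuned"`),
#'   `delta_theta` (0 or 90), `bin_center`, `mean`.
#' @export
tuning_contrast <- function(config = model_config(), spread = 150,
                            bin_width = 25, d_max = 250, grid_step = 10,
                            seed = 1L) {
  fov <- 800
  tg <- spread_targets(spread, 10, c(fov / 2, fov / 2), seed = seed)
  tg$theta <- 0
  cells <- expand.grid(x = seq(grid_step / 2, fov - grid_step / 2, grid_step),
                       y = seq(grid_step / 2, fov - grid_step / 2, grid_step))
  md <- min_target_distance(cbind(cells$x, cells$y, 0),
                            cbind(tg$x, tg$y, 0))
  keep <- md <= d_max
  variants <- list(
    ee_tuned = model_config(
      domain_size = config$domain_size, grid_spacing = config$grid_spacing,
      n_orientations = config$n_orientations, w_ee = config$w_ee,
      w_eie = config$w_eie, sigma_e_broad = config$sigma_e_broad,
      sigma_i_broad = config$sigma_i_broad,
      sigma_e_narrow = config$sigma_e_narrow,
      sigma_i_narrow = config$sigma_i_narrow,
      kappa_e = config$kappa_e, kappa_i = config$kappa_i,
      feature_ee = config$feature_ee,
      feature_ei = untuned_features(), feature_ie = untuned_features(),
      stim_amplitude = config$stim_amplitude, mode = config$mode),
    full_tuned = config)
  rows <- list()
  for (vn in names(variants)) {
    ops <- build_connectivity(variants[[vn]])
    for (po in c(0, 90)) {
      cells$po <- po
      pr <- predict_cell_responses(cells, tg, variants[[vn]], ops = ops,
                                   fov_size = fov)
      curve <- bin_distance_response(md[keep], pr[keep], bin_width,
                                     max_distance = d_max)
      rows[[length(rows) + 1]] <- data.frame(
        model = vn, delta_theta = po, bin_center = curve$bin_center,
        mean = curve$mean, n = curve$n)
    }
  }
  do.call(rbind, rows)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulate a recording, extract per-trial responses, apply the exclusion
#' rules, build the pooled distance-response curve, fit the center-surround
#' profile and summarize it. Deterministic per `gen_config$seed`.
#'
#' @param gen_config A [generator_config()].
#' @param ana_config An [analysis_config()].
#' @return A `run_report` list: `audit`, `curve`, `fit`, `summary`,
#'   `n_pairs`, `gen_config`, `ana_config`, and `pairs` (the per-(cell,
#'   ensemble) table).
#' @export
run_end_to_end <- function(gen_config = generator_config(),
                           ana_config = analysis_config()) {
  sim <- simulate_experiment(gen_config)
  ds <- extract_responses(sim, ana_config)
  ex <- apply_exclusions(ds)
  if (nrow(ex$data$ensembles) == 0 || nrow(ex$data$responses) == 0) {
    return(structure(list(audit = ex$audit, curve = NULL, fit = NULL,
                          summary = NULL, n_pairs = 0L, empty = TRUE,
                          gen_config = gen_config, ana_config = ana_config),
                     class = "run_report"))
  }
  pairs <- pair_responses(ex$data, distance_method = ana_config$distance_method)
  curve <- distance_response_curve(pairs, bin_width = ana_config$bin_width)
  fit <- fit_dog(pairs$min_distance, pairs$response)
  structure(list(audit = ex$audit, curve = curve, fit = fit,
                 summary = dog_summary(fit), n_pairs = nrow(pairs),
                 empty = FALSE, pairs = pairs,
                 gen_config = gen_config, ana_config = ana_config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  if (isTRUE(x$empty)) {
    cat("  no data survived the exclusion rules\n")
    return(invisible(x))
  }
  cat(sprintf("  %d (cell, ensemble) pairs\n", x$n_pairs))
  print(x$fit)
  cat("  exclusion audit:\n")
  for (nm in names(x$audit)) {
    cat(sprintf("    %-28s %d\n", nm, x$audit[[nm]]))
  }
  invisible(x)
}
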