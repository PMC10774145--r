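#' Photostimulation dataset container
#'
#' A light S3 container tying together the tables the analysis operates on.
#' All tables are plain data frames so they can be round-tripped through
#' CSV.
#'
#' @param cells Per-cell table: `cell_id`, `fov_id`, `plane`, `x`, `y`, `z`
#'   (um), `opsin`, `power`, `matched`, `artifact`, `visually_responsive`,
#'   `p_visual`, `po`, `osi` (tuning-curve columns `tc_1..tc_8` optional).
#' @param ensembles Per-ensemble table: `ensemble_id`, `fov_id`, `spread`,
#'   `ensemble_osi`, `mean_osi`, `ensemble_po`.
#' @param targets Target list: `ensemble_id`, `cell_id`, `x`, `y`, `z`,
#'   `plane`, `detected`.
#' @param trials Trial table: `trial_id`, `fov_id`, `ensemble_id`,
#'   `trial_order`, `run_speed` (cm/s), `reg_shift` (um), `n_targets`,
#'   `n_success`.
#' @param responses Per-(trial, cell) evoked responses: `trial_id`,
#'   `cell_id`, `response`.
#' @param fovs Optional FOV table (`fov_id`); derived from `cells` when
#'   missing.
#' @return A `stim_dataset`.
#' @export
stim_dataset <- function(cells, ensembles, targets, trials, responses,
                         fovs = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")))
    }
  }
  need(cells, c("cell_id", "fov_id", "plane", "x", "y", "z", "matched",
                "artifact", "visually_responsive", "po", "osi"), "cells")
  need(ensembles, c("ensemble_id", "fov_id"), "ensembles")
  need(targets, c("ensemble_id", "x", "y", "z", "plane", "detected"), "targets")
  need(trials, c("trial_id", "fov_id", "ensemble_id", "trial_order",
                 "run_speed", "reg_shift", "n_targets", "n_success"), "trials")
  need(responses, c("trial_id", "cell_id", "response"), "responses")
  if (is.null(fovs)) fovs <- data.frame(fov_id = sort(unique(cells$fov_id)))
  structure(list(fovs = fovs, cells = cells, ensembles = ensembles,
                 targets = targets, trials = trials, responses = responses),
            class = "stim_dataset")
}

#' @export
print.stim_dataset <- function(x, ...) {
  cat(sprintf("<stim_dataset> %d FOV(s), %d cells, %d ensembles, %d trials, %d responses\n",
              nrow(x$fovs), nrow(x$cells), nrow(x$ensembles),
              nrow(x$trials), nrow(x$responses)))
  invisible(x)
}

#' Apply the exclusion rules to a photostimulation dataset
#'
#' Filters the dataset in the fixed order FOV, ensemble, trial, cell and
#' returns the filtered dataset together with an audit log counting
#' removals per rule. The rules:
#'
#' * FOV: fewer than 5% of cells visually responsive; more than 50% of
#'   trials while running (> `run_max` cm/s); fewer than 250 detected cells.
#' * Ensemble: more than 33% of targets not detected; more than 50% of
#'   attempted trials failed; fewer than 10 surviving repetitions.
#' * Trial: running faster than 6 cm/s; 50% or more of targets failed to
#'   respond; registration shift above 4.7 um.
#' * Cell (per trial): in the off-target zone of the trial's ensemble (or a
#'   target itself); targeted in the immediately preceding trial;
#'   artifact-occluded; not matched to a detected source.
#'
#' A removed item is attributed to the first rule (in the order above) it
#' violates. The operation is idempotent.
#'
#' @param dataset A [stim_dataset()].
#' @param run_max Running-speed threshold, cm/s (default 6).
#' @param shift_max Registration-shift threshold, um (default 4.7).
#' @param fail_frac Trial target-failure fraction threshold (default 0.5).
#' @param min_reps Minimum surviving repetitions per ensemble (default 10).
#' @param min_cells Minimum detected cells per FOV (default 250).
#' @param min_visual_frac Minimum visually responsive fraction (default 0.05).
#' @param max_run_frac Maximum running-trial fraction per FOV (default 0.5).
#' @param undetected_frac Maximum fraction of undetected targets (default 1/3).
#' @return List: `data` (filtered `stim_dataset`) and `audit` (named list of
#'   removal counts per rule).
#' @export
apply_exclusions <- function(dataset, run_max = 6, shift_max = 4.7,
                             fail_frac = 0.5, min_reps = 10, min_cells = 250,
                             min_visual_frac = 0.05, max_run_frac = 0.5,
                             undetected_frac = 1 / 3) {
  stopifnot(inherits(dataset, "stim_dataset"))
  cells <- dataset$cells
  ens <- dataset$ensembles
  targets <- dataset$targets
  trials <- dataset$trials
  resp <- dataset$responses
  audit <- list()

  ## --- FOV rules -----------------------------------------------------
  fov_ids <- dataset$fovs$fov_id
  fov_visual <- vapply(fov_ids, function(f) {
    cc <- cells[cells$fov_id == f & cells$matched, ]
    if (!nrow(cc)) 0 else mean(cc$visually_responsive)
  }, numeric(1))
  fov_ncells <- vapply(fov_ids, function(f) {
    sum(cells$fov_id == f & cells$matched)
  }, numeric(1))
  fov_runfrac <- vapply(fov_ids, function(f) {
    tt <- trials[trials$fov_id == f, ]
    if (!nrow(tt)) 0 else mean(tt$run_speed > run_max)
  }, numeric(1))
  bad_visual <- fov_visual < min_visual_frac
  bad_run <- fov_runfrac > max_run_frac
  bad_ncell <- fov_ncells < min_cells
  audit$fov_low_visual <- sum(bad_visual)
  audit$fov_running <- sum(!bad_visual & bad_run)
  audit$fov_few_cells <- sum(!bad_visual & !bad_run & bad_ncell)
  keep_fov <- fov_ids[!(bad_visual | bad_run | bad_ncell)]

  cells <- cells[cells$fov_id %in% keep_fov, ]
  ens <- ens[ens$fov_id %in% keep_fov, ]
  trials <- trials[trials$fov_id %in% keep_fov, ]
  targets <- targets[targets$ensemble_id %in% ens$ensemble_id, ]

  ## --- trial pass flags (needed for the ensemble repetition rule) ----
  tr_run <- trials$run_speed > run_max
  tr_fail <- (trials$n_success / trials$n_targets) <= fail_frac
  tr_shift <- trials$reg_shift > shift_max
  tr_bad <- tr_run | tr_fail | tr_shift

  ## --- ensemble rules ------------------------------------------------
  e_ids <- ens$ensemble_id
  und <- vapply(e_ids, function(e) {
    tg <- targets[targets$ensemble_id == e, ]
    if (!nrow(tg)) 1 else mean(!tg$detected)
  }, numeric(1))
  failfrac <- vapply(e_ids, function(e) {
    i <- trials$ensemble_id == e
    if (!any(i)) 1 else mean(tr_fail[i])
  }, numeric(1))
  reps <- vapply(e_ids, function(e) {
    sum(trials$ensemble_id == e & !tr_bad)
  }, numeric(1))
  bad_und <- und > undetected_frac
  bad_fail <- failfrac > fail_frac
  bad_reps <- reps < min_reps
  audit$ensemble_undetected <- sum(bad_und)
  audit$ensemble_failed_trials <- sum(!bad_und & bad_fail)
  audit$ensemble_few_reps <- sum(!bad_und & !bad_fail & bad_reps)
  keep_ens <- e_ids[!(bad_und | bad_fail | bad_reps)]

  in_ens <- trials$ensemble_id %in% keep_ens
  audit$trial_running <- sum(in_ens & tr_run)
  audit$trial_target_failure <- sum(in_ens & !tr_run & tr_fail)
  audit$trial_registration_shift <- sum(in_ens & !tr_run & !tr_fail & tr_shift)
  keep_trials <- trials[in_ens & !tr_bad, ]
  ens <- ens[ens$ensemble_id %in% keep_ens, ]
  targets <- targets[targets$ensemble_id %in% keep_ens, ]

  ## --- cell rules (per response row) ---------------------------------
  resp <- resp[resp$trial_id %in% keep_trials$trial_id, ]
  trial_ens <- keep_trials$ensemble_id[match(resp$trial_id, keep_trials$trial_id)]
  ci <- match(resp$cell_id, cells$cell_id)

  # off-target zone per ensemble: cells x ensembles lookup matrix
  off_mat <- vapply(keep_ens, function(e) {
    tg <- targets[targets$ensemble_id == e, ]
    off_target_mask(cells, tg, target_ids = tg$cell_id)
  }, logical(nrow(cells)))
  if (is.null(dim(off_mat))) off_mat <- matrix(off_mat, nrow = nrow(cells))
  r_off <- off_mat[cbind(ci, match(trial_ens, keep_ens))]

  # targeted in the immediately preceding trial (within FOV recording order)
  prev_of <- function(tr) {
    o <- order(tr$trial_order)
    prev <- rep(NA, nrow(tr))
    prev[o[-1]] <- tr$trial_id[o[-length(o)]]
    prev
  }
  all_tr <- dataset$trials[dataset$trials$fov_id %in% keep_fov, ]
  tgt_key <- paste(dataset$targets$ensemble_id, dataset$targets$cell_id)
  r_prev <- rep(FALSE, nrow(resp))
  if (nrow(all_tr) > 0 && nrow(resp) > 0) {
    prev_id <- unlist(lapply(split(all_tr, all_tr$fov_id), function(tt) {
      stats::setNames(prev_of(tt), tt$trial_id)
    }))
    names(prev_id) <- sub("^.*\\.", "", names(prev_id))
    prev_for_resp <- prev_id[as.character(resp$trial_id)]
    prev_ens <- dataset$trials$ensemble_id[match(prev_for_resp,
                                                 dataset$trials$trial_id)]
    r_prev <- !is.na(prev_ens) & paste(prev_ens, resp$cell_id) %in% tgt_key
  }

  r_artifact <- cells$artifact[ci]
  r_unmatched <- !cells$matched[ci]

  audit$cell_off_target <- sum(r_off, na.rm = TRUE)
  audit$cell_previous_trial <- sum(!r_off & r_prev, na.rm = TRUE)
  audit$cell_artifact <- sum(!r_off & !r_prev & r_artifact, na.rm = TRUE)
  audit$cell_unmatched <- sum(!r_off & !r_prev & !r_artifact & r_unmatched,
                              na.rm = TRUE)
  drop_row <- r_off | r_prev | r_artifact | r_unmatched
  drop_row[is.na(drop_row)] <- TRUE
  resp <- resp[!drop_row, ]

  out <- stim_dataset(cells = cells, ensembles = ens, targets = targets,
                      trials = keep_trials, responses = resp,
                      fovs = dataset$fovs[dataset$fovs$fov_id %in% keep_fov, ,
                                          drop = FALSE])
  list(data = out, audit = audit)
}

#' Collapse a filtered dataset to per-(cell, ensemble) responses
#'
#' Averages each cell's response across the (included) trials of each
#' ensemble and attaches the pair's minimal 3D distance to any attempted
#' target and the cell's relative-tuning label.
#'
#' @param dataset A filtered [stim_dataset()] (from [apply_exclusions()]).
#' @param distance_method `"3d"` (default) or `"2d"`, see
#'   [min_target_distance()].
#' @return Data frame: `ensemble_id`, `cell_id`, `response`, `n_trials`,
#'   `min_distance`, `delta_theta`.
#' @export
pair_responses <- function(dataset, distance_method = "3d") {
  stopifnot(inherits(dataset, "stim_dataset"))
  resp <- dataset$responses
  trials <- dataset$trials
  cells <- dataset$cells
  resp$ensemble_id <- trials$ensemble_id[match(resp$trial_id, trials$trial_id)]
  key <- paste(resp$ensemble_id, resp$cell_id)
  agg <- data.frame(
    ensemble_id = tapply(resp$ensemble_id, key, `[`, 1),
    cell_id = tapply(resp$cell_id, key, `[`, 1),
    response = as.numeric(tapply(resp$response, key, mean)),
    n_trials = as.integer(tapply(resp$response, key, length)),
    row.names = NULL)
  ci <- match(agg$cell_id, cells$cell_id)
  out_list <- split(seq_len(nrow(agg)), agg$ensemble_id)
  agg$min_distance <- NA_real_
  agg$delta_theta <- factor(rep(NA, nrow(agg)),
                            levels = c("0", "45", "90", "untuned"))
  for (e in names(out_list)) {
    i <- out_list[[e]]
    tg <- dataset$targets[dataset$targets$ensemble_id == agg$ensemble_id[i][1], ]
    agg$min_distance[i] <- min_target_distance(
      cbind(cells$x[ci[i]], cells$y[ci[i]], cells$z[ci[i]]),
      cbind(tg$x, tg$y, tg$z), method = distance_method)
    epo <- dataset$ensembles$ensemble_po[
      dataset$ensembles$ensemble_id == agg$ensemble_id[i][1]]
    agg$delta_theta[i] <- relative_tuning_split(
      cells$po[ci[i]], epo, osi = cells$osi[ci[i]],
      p_visual = cells$p_visual[ci[i]])
  }
  agg
}
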