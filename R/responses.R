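#' Analysis configuration
#'
#' Bundles the tunable parameters of the trace-level analysis.
#'
#' @param neuropil_c Neuropil subtraction coefficient (default 0.7).
#' @param f0_window Baseline window, frames (default 1000).
#' @param f0_stride Baseline evaluation stride, frames (default 25; see
#'   [dff()]).
#' @param f0_percentile Baseline percentile (default 0.10).
#' @param f0_smooth Pre-percentile smoothing frames (default 5, see [dff()]).
#' @param window_extra Frames appended after the stimulation frames when
#'   averaging the evoked response (default 1).
#' @param baseline_frames Pre-stimulus frames averaged as the per-trial
#'   baseline (default 3).
#' @param bin_width Distance-bin width for response curves, um (default 15).
#' @param distance_method `"3d"` or `"2d"` minimal target distance.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(neuropil_c = 0.7, f0_window = 1000,
                            f0_stride = 25, f0_percentile = 0.10,
                            f0_smooth = 5,
                            window_extra = 1, baseline_frames = 3,
                            bin_width = 15, distance_method = "3d") {
  structure(as.list(environment()), class = "analysis_config")
}

#' Extract per-trial evoked responses from a simulated recording
#'
#' Computes dF/F for every cell ([dff()]: neuropil subtraction,
#' rolling-percentile baseline) and measures each trial's evoked response
#' as the mean dF/F over the stimulation frames plus `window_extra`
#' trailing frame(s), minus the mean over the `baseline_frames` immediately
#' preceding stimulation. Returns the assembled [stim_dataset()] ready for
#' [apply_exclusions()].
#'
#' @param sim A `sim_experiment` from [simulate_experiment()], or any list
#'   with `cells`, `ensembles`, `targets`, `trials`, `F`, `Fneu`.
#' @param config An [analysis_config()].
#' @return A [stim_dataset()]. Cells whose baseline was non-positive
#'   anywhere are marked unmatched (their dF/F is undefined).
#' @export
extract_responses <- function(sim, config = analysis_config()) {
  nc <- nrow(sim$cells)
  n_frames <- ncol(sim$F)
  dmat <- matrix(NA_real_, nc, n_frames)
  bad <- logical(nc)
  for (i in seq_len(nc)) {
    d <- dff(sim$F[i, ], sim$Fneu[i, ], c = config$neuropil_c,
             window = config$f0_window, stride = config$f0_stride,
             percentile = config$f0_percentile, f0_smooth = config$f0_smooth)
    if (!attr(d, "valid")) bad[i] <- TRUE else dmat[i, ] <- d
  }
  tr <- sim$trials
  nt <- nrow(tr)
  resp <- matrix(NA_real_, nc, nt)
  for (t in seq_len(nt)) {
    win <- tr$frame_start[t]:min(n_frames, tr$frame_end[t] + config$window_extra)
    pre <- max(1, tr$frame_start[t] - config$baseline_frames):(tr$frame_start[t] - 1)
    resp[, t] <- rowMeans(dmat[, win, drop = FALSE]) -
      rowMeans(dmat[, pre, drop = FALSE])
  }
  cells <- sim$cells
  cells$matched <- cells$matched & !bad
  responses <- data.frame(
    trial_id = rep(tr$trial_id, each = nc),
    cell_id = rep(cells$cell_id, nt),
    response = as.vector(resp))
  responses <- responses[is.finite(responses$response), ]
  stim_dataset(cells = cells, ensembles = sim$ensembles,
               targets = sim$targets, trials = tr, responses = responses)
}
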