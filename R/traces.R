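#' Baseline-normalized fluorescence (dF/F)
#'
#' Neuropil-subtracts the raw trace (`F = F_cell - c * F_neuropil`),
#' estimates the slowly drifting baseline `F0` as a moving average of the
#' rolling 10th percentile of a window (default 1,000 frames, ~3 min at
#' 6 Hz), and returns `(F - F0) / F0`.
#'
#' @param f_cell,f_neuropil Raw fluorescence traces (equal length).
#' @param c Neuropil coefficient in `[0, 1]` (default 0.7).
#' @param window Baseline window in frames (default 1000). Centered, with
#'   truncated windows at the trace edges.
#' @param stride Evaluate the rolling percentile every `stride` frames and
#'   interpolate linearly in between (`1` = exact at every frame). A stride
#'   much smaller than `window` changes the slowly varying baseline
#'   negligibly while cutting cost proportionally.
#' @param percentile Baseline percentile (default 0.10).
#' @param f0_smooth Frames of running-mean smoothing applied to the trace
#'   *before* the rolling percentile (default 5; 1 = none). Without it the
#'   percentile of a noisy trace tracks the noise floor rather than the
#'   baseline, biasing every dF/F amplitude upward; smoothing over a few
#'   frames suppresses that bias while leaving the slow baseline intact
#'   (the same reason source-extraction pipelines low-pass before their
#'   rolling baselines). dF/F itself is always computed from the raw trace.
#' @return Numeric dF/F trace with attributes `f0` (the baseline) and
#'   `valid` (`FALSE` when the baseline is not strictly positive somewhere,
#'   in which case dF/F is `NA` — flagged, never silently clipped).
#' @export
dff <- function(f_cell, f_neuropil, c = 0.7, window = 1000, stride = 1,
                percentile = 0.10, f0_smooth = 5) {
  if (length(f_cell) != length(f_neuropil)) {
    stop("f_cell and f_neuropil must have equal length")
  }
  if (c < 0 || c > 1) stop("neuropil coefficient must lie in [0, 1]")
  f <- f_cell - c * f_neuropil
  f_base <- if (f0_smooth > 1) running_mean(f, f0_smooth) else f
  f0 <- rolling_percentile(f_base, window, percentile, stride)
  f0 <- running_mean(f0, window)
  valid <- all(f0 > 0)
  out <- if (valid) (f - f0) / f0 else rep(NA_real_, length(f))
  attr(out, "f0") <- f0
  attr(out, "valid") <- valid
  out
}

# Centered rolling percentile with truncated edge windows; optional stride
# with linear interpolation between evaluation points.
rolling_percentile <- function(x, window, percentile, stride = 1) {
  n <- length(x)
  half <- floor(window / 2)
  eval_at <- if (stride <= 1) seq_len(n) else unique(c(seq(1, n, by = stride), n))
  vals <- vapply(eval_at, function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    stats::quantile(x[lo:hi], probs = percentile, names = FALSE, type = 7)
  }, numeric(1))
  if (stride <= 1) vals else stats::approx(eval_at, vals, xout = seq_len(n))$y
}

# Centered running mean with truncated edge windows (cumsum based).
running_mean <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
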