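#' Classify photostimulation modulation of nontarget cells
#'
#' For each cell, bootstraps the mean across-trial response (percentile CI,
#' default 99%) and classifies the cell as `activated` or `suppressed` only
#' if the CI excludes zero *and* the cell survives false-discovery-rate
#' control (Benjamini-Hochberg step-up, default 1%) applied to bootstrap
#' two-sided p-values across all cells. Cells with fewer than `min_trials`
#' responses are returned as `neither` with `insufficient = TRUE`.
#'
#' @param responses A list of per-trial response vectors (one element per
#'   cell) or a cells-by-trials matrix.
#' @param ci Confidence level of the bootstrap CI (default 0.99).
#' @param fdr FDR level for the step-up procedure (default 0.01).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param min_trials Minimum trials per cell (default 10).
#' @param seed Seed for the bootstrap resampling (local RNG stream).
#' @return Data frame: `mean`, `ci_lo`, `ci_hi`, `p`, `p_adj`, `label`
#'   (factor `activated` / `suppressed` / `neither`), `insufficient`.
#' @export
modulation_significance <- function(responses, ci = 0.99, fdr = 0.01,
                                    n_boot = 2000, min_trials = 10,
                                    seed = 1L) {
  if (is.matrix(responses)) {
    responses <- lapply(seq_len(nrow(responses)), function(i) {
      r <- responses[i, ]
      r[is.finite(r)]
    })
  }
  nc <- length(responses)
  alpha <- 1 - ci
  out <- data.frame(mean = rep(NA_real_, nc), ci_lo = NA_real_,
                    ci_hi = NA_real_, p = NA_real_, p_adj = NA_real_,
                    label = factor(rep("neither", nc),
                                   levels = c("activated", "suppressed", "neither")),
                    insufficient = FALSE)
  with_local_seed(seed, {
    for (i in seq_len(nc)) {
      x <- responses[[i]]
      n <- length(x)
      out$mean[i] <- if (n > 0) mean(x) else NA_real_
      if (n < min_trials) {
        out$insufficient[i] <- TRUE
        next
      }
      bm <- colMeans(matrix(x[sample.int(n, n * n_boot, replace = TRUE)], n))
      qs <- stats::quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      out$ci_lo[i] <- qs[1]
      out$ci_hi[i] <- qs[2]
      # two-sided bootstrap p with the +1 continuity correction
      p_lo <- (sum(bm <= 0) + 1) / (n_boot + 1)
      p_hi <- (sum(bm >= 0) + 1) / (n_boot + 1)
      out$p[i] <- min(1, 2 * min(p_lo, p_hi))
    }
  })
  tested <- !out$insufficient
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  sig <- tested & !is.na(out$p_adj) & out$p_adj <= fdr
  act <- sig & out$ci_lo > 0
  sup <- sig & out$ci_hi < 0
  out$label[act] <- "activated"
  out$label[sup] <- "suppressed"
  out
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
  invisible(NULL)
}
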