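#' Specification for discrete ensemble design
#'
#' Describes what the optimizer should produce: how many ensembles of what
#' size, the desired windows for spread and selectivity, the hard
#' within-ensemble spacing constraint, and the relative weights of the soft
#' criteria.
#'
#' The soft criteria mirror the experimental design goals: (1) ensembles
#' maximally distinct from each other (pairwise membership overlap), (2)
#' minimal reuse of individual cells, (3) prefer cells stimulable at low
#' power, (4) prefer visually responsive cells, (6) spread cells out within
#' an ensemble, (7)-(9) hit the requested spread, ensemble-OSI and mean-OSI
#' windows. Criterion (5) - no two members within `min_within_pair` um - is
#' a hard constraint.
#'
#' @param n_ensembles Number of ensembles to design.
#' @param ensemble_size Targets per ensemble (default 10, minimum 3).
#' @param spread_window Length-2 window for the 3D spread, um (`NULL` = no
#'   preference).
#' @param ensemble_osi_window Length-2 window for the ensemble OSI.
#' @param mean_osi_window Length-2 window for the mean member OSI.
#' @param min_within_pair Hard minimum pairwise 3D distance within an
#'   ensemble, um (default 30).
#' @param weights Named numeric weights for the soft cost terms:
#'   `spread`, `ensemble_osi`, `mean_osi`, `overlap`, `reuse`, `power`,
#'   `visual`, `spacing`.
#' @param n_restarts Random restarts (default 8).
#' @param max_iter Swap iterations per restart (default 1500).
#' @param stall_iter Stop a restart after this many consecutive rejected
#'   swaps (default 300). The best restart is then polished by a
#'   deterministic full coordinate-descent sweep.
#' @param seed Mandatory RNG seed for reproducible designs.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_ensembles = 5, ensemble_size = 10,
                          spread_window = NULL,
                          ensemble_osi_window = NULL,
                          mean_osi_window = NULL,
                          min_within_pair = 30,
                          weights = c(spread = 1, ensemble_osi = 1,
                                      mean_osi = 1, overlap = 1, reuse = 0.5,
                                      power = 0.25, visual = 0.25,
                                      spacing = 0.25),
                          n_restarts = 8, max_iter = 1500, stall_iter = 300,
                          seed = 1L) {
  if (ensemble_size < 3) stop("ensembles must contain at least 3 targets")
  chk_win <- function(w, nm) {
    if (!is.null(w) && (length(w) != 2 || w[1] > w[2])) {
      stop(nm, " window must be an ordered length-2 range")
    }
  }
  chk_win(spread_window, "spread")
  chk_win(ensemble_osi_window, "ensemble_osi")
  chk_win(mean_osi_window, "mean_osi")
  if (any(weights < 0)) stop("cost weights must be non-negative")
  structure(list(n_ensembles = n_ensembles, ensemble_size = ensemble_size,
                 spread_window = spread_window,
                 ensemble_osi_window = ensemble_osi_window,
                 mean_osi_window = mean_osi_window,
                 min_within_pair = min_within_pair, weights = weights,
                 n_restarts = n_restarts, max_iter = max_iter,
                 stall_iter = stall_iter, seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Window deviation: zero inside the requested window, squared distance to
# the nearer edge (in units of the window half-width) outside. The hinge
# makes "inside the window" a bona fide optimum instead of trading off
# against the preference terms.
window_dev <- function(value, window) {
  if (is.null(window)) return(0)
  half <- max((window[2] - window[1]) / 2, 1e-6)
  over <- max(0, window[1] - value, value - window[2])
  (over / half)^2
}

#' Design stimulation ensembles with a swap-based discrete optimizer
#'
#' Selects `n_ensembles` disjoint-ish groups of targets from a candidate
#' pool by random-restart greedy single-cell swaps: starting from a random
#' feasible assignment, each step proposes replacing one member with an
#' unused candidate and accepts the move only if it lowers the total
#' weighted cost (so the accepted-cost sequence is monotone
#' non-increasing). The hard constraint - no two members of one ensemble
#' within `min_within_pair` um in 3D - is enforced at initialization and on
#' every proposal. Deterministic given `spec$seed`.
#'
#' @param cells Candidate pool: data frame with columns `cell_id`, `x`,
#'   `y`, `z`, `osi`, `power`, `visually_responsive`, and tuning-curve
#'   columns `tc_1 .. tc_8` (directions 0-315).
#' @param spec An [ensemble_spec()].
#' @return List of ensembles; each is a list with `target_ids`,
#'   `target_xyz`, `spread`, `ensemble_osi`, `mean_osi`, `ensemble_po`,
#'   `spatial_class`, `tuning_class`. The total cost and the accepted cost
#'   trace of the winning restart are attached as attributes `cost` and
#'   `cost_trace`.
#' @export
optimize_ensembles <- function(cells, spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- nrow(cells)
  k <- spec$ensemble_size
  m <- spec$n_ensembles
  if (n < k) stop("candidate pool smaller than one ensemble")
  xyz <- as.matrix(cells[, c("x", "y", "z")])
  tc <- tuning_matrix(cells)
  pw <- cells$power
  pw_norm <- if (diff(range(pw)) > 0) (pw - min(pw)) / diff(range(pw)) else rep(0, n)
  vis <- as.logical(cells$visually_responsive)
  W <- spec$weights
  # precompute folded orientation curves and member OSIs once; the swap loop
  # then only averages rows
  dirs <- seq(0, 315, by = 45)
  orients <- c(0, 45, 90, 135)
  foldm <- vapply(orients, function(o) {
    rowMeans(tc[, dirs %% 180 == o, drop = FALSE])
  }, numeric(n))
  osi_v <- apply(foldm, 1, function(f) osi_from_folded(f, orients)$osi)
  ortho_idx <- match((orients + 90) %% 180, orients)

  feasible <- function(idx) {
    d <- stats::dist(xyz[idx, , drop = FALSE])
    all(d >= spec$min_within_pair)
  }
  feasible_with <- function(idx, cand) {
    dd <- sqrt(colSums((t(xyz[idx, , drop = FALSE]) - xyz[cand, ])^2))
    all(dd >= spec$min_within_pair)
  }
  ens_cost <- function(idx) {
    d <- as.numeric(stats::dist(xyz[idx, , drop = FALSE]))
    spread <- mean(d)
    mf <- pmax(colMeans(foldm[idx, , drop = FALSE]), 0)
    ipo <- which.max(mf)
    denom <- mf[ipo] + mf[ortho_idx[ipo]]
    eosi <- if (denom > 0) (mf[ipo] - mf[ortho_idx[ipo]]) / denom else 0
    W[["spread"]] * window_dev(spread, spec$spread_window) +
      W[["ensemble_osi"]] * window_dev(eosi, spec$ensemble_osi_window) +
      W[["mean_osi"]] * window_dev(mean(osi_v[idx]), spec$mean_osi_window) +
      W[["power"]] * mean(pw_norm[idx]) +
      W[["visual"]] * mean(!vis[idx]) +
      W[["spacing"]] * mean(pmax(0, 1 - d / 60)^2)
  }
  overlap_cost <- function(a, b) {
    W[["overlap"]] * length(intersect(a, b)) / length(union(a, b))
  }
  reuse_cost <- function(counts) {
    W[["reuse"]] * sum(pmax(0, counts - 1)^2)
  }

  init_assignment <- function() {
    lapply(seq_len(m), function(e) {
      for (try in 1:200) {
        idx <- sample.int(n, k)
        if (feasible(idx)) return(idx)
      }
      # greedy fallback: grow a feasible set cell by cell
      ordc <- sample.int(n)
      idx <- ordc[1]
      for (c2 in ordc[-1]) {
        if (length(idx) == k) break
        if (feasible_with(idx, c2)) idx <- c(idx, c2)
      }
      if (length(idx) < k) {
        stop("infeasible hard constraint: cannot place ", k,
             " cells >= ", spec$min_within_pair, " um apart")
      }
      idx
    })
  }

  run_restart <- function() {
    ensembles <- init_assignment()
    per_cost <- vapply(ensembles, ens_cost, numeric(1))
    ov <- matrix(0, m, m)
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        ov[i, j] <- overlap_cost(ensembles[[i]], ensembles[[j]])
      }
    }
    counts <- tabulate(unlist(ensembles), nbins = n)
    total <- sum(per_cost) + sum(ov) + reuse_cost(counts)
    trace <- total
    stall <- 0
    eval_swap <- function(e, pos, cand) {
      idx <- ensembles[[e]]
      if (cand %in% idx) return(NULL)
      new_idx <- idx
      new_idx[pos] <- cand
      if (!feasible(new_idx)) return(NULL)
      new_pc <- ens_cost(new_idx)
      new_ov <- ov
      if (m > 1) {
        for (j in seq_len(m)[-e]) {
          v <- overlap_cost(new_idx, ensembles[[j]])
          if (j < e) new_ov[j, e] <- v else new_ov[e, j] <- v
        }
      }
      new_counts <- counts
      new_counts[idx[pos]] <- new_counts[idx[pos]] - 1
      new_counts[cand] <- new_counts[cand] + 1
      total_new <- total - per_cost[e] + new_pc - sum(ov) + sum(new_ov) -
        reuse_cost(counts) + reuse_cost(new_counts)
      list(idx = new_idx, pc = new_pc, ov = new_ov, counts = new_counts,
           total = total_new)
    }
    for (it in seq_len(spec$max_iter)) {
      e <- sample.int(m, 1)
      pos <- sample.int(k, 1)
      # best-of-several candidate replacements for the chosen slot
      cands <- sample.int(n, min(n, 8))
      props <- lapply(cands, function(cand) eval_swap(e, pos, cand))
      best_p <- NULL
      for (p in props) {
        if (!is.null(p) && (is.null(best_p) || p$total < best_p$total)) best_p <- p
      }
      if (!is.null(best_p) && best_p$total < total - 1e-12) {
        ensembles[[e]] <- best_p$idx
        per_cost[e] <- best_p$pc
        ov <- best_p$ov
        counts <- best_p$counts
        total <- best_p$total
        trace <- c(trace, total)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= spec$stall_iter) break
      }
    }
    list(ensembles = ensembles, cost = total, trace = trace)
  }

  # deterministic coordinate-descent polish: for every slot, try every
  # candidate, keep the best; repeat until a full sweep makes no improvement
  polish <- function(state) {
    ensembles <- state$ensembles
    per_cost <- vapply(ensembles, ens_cost, numeric(1))
    ov <- matrix(0, m, m)
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        ov[i, j] <- overlap_cost(ensembles[[i]], ensembles[[j]])
      }
    }
    counts <- tabulate(unlist(ensembles), nbins = n)
    total <- sum(per_cost) + sum(ov) + reuse_cost(counts)
    trace <- state$trace
    repeat {
      improved <- FALSE
      for (e in seq_len(m)) {
        for (pos in seq_len(k)) {
          idx <- ensembles[[e]]
          cur_other <- total - per_cost[e]
          best_sw <- NULL
          for (cand in seq_len(n)) {
            if (cand %in% idx) next
            new_idx <- idx
            new_idx[pos] <- cand
            if (!feasible(new_idx)) next
            new_pc <- ens_cost(new_idx)
            new_ov <- ov
            if (m > 1) {
              for (j in seq_len(m)[-e]) {
                v <- overlap_cost(new_idx, ensembles[[j]])
                if (j < e) new_ov[j, e] <- v else new_ov[e, j] <- v
              }
            }
            new_counts <- counts
            new_counts[idx[pos]] <- new_counts[idx[pos]] - 1
            new_counts[cand] <- new_counts[cand] + 1
            tn <- total - per_cost[e] + new_pc - sum(ov) + sum(new_ov) -
              reuse_cost(counts) + reuse_cost(new_counts)
            if (tn < total - 1e-12 &&
                (is.null(best_sw) || tn < best_sw$total)) {
              best_sw <- list(idx = new_idx, pc = new_pc, ov = new_ov,
                              counts = new_counts, total = tn)
            }
          }
          if (!is.null(best_sw)) {
            ensembles[[e]] <- best_sw$idx
            per_cost[e] <- best_sw$pc
            ov <- best_sw$ov
            counts <- best_sw$counts
            total <- best_sw$total
            trace <- c(trace, total)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    list(ensembles = ensembles, cost = total, trace = trace)
  }

  best <- NULL
  with_local_seed(spec$seed, {
    runs <- lapply(seq_len(spec$n_restarts), function(r) run_restart())
    costs <- vapply(runs, `[[`, numeric(1), "cost")
    # polish the few best restarts to their local optima, keep the winner
    for (r in utils::head(order(costs), 3)) {
      res <- polish(runs[[r]])
      if (is.null(best) || res$cost < best$cost) best <- res
    }
  })

  out <- lapply(seq_along(best$ensembles), function(e) {
    idx <- sort(best$ensembles[[e]])      # id-order tie-stable output
    spread <- mean_pairwise_spread(xyz[idx, , drop = FALSE])
    eo <- ensemble_osi(tc[idx, , drop = FALSE])
    cls <- classify_ensemble(spread, eo$ensemble_osi, eo$mean_osi)
    list(target_ids = cells$cell_id[idx],
         target_xyz = xyz[idx, , drop = FALSE],
         spread = spread,
         ensemble_osi = eo$ensemble_osi,
         mean_osi = eo$mean_osi,
         ensemble_po = eo$ensemble_po,
         spatial_class = cls$spatial_class,
         tuning_class = cls$tuning_class)
  })
  attr(out, "cost") <- best$cost
  attr(out, "cost_trace") <- best$trace
  out
}

#' Extract the tuning-curve matrix from a cell table
#'
#' @param cells Data frame with columns `tc_1 .. tc_8` (mean response per
#'   direction, directions `0, 45, ..., 315`).
#' @return Cells-by-8 numeric matrix.
#' @export
tuning_matrix <- function(cells) {
  cols <- paste0("tc_", 1:8)
  if (!all(cols %in% names(cells))) {
    stop("cell table lacks tuning-curve columns tc_1..tc_8")
  }
  as.matrix(cells[, cols])
}
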