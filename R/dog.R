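#' Evaluate the center-surround (sum-of-two-Gaussians) spatial response
#'
#' `f(d) = A1 exp(-(d/sigma1)^2) + A2 exp(-(d/sigma2)^2)`. With `A1 > 0`,
#' `A2 < 0` and `sigma2 > sigma1` this describes nearby activation with
#' surround suppression. Note the convention: no factor 1/2 in the exponent
#' (unlike the connectivity kernel [spatial_kernel()], which uses the
#' standard Gaussian-density convention); both conventions are kept as is
#' and documented in the methods vignette.
#'
#' @param d Distance(s), um.
#' @param A1,sigma1 Amplitude and scale of the narrow component.
#' @param A2,sigma2 Amplitude and scale of the broad component.
#' @return `f(d)`.
#' @export
dog_profile <- function(d, A1, sigma1, A2, sigma2) {
  A1 * exp(-(d / sigma1)^2) + A2 * exp(-(d / sigma2)^2)
}

#' Reference center-surround fit of the pooled distance-response data
#'
#' The published fit of pooled nontargeted-cell responses versus minimal
#' distance to the stimulated ensemble (15 um bins):
#' `A1 = 0.196`, `sigma1 = 22.1` um, `A2 = -0.021`, `sigma2 = 147.3` um.
#' Used as a reference fixture for worked examples and for centering the
#' experimentally observed regime box.
#'
#' @return A `dog_fit` object with the reference parameters.
#' @export
reference_dog_fit <- function() {
  new_dog_fit(A1 = 0.196, sigma1 = 22.1, A2 = -0.021, sigma2 = 147.3)
}

new_dog_fit <- function(A1, sigma1, A2, sigma2, rss = NA_real_,
                        n = NA_integer_) {
  structure(list(A1 = A1, sigma1 = sigma1, A2 = A2, sigma2 = sigma2,
                 rss = rss, n = n),
            class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat(sprintf("<dog_fit> A1=%.4g sigma1=%.4g um, A2=%.4g sigma2=%.4g um\n",
              x$A1, x$sigma1, x$A2, x$sigma2))
  s <- dog_summary(x)
  cat(sprintf("  zero crossing %s um, activation/suppression ratio %s\n",
              if (is.na(s$zero_crossing)) "none" else sprintf("%.1f", s$zero_crossing),
              if (is.na(s$act_supp_ratio)) "none" else sprintf("%.2f", s$act_supp_ratio)))
  invisible(x)
}

#' Fit the center-surround profile to distance-response data
#'
#' Least-squares fit of [dog_profile()] to `(distance, response)` pairs or
#' to a binned [distance_response_curve()]. Because the model is linear in
#' the amplitudes given the scales, fitting uses variable projection over a
#' grid of `(sigma1, sigma2)` starts (amplitudes solved by linear least
#' squares), followed by full Levenberg-Marquardt refinement
#' (`minpack.lm::nlsLM`) from the best start. This makes the fit robust to
#' the local minima that plague naive 4-parameter starts.
#'
#' @param distance Distances in um, or a `distance_curve` object (in which
#'   case bin centers and means are used and `response` is ignored).
#' @param response Responses at `distance`.
#' @param sigma1_grid,sigma2_grid Candidate scale starts, um.
#' @param fix_A2_zero If `TRUE`, fit a single Gaussian (`A2 = 0`).
#' @return A `dog_fit` object (components sorted so `sigma1 <= sigma2`).
#' @export
fit_dog <- function(distance, response = NULL,
                    sigma1_grid = c(10, 15, 20, 30, 45, 60),
                    sigma2_grid = c(80, 110, 150, 200, 300),
                    fix_A2_zero = FALSE) {
  if (inherits(distance, "distance_curve")) {
    keep <- !is.na(distance$mean)
    response <- distance$mean[keep]
    distance <- distance$bin_center[keep]
  }
  ok <- is.finite(distance) & is.finite(response)
  d <- distance[ok]
  y <- response[ok]
  if (length(d) < (if (fix_A2_zero) 3 else 6)) {
    stop("too few points for a center-surround fit")
  }
  if (fix_A2_zero) {
    best <- NULL
    for (s1 in sigma1_grid) {
      X <- cbind(exp(-(d / s1)^2))
      co <- stats::lm.fit(X, y)$coefficients
      rss <- sum((y - X %*% co)^2)
      if (is.null(best) || rss < best$rss) best <- list(s1 = s1, A1 = unname(co[1]), rss = rss)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-(d / s1)^2),
                        start = list(A1 = best$A1, s1 = best$s1),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(new_dog_fit(best$A1, best$s1, 0, best$s1, best$rss, length(d)))
    }
    co <- stats::coef(fit)
    return(new_dog_fit(co[["A1"]], abs(co[["s1"]]), 0, abs(co[["s1"]]),
                       sum(stats::resid(fit)^2), length(d)))
  }
  best <- NULL
  for (s1 in sigma1_grid) {
    for (s2 in sigma2_grid) {
      if (s2 <= s1) next
      X <- cbind(exp(-(d / s1)^2), exp(-(d / s2)^2))
      co <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
      if (is.null(co) || anyNA(co)) next
      rss <- sum((y - X %*% co)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(s1 = s1, s2 = s2, A1 = unname(co[1]), A2 = unname(co[2]), rss = rss)
      }
    }
  }
  if (is.null(best)) stop("center-surround fit failed: no valid start found")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-(d / s1)^2) + A2 * exp(-(d / s2)^2),
      start = list(A1 = best$A1, s1 = best$s1, A2 = best$A2, s2 = best$s2),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- new_dog_fit(best$A1, best$s1, best$A2, best$s2, best$rss, length(d))
  } else {
    co <- stats::coef(fit)
    out <- new_dog_fit(co[["A1"]], abs(co[["s1"]]), co[["A2"]], abs(co[["s2"]]),
                       sum(stats::resid(fit)^2), length(d))
  }
  if (out$sigma1 > out$sigma2) {
    out <- new_dog_fit(out$A2, out$sigma2, out$A1, out$sigma1, out$rss, out$n)
  }
  out
}

#' Zero crossing and activation/suppression ratio of a center-surround fit
#'
#' The zero crossing is the positive distance where activation hands over
#' to suppression, available in closed form when `A1 > 0 > A2` and
#' `sigma2 > sigma1`:
#' \deqn{d^* = \sqrt{\ln(A_1/|A_2|) / (1/\sigma_1^2 - 1/\sigma_2^2)}.}
#' The ratio is `max f / |min f|` over `d >= 0` (located numerically on a
#' fine grid with local refinement).
#'
#' @param fit A `dog_fit` (from [fit_dog()] or [reference_dog_fit()]).
#' @param d_max Upper end of the search range for the extrema, um.
#' @return List with `zero_crossing` (um, `NA` if the components do not
#'   change sign) and `act_supp_ratio` (`NA` if there is no suppression).
#' @export
dog_summary <- function(fit, d_max = 1000) {
  stopifnot(inherits(fit, "dog_fit"))
  zc <- NA_real_
  if (fit$A1 * fit$A2 < 0) {
    a_n <- if (fit$A1 > 0) fit$A1 else fit$A2      # positive amplitude
    a_p <- if (fit$A1 > 0) fit$A2 else fit$A1
    s_n <- if (fit$A1 > 0) fit$sigma1 else fit$sigma2
    s_p <- if (fit$A1 > 0) fit$sigma2 else fit$sigma1
    denom <- 1 / s_n^2 - 1 / s_p^2
    num <- log(a_n / abs(a_p))
    if (denom != 0 && num / denom >= 0) zc <- sqrt(num / denom)
  }
  f <- function(d) dog_profile(d, fit$A1, fit$sigma1, fit$A2, fit$sigma2)
  grid <- seq(0, d_max, by = 0.5)
  v <- f(grid)
  refine <- function(d0, maximize) {
    lo <- max(0, d0 - 1); hi <- min(d_max, d0 + 1)
    stats::optimize(f, c(lo, hi), maximum = maximize)
  }
  imax <- which.max(v)
  opt_max <- refine(grid[imax], TRUE)
  fmax <- max(v[imax], opt_max$objective)
  imin <- which.min(v)
  opt_min <- refine(grid[imin], FALSE)
  fmin <- min(v[imin], opt_min$objective)
  ratio <- if (fmin < 0) fmax / abs(fmin) else NA_real_
  list(zero_crossing = zc, act_supp_ratio = ratio)
}

#' Regime box spanned by center-surround summaries across bin widths
#'
#' Mirrors the procedure that defines the experimentally observed regime:
#' bin the raw `(distance, response)` pairs at each candidate bin width, fit
#' the center-surround profile to each binned curve, summarize each fit by
#' its zero crossing and activation/suppression ratio, and take the
#' smallest rectangle containing all summaries.
#'
#' @param distance,response Raw per-(cell, ensemble) pairs.
#' @param bin_widths Bin widths in um (default 5 to 20).
#' @return A `regime_box` list: `crossing_min`, `crossing_max`, `ratio_min`,
#'   `ratio_max`, plus the per-width summary table (`per_width`). Widths
#'   whose fit fails or yields no crossing are flagged in the table and
#'   skipped (with a warning) when forming the box.
#' @export
data_regime_box <- function(distance, response, bin_widths = 5:20) {
  rows <- lapply(bin_widths, function(w) {
    res <- tryCatch({
      curve <- bin_distance_response(distance, response, w)
      fit <- fit_dog(curve)
      s <- dog_summary(fit)
      data.frame(bin_width = w, zero_crossing = s$zero_crossing,
                 act_supp_ratio = s$act_supp_ratio, ok = TRUE)
    }, error = function(e) {
      data.frame(bin_width = w, zero_crossing = NA_real_,
                 act_supp_ratio = NA_real_, ok = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  good <- tab$ok & is.finite(tab$zero_crossing) & is.finite(tab$act_supp_ratio)
  if (!all(good)) {
    warning(sum(!good), " bin width(s) excluded from the regime box")
  }
  if (!any(good)) stop("no bin width produced a usable fit")
  structure(list(
    crossing_min = min(tab$zero_crossing[good]),
    crossing_max = max(tab$zero_crossing[good]),
    ratio_min = min(tab$act_supp_ratio[good]),
    ratio_max = max(tab$act_supp_ratio[good]),
    per_width = tab
  ), class = "regime_box")
}

#' Construct a regime box directly
#'
#' @param crossing Range (length-2) of zero crossings, um.
#' @param ratio Range (length-2) of activation/suppression ratios.
#' @return A `regime_box`.
#' @export
regime_box <- function(crossing, ratio) {
  stopifnot(length(crossing) == 2, length(ratio) == 2,
            crossing[1] <= crossing[2], ratio[1] <= ratio[2])
  structure(list(crossing_min = crossing[1], crossing_max = crossing[2],
                 ratio_min = ratio[1], ratio_max = ratio[2],
                 per_width = NULL),
            class = "regime_box")
}

#' Does a (crossing, ratio) point fall inside a regime box?
#'
#' @param box A `regime_box`.
#' @param zero_crossing,act_supp_ratio Point coordinates (`NA` never falls
#'   inside).
#' @return Logical.
#' @export
in_regime_box <- function(box, zero_crossing, act_supp_ratio) {
  stopifnot(inherits(box, "regime_box"))
  !is.na(zero_crossing) & !is.na(act_supp_ratio) &
    zero_crossing >= box$crossing_min & zero_crossing <= box$crossing_max &
    act_supp_ratio >= box$ratio_min & act_supp_ratio <= box$ratio_max
}

#' @export
print.regime_box <- function(x, ...) {
  cat(sprintf("<regime_box> crossing [%.1f, %.1f] um, ratio [%.2f, %.2f]\n",
              x$crossing_min, x$crossing_max, x$ratio_min, x$ratio_max))
  invisible(x)
}
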