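test_that("dff handles constant traces, plateaus and gain rescaling", {
  n <- 200
  # constant trace: F = 100 - 0.7 * 50 = 65, so dF/F is identically 0
  d0 <- dff(rep(100, n), rep(50, n), c = 0.7, window = 50)
  expect_true(attr(d0, "valid"))
  expect_equal(max(abs(d0)), 0, tolerance = 1e-12)
  expect_equal(unname(attr(d0, "f0")[1]), 65)
  # a short plateau at twice baseline reads out as dF/F = 1
  f <- rep(100, n); f[100:104] <- 230 - 0.7 * 50 * 0 + 130 - 100  # -> F 165
  f <- rep(100, n); f[100:104] <- 100 + 65                         # F: 65 -> 130
  d1 <- dff(f, rep(50, n), c = 0.7, window = 101)
  expect_equal(unname(d1[102]), 1, tolerance = 0.05)
  # gain invariance: scaling both channels by k leaves dF/F unchanged
  d2 <- dff(3 * f, 3 * rep(50, n), c = 0.7, window = 101)
  expect_equal(as.numeric(d2), as.numeric(d1), tolerance = 1e-12)
  # non-positive baseline flags the cell instead of clipping
  bad <- dff(rep(10, n), rep(50, n), c = 0.7, window = 50)
  expect_false(attr(bad, "valid"))
  expect_true(all(is.na(bad)))
})

test_that("rolling percentile matches a brute-force oracle on a sawtooth", {
  x <- rep(seq(1, 40), 5) + sin(seq_len(200) / 7)
  w <- 31
  brute <- sapply(seq_along(x), function(i) {
    lo <- max(1, i - 15); hi <- min(length(x), i + 15)
    quantile(x[lo:hi], 0.1, names = FALSE)
  })
  expect_equal(holofield:::rolling_percentile(x, w, 0.1, stride = 1), brute)
  # strided evaluation is exact at its evaluation points and interpolates
  # in between, so its error is bounded by stride times the local slope
  strided <- holofield:::rolling_percentile(x, w, 0.1, stride = 5)
  eval_at <- unique(c(seq(1, length(x), by = 5), length(x)))
  expect_equal(strided[eval_at], brute[eval_at], tolerance = 1e-12)
  expect_lt(max(abs(strided - brute)), 5 * max(abs(diff(brute))))
})

test_that("tuning summary folds directions and computes OSI", {
  # folded (1.0 pref, 0.5 ortho) gives OSI 1/3
  dirs <- rep(c(0, 45, 90, 135, 180, 225, 270, 315), each = 3)
  resp <- rep(c(1, 0.75, 0.5, 0.75, 1, 0.75, 0.5, 0.75), each = 3)
  t1 <- tuning_and_osi(resp, dirs)
  expect_equal(t1$osi, 1 / 3, tolerance = 1e-12)
  expect_equal(t1$po, 0)
  expect_equal(t1$oo, 90)
  # direction pair (0.8 at 0, 0.4 at 180) folds to 0.6 at orientation 0
  dirs2 <- rep(c(0, 90, 180, 270), each = 2)
  resp2 <- rep(c(0.8, 0.5, 0.4, 0.5), each = 2)
  t2 <- tuning_and_osi(resp2, dirs2)
  expect_equal(t2$folded[t2$orientations == 0], 0.6)
  # flat curve: OSI 0
  t3 <- tuning_and_osi(rep(1, 16), rep(c(0, 45, 90, 135), 4))
  expect_equal(t3$osi, 0)
  # all-negative folded responses rectify to zero -> OSI defined as 0
  t4 <- tuning_and_osi(rep(c(-1, -0.5), each = 4), rep(c(0, 90), each = 4))
  expect_equal(t4$osi, 0)
  # strong visual modulation vs blank yields a small ANOVA p
  set.seed(1)
  dirs5 <- c(rep(c(0, 45, 90, 135), each = 5), rep(NA, 5))
  resp5 <- c(rnorm(5, 1, 0.05), rnorm(15, 0.2, 0.05), rnorm(5, 0, 0.05))
  expect_lt(tuning_and_osi(resp5, dirs5)$p_visual, 0.001)
  expect_error(tuning_and_osi(1:3, c(0, 45, 90)), "2 trials")
})

test_that("minimal target distance uses 3D geometry with 30 um planes", {
  tg <- rbind(c(0, 0, 0), c(500, 500, 30))
  expect_equal(min_target_distance(c(0, 0, 0), tg), 0)
  expect_equal(min_target_distance(c(500, 500, 0), tg), 30)   # one plane away
  expect_equal(min_target_distance(c(30, 40, 0), rbind(c(0, 0, 0))), 50)
  expect_equal(min_target_distance(c(30, 40, 120), rbind(c(0, 0, 0)),
                                   method = "2d"), 50)
})

test_that("off-target mask follows the cylindrical exclusion zone", {
  targets <- data.frame(x = 100, y = 100, plane = 1)
  cells <- data.frame(cell_id = 1:5,
                      x = c(110, 120, 125, 135, 100),
                      y = 100, plane = c(1, 1, 2, 2, 3))
  m <- off_target_mask(cells, targets)
  expect_equal(m, c(TRUE,   # 10 um same plane (< 15)
                    FALSE,  # 20 um same plane (>= 15)
                    TRUE,   # 25 um adjacent plane (< 30)
                    FALSE,  # 35 um adjacent plane
                    FALSE)) # directly below but two planes away
  # target ids force exclusion
  m2 <- off_target_mask(cells, targets, target_ids = 4)
  expect_true(m2[4])
})

test_that("relative tuning labels snap to iso/oblique/ortho", {
  expect_equal(as.character(relative_tuning_split(c(0, 90, 135, 30), 0)),
               c("0", "90", "45", "45"))
  # direction-valued preferred orientations behave like their orientation
  expect_equal(relative_tuning_split(c(0, 90, 135) + 180, 0),
               relative_tuning_split(c(0, 90, 135), 0))
  # untuned filter overrides the geometric label
  lab <- relative_tuning_split(c(0, 0), 0, osi = c(0.5, 0.1),
                               p_visual = c(0.01, 0.01))
  expect_equal(as.character(lab), c("0", "untuned"))
})

test_that("center-surround fit recovers noiseless parameters", {
  d <- seq(2.5, 400, by = 5)
  y <- dog_profile(d, 0.2, 20, -0.02, 150)
  fit <- fit_dog(d, y)
  expect_equal(fit$A1, 0.2, tolerance = 0.01)
  expect_equal(fit$sigma1, 20, tolerance = 0.01)
  expect_equal(fit$A2, -0.02, tolerance = 0.01)
  expect_equal(fit$sigma2, 150, tolerance = 0.01)
  # single-Gaussian restriction
  g <- 0.3 * exp(-(d / 35)^2)
  fg <- fit_dog(d, g, fix_A2_zero = TRUE)
  expect_equal(fg$A1, 0.3, tolerance = 1e-4)
  expect_equal(fg$sigma1, 35, tolerance = 1e-3)
  expect_equal(fg$A2, 0)
})

test_that("summary of the reference fit: closed form, crossing, ratio", {
  fit <- reference_dog_fit()
  s <- dog_summary(fit)
  # closed form d* = sqrt(ln(A1/|A2|) / (1/s1^2 - 1/s2^2))
  d_star <- sqrt(log(0.196 / 0.021) / (1 / 22.1^2 - 1 / 147.3^2))
  expect_equal(s$zero_crossing, d_star, tolerance = 1e-12)
  expect_equal(d_star, 33.41, tolerance = 1e-3)
  # the closed form agrees with numeric root finding to 1e-9 um
  root <- uniroot(function(d) dog_profile(d, fit$A1, fit$sigma1, fit$A2,
                                          fit$sigma2),
                  c(5, 100), tol = 1e-12)$root
  expect_equal(s$zero_crossing, root, tolerance = 1e-9)
  # maximum activation sits at d = 0 and equals A1 + A2
  expect_equal(dog_profile(0, fit$A1, fit$sigma1, fit$A2, fit$sigma2),
               fit$A1 + fit$A2)
  # no surround component, no crossing
  s0 <- dog_summary(new_dog_fit <- fit_dog(seq(2.5, 200, 5),
                                           0.3 * exp(-(seq(2.5, 200, 5) / 35)^2),
                                           fix_A2_zero = TRUE))
  expect_true(is.na(s0$zero_crossing))
})

test_that("distance binning uses 15 um edges and keeps empty bins missing", {
  d <- c(2, 7, 20, 100)
  r <- c(1, 3, 5, -1)
  cv <- bin_distance_response(d, r, 15)
  expect_equal(cv$bin_lo[1:3], c(0, 15, 30))
  expect_equal(cv$mean[1], 2)      # two points in [0, 15)
  expect_equal(cv$mean[2], 5)
  expect_true(is.na(cv$mean[3]))   # empty bin recorded as missing
  expect_equal(cv$n[3], 0)
  expect_true(is.na(cv$sem[2]))    # single observation: sem missing
  expect_equal(cv$sem[1], sd(c(1, 3)) / sqrt(2))
})

test_that("regime box brackets per-width summaries", {
  set.seed(42)
  d <- runif(4000, 0, 450)
  y <- dog_profile(d, 0.2, 20, -0.02, 150) + rnorm(4000, 0, 0.02)
  box <- data_regime_box(d, y, bin_widths = c(5, 10, 15, 20))
  truth <- dog_summary(fit_dog(d, y))
  expect_true(in_regime_box(box, truth$zero_crossing, truth$act_supp_ratio) ||
                (box$crossing_max - box$crossing_min) < 10)
  # box center close to the generating profile's crossing
  true_cross <- dog_summary(reference_dog_fit())  # same functional family
  gen_cross <- sqrt(log(0.2 / 0.02) / (1 / 20^2 - 1 / 150^2))
  expect_lt(abs((box$crossing_min + box$crossing_max) / 2 - gen_cross), 8)
  # per-width points are inside by construction
  pw <- box$per_width
  ok <- pw$ok & is.finite(pw$zero_crossing)
  expect_true(all(pw$zero_crossing[ok] >= box$crossing_min - 1e-9 &
                    pw$zero_crossing[ok] <= box$crossing_max + 1e-9))
  # identical summaries at every width give a degenerate box
  d2 <- seq(1, 400, by = 1)
  y2 <- dog_profile(d2, 0.2, 20, -0.02, 150)
  box2 <- data_regime_box(d2, y2, bin_widths = c(5, 10))
  expect_lt(box2$crossing_max - box2$crossing_min, 1.5)
})

test_that("modulation significance classifies obvious cases", {
  zeros <- matrix(0, 3, 15)
  m0 <- modulation_significance(zeros, seed = 3)
  expect_true(all(m0$label == "neither"))
  set.seed(2)
  strong <- rbind(matrix(1 + rnorm(30, 0, 0.05), 2, 15),
                  matrix(-1 + rnorm(15, 0, 0.05), 1, 15),
                  matrix(rnorm(15, 0, 0.5), 1, 15))
  m1 <- modulation_significance(strong, seed = 3)
  expect_equal(as.character(m1$label), c("activated", "activated",
                                         "suppressed", "neither"))
  # too few trials: neither, flagged
  m2 <- modulation_significance(matrix(1, 1, 5), seed = 3)
  expect_true(m2$insufficient[1])
  expect_equal(as.character(m2$label), "neither")
})

test_that("PPSF fit returns the right widths", {
  off <- seq(-3, 30, by = 3)
  # exact Gaussian, sigma = 5 -> FWHM = 2 sqrt(2 ln 2) * 5
  p <- ppsf_fit(off, exp(-off^2 / (2 * 25)))
  expect_equal(p$fwhm, 2 * sqrt(2 * log(2)) * 5, tolerance = 1e-6)
  expect_equal(p$hwhm, p$fwhm / 2)
  # noisy recovery within 10% at SNR ~ 10
  set.seed(5)
  noisy <- exp(-(off - 2)^2 / (2 * 36)) + rnorm(length(off), 0, 0.1)
  pn <- ppsf_fit(off, noisy)
  expect_equal(pn$sigma, 6, tolerance = 0.1 * 6)
  expect_error(ppsf_fit(1:3, 1:3), "few")
})
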