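#' Two-scale spatial connection-probability kernel
#'
#' Mixture of a broad and a narrow isotropic 2D Gaussian, each normalized to
#' unit mass over the plane, weighted by `kappa`:
#' \deqn{g(r) = \frac{1-\kappa}{2\pi\sigma_b^2} e^{-r^2/(2\sigma_b^2)} +
#'              \frac{\kappa}{2\pi\sigma_n^2} e^{-r^2/(2\sigma_n^2)}.}
#' The broad scale captures the classical lateral extent of L2/3 recurrent
#' connections; the narrow scale concentrates extra weight on very nearby
#' partners (sub-50 um), which is what allows the model to amplify activity
#' immediately around a stimulated ensemble.
#'
#' @param r Distance(s) in um, `>= 0`.
#' @param sigma_broad Broad Gaussian scale in um, `> 0`.
#' @param sigma_narrow Narrow Gaussian scale in um, `> 0`. Ignored when
#'   `kappa = 0`.
#' @param kappa Weight of the narrow component, in `[0, 1]`.
#' @return Density value(s), per um^2. Integrates to 1 over the plane.
#' @examples
#' spatial_kernel(0, sigma_broad = 100, sigma_narrow = 10, kappa = 0)
#' @export
spatial_kernel <- function(r, sigma_broad, sigma_narrow = sigma_broad,
                           kappa = 0) {
  if (sigma_broad <= 0 || sigma_narrow <= 0) {
    stop("spatial kernel scales must be positive")
  }
  if (kappa < 0 || kappa > 1) stop("kappa must lie in [0, 1]")
  if (any(r < 0)) stop("distances must be non-negative")
  (1 - kappa) / (2 * pi * sigma_broad^2) * exp(-r^2 / (2 * sigma_broad^2)) +
    kappa / (2 * pi * sigma_narrow^2) * exp(-r^2 / (2 * sigma_narrow^2))
}

#' Feature (orientation) connection kernel parameters
#'
#' Like-to-like wiring in orientation space: a baseline weight `r0` plus a
#' Gaussian bump `rp * exp(-theta^2 / (2 sigma_theta^2))` over the folded
#' orientation difference `theta` in `[0, 90]` degrees.
#'
#' @param r0 Baseline (orientation-independent) weight, `>= 0`.
#' @param rp Peak tuned weight at zero orientation difference, `>= 0`.
#' @param sigma_theta Tuning width in degrees, `> 0`.
#' @return A `feature_params` list.
#' @seealso [feature_kernel()], [untuned_features()]
#' @export
feature_params <- function(r0, rp, sigma_theta = 30) {
  if (r0 < 0 || rp < 0) stop("feature kernel weights must be non-negative")
  if (sigma_theta <= 0) stop("sigma_theta must be positive")
  structure(list(r0 = r0, rp = rp, sigma_theta = sigma_theta),
            class = "feature_params")
}

#' Orientation-independent feature kernel (h = 1)
#'
#' @return `feature_params` with `r0 = 1`, `rp = 0`, the convention for
#'   models without feature-based connectivity.
#' @export
untuned_features <- function() feature_params(r0 = 1, rp = 0)

#' Evaluate the orientation connection kernel
#'
#' @param delta_theta Folded orientation difference(s) in degrees, in
#'   `[0, 90]`. Use [fold_orientation()] to fold raw differences.
#' @param params A [feature_params()] object.
#' @return Weight(s) `h(delta_theta) = r0 + rp * exp(-dt^2/(2 s^2))`.
#' @export
feature_kernel <- function(delta_theta, params) {
  stopifnot(inherits(params, "feature_params"))
  if (any(delta_theta < 0 | delta_theta > 90)) {
    stop("delta_theta must be folded into [0, 90] degrees")
  }
  params$r0 + params$rp * exp(-delta_theta^2 / (2 * params$sigma_theta^2))
}

#' Fold an orientation difference into [0, 90] degrees
#'
#' Orientations are circular with period 180 degrees; the relevant quantity
#' for like-to-like wiring and for iso/ortho analyses is the acute angle
#' between two orientations.
#'
#' @param delta Raw difference(s) in degrees (any real value).
#' @return Folded difference(s) in `[0, 90]`.
#' @export
fold_orientation <- function(delta) {
  d <- abs(delta) %% 180
  pmin(d, 180 - d)
}
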