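#' Configuration of the linearized neural-field model
#'
#' Defines the discretized periodic domain, the effective synaptic weights
#' and the space/feature kernel parameters of the two-population (E, I)
#' linear response model. Gains and time constants of the underlying
#' nonlinear field model are absorbed into the effective weights
#' (`W = g * j`), so only dimensionless pathway strengths appear here.
#'
#' The broad spatial scales and the excitatory feature rule follow published
#' connectivity measurements; the narrow-scale and inhibitory feature
#' parameters are free parameters of the model and the defaults below are
#' this package's reference choices (see the methods vignette).
#'
#' @param domain_size Side of the square periodic domain, um.
#' @param grid_spacing Node spacing, um. Must divide `domain_size`; a
#'   warning is emitted if it is too coarse to resolve `sigma_e_narrow`
#'   (spacing > sigma_e_narrow / 3).
#' @param n_orientations Number of discrete preferred-orientation levels on
#'   `[0, 180)` degrees (>= 2 when orientation matters; 1 is allowed for
#'   purely spatial models).
#' @param w_ee Effective monosynaptic E-to-E strength (total operator gain).
#' @param w_eie Effective disynaptic inhibitory strength, `w_ei * w_ie`
#'   (positive number; the pathway enters the response with a minus sign).
#' @param sigma_e_broad,sigma_i_broad Broad spatial scales of excitatory and
#'   inhibitory outgoing projections, um.
#' @param sigma_e_narrow,sigma_i_narrow Narrow spatial scales, um.
#' @param kappa_e,kappa_i Narrow-scale weights in `[0, 1]` for E- and
#'   I-outgoing projections. By default only recurrent excitation carries a
#'   narrow component (`kappa_i = 0`).
#' @param feature_ee,feature_ei,feature_ie [feature_params()] for the E-E,
#'   I-to-E and E-to-I orientation rules. Use [untuned_features()] for a
#'   purely spatial model.
#' @param stim_amplitude Added-rate mass delivered per photostimulation
#'   target (dimensionless rate units; default 10).
#' @param mode `"expansion"` (truncated pathway expansion
#'   `W + W*W`) or `"exact"` (full resolvent `(I - W)^-1 W` per Fourier
#'   mode).
#' @return A validated `model_config` object.
#' @export
model_config <- function(domain_size = 1400,
                         grid_spacing = 4,
                         n_orientations = 4,
                         w_ee = 0.45,
                         w_eie = 0.5,
                         sigma_e_broad = 110,
                         sigma_i_broad = 90,
                         sigma_e_narrow = 15,
                         sigma_i_narrow = 15,
                         kappa_e = 0.3,
                         kappa_i = 0,
                         feature_ee = feature_params(0.5, 0.5, 30),
                         feature_ei = feature_params(0.1, 0.9, 30),
                         feature_ie = feature_params(0.1, 0.9, 30),
                         stim_amplitude = 10,
                         mode = c("expansion", "exact")) {
  mode <- match.arg(mode)
  n_nodes <- domain_size / grid_spacing
  if (abs(n_nodes - round(n_nodes)) > 1e-9) {
    stop("grid_spacing must divide domain_size")
  }
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  for (s in c(sigma_e_broad, sigma_i_broad, sigma_e_narrow, sigma_i_narrow)) {
    if (s <= 0) stop("spatial scales must be positive")
  }
  for (k in c(kappa_e, kappa_i)) {
    if (k < 0 || k > 1) stop("kappa must lie in [0, 1]")
  }
  if (w_ee < 0 || w_eie < 0) stop("effective weights must be non-negative")
  stopifnot(inherits(feature_ee, "feature_params"),
            inherits(feature_ei, "feature_params"),
            inherits(feature_ie, "feature_params"))
  if (kappa_e > 0 && grid_spacing > sigma_e_narrow / 3) {
    warning("grid_spacing > sigma_e_narrow / 3: the narrow spatial scale ",
            "is under-resolved")
  }
  structure(list(
    domain_size = domain_size,
    grid_spacing = grid_spacing,
    n_nodes = as.integer(round(n_nodes)),
    n_orientations = as.integer(n_orientations),
    w_ee = w_ee,
    w_eie = w_eie,
    sigma_e_broad = sigma_e_broad,
    sigma_i_broad = sigma_i_broad,
    sigma_e_narrow = sigma_e_narrow,
    sigma_i_narrow = sigma_i_narrow,
    kappa_e = kappa_e,
    kappa_i = kappa_i,
    feature_ee = feature_ee,
    feature_ei = feature_ei,
    feature_ie = feature_ie,
    stim_amplitude = stim_amplitude,
    mode = mode
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  cat(sprintf("  domain %g um, spacing %g um (%d x %d nodes), %d orientations\n",
              x$domain_size, x$grid_spacing, x$n_nodes, x$n_nodes,
              x$n_orientations))
  cat(sprintf("  w_ee = %g, w_eie = %g, mode = %s\n", x$w_ee, x$w_eie, x$mode))
  cat(sprintf("  E kernel: sigma_b %g, sigma_n %g, kappa %g; I kernel: sigma_b %g, kappa %g\n",
              x$sigma_e_broad, x$sigma_e_narrow, x$kappa_e,
              x$sigma_i_broad, x$kappa_i))
  invisible(x)
}

#' Orientation levels of a model configuration
#'
#' @param config A [model_config()].
#' @return Numeric vector of preferred-orientation levels in degrees,
#'   evenly spaced on `[0, 180)`.
#' @export
orientation_levels <- function(config) {
  (seq_len(config$n_orientations) - 1) * 180 / config$n_orientations
}
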