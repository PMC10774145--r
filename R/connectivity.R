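#' Build the discretized connectivity operators
#'
#' Constructs the three translation-invariant operators of the linearized
#' two-population model: `W_ee` (recurrent excitation), `W_ie` (E-to-I) and
#' `W_ei` (I-to-E, carrying the negative sign of inhibition). Each operator
#' is separable in space and orientation,
#' `W(x1, t1; x2, t2) = w * g(r) * h(dtheta) / z`, with `g` the two-scale
#' spatial kernel ([spatial_kernel()]), `h` the orientation kernel
#' ([feature_kernel()]) and `z` the discrete normalization that makes the
#' kernel sum (over space weighted by cell area, and over orientation
#' levels) equal 1, so that `w` is the total operator gain.
#'
#' The individual inhibitory weights are not separately identifiable from
#' the disynaptic strength `w_eie = w_ei * w_ie`; they are split
#' symmetrically as `w_ie = sqrt(w_eie)`, `w_ei = -sqrt(w_eie)`.
#'
#' @param config A [model_config()].
#' @return A `connectivity_ops` object: list with elements `W_ee`, `W_ei`,
#'   `W_ie`, each containing the real-space kernel array (`kernel`, offset
#'   zero at index `[1, 1, 1]`), its Fourier transform scaled to operator
#'   gain (`spec`, so `spec[1,1,1] == w`), and the signed gain `w`.
#' @export
build_connectivity <- function(config) {
  w_ie <- sqrt(config$w_eie)
  w_ei <- -sqrt(config$w_eie)
  ops <- list(
    W_ee = build_operator(config$w_ee, config$sigma_e_broad,
                          config$sigma_e_narrow, config$kappa_e,
                          config$feature_ee, config),
    W_ei = build_operator(w_ei, config$sigma_i_broad,
                          config$sigma_i_narrow, config$kappa_i,
                          config$feature_ei, config),
    W_ie = build_operator(w_ie, config$sigma_e_broad,
                          config$sigma_e_narrow, config$kappa_e,
                          config$feature_ie, config)
  )
  structure(ops, class = "connectivity_ops", config = config)
}

# Discretize one separable operator kernel and cache its Fourier transform.
build_operator <- function(w, sigma_broad, sigma_narrow, kappa, feature,
                           config) {
  n <- config$n_nodes
  nt <- config$n_orientations
  sp <- config$grid_spacing
  idx <- 0:(n - 1)
  d1 <- sp * pmin(idx, n - idx)          # periodic offset distances
  r <- sqrt(outer(d1^2, d1^2, "+"))
  g <- spatial_kernel(r, sigma_broad, sigma_narrow, kappa)
  step <- 180 / nt
  dtheta <- fold_orientation((0:(nt - 1)) * step)
  h <- feature_kernel(dtheta, feature)
  kernel <- outer(g, h)                   # (n, n, nt)
  z <- sum(g) * sp^2 * sum(h)
  kernel <- w * kernel / z
  spec <- fft(kernel) * sp^2
  list(w = w, kernel = kernel, spec = spec)
}

#' @export
print.connectivity_ops <- function(x, ...) {
  cat("<connectivity_ops> gains:",
      sprintf("W_ee=%.3g W_ei=%.3g W_ie=%.3g",
              x$W_ee$w, x$W_ei$w, x$W_ie$w), "\n")
  invisible(x)
}

#' Apply a connectivity operator to a field (circular convolution)
#'
#' @param op One element of [build_connectivity()] output.
#' @param field A [field_state()].
#' @param config The matching [model_config()].
#' @return A [field_state()] with the convolved values.
#' @export
apply_operator <- function(op, field, config) {
  xhat <- fft(field$values)
  out <- Re(fft(op$spec * xhat, inverse = TRUE)) / length(xhat)
  field_state(out, config)
}
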