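#' Steady-state linear response to a stimulation field
#'
#' Solves the linearized field equations in Fourier space. In `"exact"` mode
#' the excitatory response per Fourier mode is obtained from the
#' two-population resolvent: writing `a`, `b`, `c` for the transforms of
#' `W_ee`, `W_ei`, `W_ie` at that mode, the stimulated-population response
#' is `dr_e = (a + b c) / (1 - a - b c) * r_stim`. In `"expansion"` mode the
#' resolvent is truncated at second order in the weights,
#' `dr_e = (a + a^2 + b c) * r_stim`, i.e. the sum of the monosynaptic E-E,
#' disynaptic E-E-E and disynaptic E-I-E pathways.
#'
#' @param ops [build_connectivity()] output.
#' @param r_stim A [field_state()], typically from [stim_field()].
#' @param config The matching [model_config()]. `config$mode` selects the
#'   solver unless overridden by `mode`.
#' @param mode Optional override, `"expansion"` or `"exact"`.
#' @return A [field_state()] with the excitatory response `dr_e`.
#' @details In exact mode the per-mode spectral radius of the 2x2 weight
#'   block is checked; if any mode has spectral radius `>= 1` the inversion
#'   is invalid and an error identifies the offending mode. In expansion
#'   mode the same condition only triggers a warning (the truncated series
#'   is still evaluable, though inaccurate).
#' @export
solve_linear_response <- function(ops, r_stim, config, mode = NULL) {
  mode <- if (is.null(mode)) config$mode else match.arg(mode, c("expansion", "exact"))
  a <- ops$W_ee$spec
  bc <- ops$W_ei$spec * ops$W_ie$spec
  rho <- spectral_radius_modes(a, bc)
  if (max(rho) >= 1) {
    worst <- which.max(rho)
    msg <- sprintf(
      "spectral radius %.4f >= 1 at Fourier mode index %s: linear %s invalid",
      max(rho), paste(arrayInd(worst, dim(a)) - 1L, collapse = ","),
      if (mode == "exact") "inversion" else "expansion")
    if (mode == "exact") stop(msg) else warning(msg)
  }
  shat <- fft(r_stim$values)
  gain <- if (mode == "exact") (a + bc) / (1 - a - bc) else a + a^2 + bc
  out <- Re(fft(gain * shat, inverse = TRUE)) / length(shat)
  field_state(out, config)
}

# Per-mode spectral radius of the 2x2 block [[a, b], [c, 0]]; depends on b, c
# only through their product.
spectral_radius_modes <- function(a, bc) {
  disc <- sqrt(as.complex(a^2 + 4 * bc))
  pmax(Mod((a + disc) / 2), Mod((a - disc) / 2))
}

#' Decompose the truncated response into synaptic pathways
#'
#' Splits the second-order expansion of the excitatory response into its
#' three synaptic routes: monosynaptic `W_ee * r_stim`, disynaptic
#' excitatory `W_ee * W_ee * r_stim` and disynaptic inhibitory
#' `W_ei * W_ie * r_stim` (negative-valued). Their elementwise sum equals
#' [solve_linear_response()] in expansion mode.
#'
#' @inheritParams solve_linear_response
#' @return A `pathway_response` list of [field_state()]s: `mono_ee`,
#'   `di_eee`, `di_eie`, `total`.
#' @export
decompose_pathways <- function(ops, r_stim, config) {
  a <- ops$W_ee$spec
  bc <- ops$W_ei$spec * ops$W_ie$spec
  shat <- fft(r_stim$values)
  nfac <- length(shat)
  back <- function(gain) {
    field_state(Re(fft(gain * shat, inverse = TRUE)) / nfac, config)
  }
  mono <- back(a)
  eee <- back(a^2)
  eie <- back(bc)
  total <- field_state(mono$values + eee$values + eie$values, config)
  structure(list(mono_ee = mono, di_eee = eee, di_eie = eie, total = total),
            class = "pathway_response")
}

#' Sample the model response at recorded-cell positions
#'
#' Embeds a recorded population (FOV coordinates, planes collapsed: the
#' model is two-dimensional) in the center of the periodic model domain,
#' builds the stimulation field from the ensemble's targets, solves for the
#' excitatory response and reads it out at each cell's position and
#' preferred orientation (bilinear interpolation in space, nearest
#' orientation level).
#'
#' @param cells Data frame with columns `x`, `y` (um, FOV frame) and `po`
#'   (preferred orientation, degrees). Untuned models ignore `po`.
#' @param targets Data frame with columns `x`, `y` and optionally `theta`
#'   (target preferred orientations), in the same FOV frame.
#' @param config A [model_config()].
#' @param ops Optional precomputed [build_connectivity()] (rebuilt when
#'   missing).
#' @param fov_size FOV side length in um used for centering (default 800).
#' @return Numeric vector: predicted rate change per cell.
#' @export
predict_cell_responses <- function(cells, targets, config, ops = NULL,
                                   fov_size = 800) {
  if (fov_size > config$domain_size) {
    stop("population does not fit inside the model domain")
  }
  off <- (config$domain_size - fov_size) / 2
  if (any(cells$x < 0 | cells$x > fov_size | cells$y < 0 | cells$y > fov_size)) {
    stop("cell coordinates outside the FOV frame")
  }
  if (is.null(ops)) ops <- build_connectivity(config)
  tg <- data.frame(x = targets$x + off, y = targets$y + off)
  tg$theta <- if (!is.null(targets$theta)) targets$theta else 0
  resp <- solve_linear_response(ops, stim_field(tg, config), config)
  po <- if (!is.null(cells$po)) cells$po else rep(0, nrow(cells))
  interp_field(resp, cells$x + off, cells$y + off, po, config)
}

# Bilinear interpolation on the periodic grid at the nearest theta level.
interp_field <- function(field, x, y, theta, config) {
  n <- config$n_nodes
  sp <- config$grid_spacing
  nt <- config$n_orientations
  step <- 180 / nt
  it <- (round(theta / step) %% nt) + 1L
  fx <- x / sp
  fy <- y / sp
  ix0 <- floor(fx); iy0 <- floor(fy)
  tx <- fx - ix0; ty <- fy - iy0
  i0 <- (ix0 %% n) + 1L; i1 <- ((ix0 + 1) %% n) + 1L
  j0 <- (iy0 %% n) + 1L; j1 <- ((iy0 + 1) %% n) + 1L
  v <- field$values
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    sl <- v[, , it[k]]
    out[k] <- (1 - tx[k]) * (1 - ty[k]) * sl[i0[k], j0[k]] +
      tx[k] * (1 - ty[k]) * sl[i1[k], j0[k]] +
      (1 - tx[k]) * ty[k] * sl[i0[k], j1[k]] +
      tx[k] * ty[k] * sl[i1[k], j1[k]]
  }
  out
}
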