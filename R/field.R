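#' Discretized field on the periodic space-by-orientation domain
#'
#' A `field_state` wraps a numeric array of shape
#' `(n_nodes, n_nodes, n_orientations)` holding values of a rate field at
#' every grid node and orientation level, plus grid metadata.
#'
#' @param values Numeric array `(nx, ny, n_orientations)` of finite values.
#' @param config The [model_config()] the grid belongs to.
#' @return A `field_state` object.
#' @export
field_state <- function(values, config) {
  n <- config$n_nodes
  nt <- config$n_orientations
  if (length(dim(values)) == 2 && nt == 1) dim(values) <- c(dim(values), 1L)
  if (!identical(dim(values), c(n, n, nt))) {
    stop(sprintf("field values must have shape (%d, %d, %d)", n, n, nt))
  }
  if (!all(is.finite(values))) stop("field values must be finite")
  structure(list(values = values,
                 grid_spacing = config$grid_spacing,
                 domain_size = config$domain_size,
                 orientations = orientation_levels(config)),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<field_state> %d x %d x %d, spacing %g um, mass %.6g\n",
              d[1], d[2], d[3], x$grid_spacing, field_mass(x)))
  invisible(x)
}

#' Integrated mass of a field (sum of values times cell area)
#'
#' Orientation is a discrete label, not an integration variable: mass is
#' summed over orientation levels with unit weight.
#'
#' @param field A [field_state()].
#' @return Scalar integral over the domain.
#' @export
field_mass <- function(field) {
  sum(field$values) * field$grid_spacing^2
}

#' Photostimulation input field for a set of holographic targets
#'
#' Each target deposits a discretized point mass of `config$stim_amplitude`
#' at the grid node and orientation level nearest to its coordinates, i.e. a
#' node value of `amplitude / grid_spacing^2` so that total integrated mass
#' is `amplitude * n_targets`. Coincident targets accumulate.
#'
#' @param targets Data frame (or matrix) with columns `x`, `y` in um and
#'   optionally `theta` (preferred orientation in degrees; defaults to the
#'   first orientation level). Coordinates are wrapped into the periodic
#'   domain. An empty target set yields a zero field.
#' @param config A [model_config()].
#' @return A [field_state()] holding the stimulation field.
#' @export
stim_field <- function(targets, config) {
  n <- config$n_nodes
  nt <- config$n_orientations
  vals <- array(0, dim = c(n, n, nt))
  targets <- as.data.frame(targets)
  if (nrow(targets) > 0) {
    if (is.null(targets$theta)) targets$theta <- 0
    ix <- (round(targets$x / config$grid_spacing) %% n) + 1L
    iy <- (round(targets$y / config$grid_spacing) %% n) + 1L
    lev <- orientation_levels(config)
    step <- 180 / nt
    it <- (round(targets$theta / step) %% nt) + 1L
    amp <- config$stim_amplitude / config$grid_spacing^2
    for (k in seq_len(nrow(targets))) {
      vals[ix[k], iy[k], it[k]] <- vals[ix[k], iy[k], it[k]] + amp
    }
  }
  field_state(vals, config)
}
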