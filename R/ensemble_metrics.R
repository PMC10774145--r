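#' Mean pairwise 3D spread of a target set
#'
#' The spread of an ensemble is the arithmetic mean of all pairwise
#' Euclidean distances between its targets' centers of mass, computed in 3D
#' (plane index times plane spacing supplies depth).
#'
#' @param points An `n x 3` matrix or data frame of `(x, y, z)` um
#'   coordinates, `n >= 2`.
#' @return Spread in um.
#' @export
mean_pairwise_spread <- function(points) {
  pm <- as.matrix(points)
  if (nrow(pm) < 2) stop("spread needs at least 2 points")
  mean(stats::dist(pm))
}

#' Ensemble-level orientation selectivity
#'
#' The ensemble OSI is the OSI of the elementwise mean tuning curve of the
#' member cells (curves averaged first, then folded to orientations and
#' summarized); the mean OSI is the arithmetic mean of the members'
#' individual OSIs. The two differ when members prefer different
#' orientations: strongly tuned members with scattered preferences yield a
#' flat mean curve (low ensemble OSI, high mean OSI).
#'
#' @param tuning_curves Members-by-directions matrix of mean responses (8
#'   directions `0, 45, ..., 315` by default).
#' @param directions Direction grid in degrees.
#' @return List: `ensemble_osi`, `ensemble_po` (degrees), `mean_osi`.
#' @export
ensemble_osi <- function(tuning_curves, directions = seq(0, 315, by = 45)) {
  tm <- as.matrix(tuning_curves)
  stopifnot(ncol(tm) == length(directions))
  mean_curve <- colMeans(tm)
  fm <- fold_directions(mean_curve, directions)
  ens <- osi_from_folded(fm$folded, fm$orientations)
  member_osis <- apply(tm, 1, function(cv) {
    f <- fold_directions(cv, directions)
    osi_from_folded(f$folded, f$orientations)$osi
  })
  list(ensemble_osi = ens$osi, ensemble_po = ens$po,
       mean_osi = mean(member_osis))
}

#' Classify an ensemble by spatial spread and tuning
#'
#' Spatial class: `compact` when spread < 200 um, else `diffuse`. Tuning
#' class: `cotuned` when ensemble OSI > 0.7 and mean OSI > 0.5; `untuned`
#' when ensemble OSI < 0.3 and mean OSI < 0.5; otherwise `mixed`.
#'
#' @param spread Mean pairwise 3D spread, um.
#' @param ensemble_osi_value Ensemble OSI.
#' @param mean_osi Mean member OSI.
#' @return List: `spatial_class`, `tuning_class` (character).
#' @export
classify_ensemble <- function(spread, ensemble_osi_value, mean_osi) {
  spatial <- if (spread < 200) "compact" else "diffuse"
  tuning <- if (ensemble_osi_value > 0.7 && mean_osi > 0.5) {
    "cotuned"
  } else if (ensemble_osi_value < 0.3 && mean_osi < 0.5) {
    "untuned"
  } else {
    "mixed"
  }
  list(spatial_class = spatial, tuning_class = tuning)
}
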