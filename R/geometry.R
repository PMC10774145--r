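#' Minimal distance from a cell to any attempted target
#'
#' Distances are Euclidean in 3D by default, with plane index converted to
#' depth via the plane spacing (30 um). Every attempted target counts,
#' whether or not it was matched to a detected cell.
#'
#' @param cell_xyz Length-3 numeric `(x, y, z)` in um, or an `n x 3` matrix.
#' @param target_xyz `m x 3` matrix of target coordinates in um.
#' @param method `"3d"` (default) or `"2d"` (in-plane radial distance only).
#' @return Minimal distance(s) in um (vector of length `n`).
#' @export
min_target_distance <- function(cell_xyz, target_xyz, method = c("3d", "2d")) {
  method <- match.arg(method)
  cm <- matrix(as.numeric(unlist(cell_xyz)), ncol = 3)
  tm <- matrix(as.numeric(unlist(target_xyz)), ncol = 3)
  vapply(seq_len(nrow(cm)), function(i) {
    dx <- tm[, 1] - cm[i, 1]
    dy <- tm[, 2] - cm[i, 2]
    dz <- if (method == "3d") tm[, 3] - cm[i, 3] else 0
    min(sqrt(dx^2 + dy^2 + dz^2))
  }, numeric(1))
}

#' Off-target exclusion mask
#'
#' Cells at risk of stray-light activation are excluded from nontarget
#' analyses: within 15 um radially (in-plane) of a target on the same
#' plane, or within 30 um radially of a target exactly one plane away.
#' Targeted cells themselves are always masked.
#'
#' @param cells Data frame with columns `x`, `y` (um) and `plane` (integer),
#'   plus `cell_id` if `target_ids` is used.
#' @param targets Data frame with columns `x`, `y`, `plane` for each
#'   attempted target.
#' @param target_ids Optional cell ids of the targets (rows of `cells`
#'   matching these ids are masked regardless of geometry).
#' @param same_plane_um,adjacent_plane_um Radial thresholds (defaults 15
#'   and 30 um).
#' @return Logical vector: `TRUE` = excluded.
#' @export
off_target_mask <- function(cells, targets, target_ids = NULL,
                            same_plane_um = 15, adjacent_plane_um = 30) {
  n <- nrow(cells)
  excl <- rep(FALSE, n)
  for (j in seq_len(nrow(targets))) {
    r <- sqrt((cells$x - targets$x[j])^2 + (cells$y - targets$y[j])^2)
    dp <- abs(cells$plane - targets$plane[j])
    excl <- excl | (dp == 0 & r < same_plane_um) |
      (dp == 1 & r < adjacent_plane_um)
  }
  if (!is.null(target_ids)) excl <- excl | cells$cell_id %in% target_ids
  excl
}

#' Relative orientation preference of cells versus a stimulated ensemble
#'
#' Folds the difference between each cell's preferred orientation and the
#' ensemble's preferred orientation into `[0, 90]` degrees and snaps it to
#' the nearest of 0 (iso), 45 (oblique) or 90 (ortho). Cells failing the
#' tuned-cell filter (visually responsive with `p < 0.05` and OSI > 0.25)
#' are labeled `"untuned"` and reported as their own group.
#'
#' @param po_cell Preferred orientations of the cells, degrees (direction-
#'   valued input is fine: folding removes any 180-degree component).
#' @param po_ensemble Ensemble preferred orientation, degrees.
#' @param osi Cell OSIs (for the tuned filter).
#' @param p_visual Cell visual-responsiveness p-values.
#' @param osi_min,p_max Filter thresholds (defaults 0.25 and 0.05).
#' @return Factor with levels `"0"`, `"45"`, `"90"`, `"untuned"`.
#' @export
relative_tuning_split <- function(po_cell, po_ensemble, osi = NULL,
                                  p_visual = NULL, osi_min = 0.25,
                                  p_max = 0.05) {
  dt <- fold_orientation(po_cell - po_ensemble)
  lab <- as.character(c(0, 45, 90)[pmax(1, round(dt / 45) + 1)])
  if (!is.null(osi) || !is.null(p_visual)) {
    untuned <- rep(FALSE, length(dt))
    if (!is.null(osi)) untuned <- untuned | !(osi > osi_min) | is.na(osi)
    if (!is.null(p_visual)) untuned <- untuned | !(p_visual < p_max) | is.na(p_visual)
    lab[untuned] <- "untuned"
  }
  factor(lab, levels = c("0", "45", "90", "untuned"))
}
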