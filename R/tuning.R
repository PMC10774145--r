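#' Tuning curve, preferred orientation and selectivity from trial responses
#'
#' Computes the mean response per drifting-grating direction, folds opposite
#' directions into orientations by averaging, and summarizes selectivity as
#' `OSI = (PO - OO) / (PO + OO)` where PO is the maximal folded response and
#' OO the response at the orthogonal orientation. Folded responses are
#' rectified at zero before the OSI so that the index stays in `[0, 1]` even
#' with negative dF/F responses; an all-zero denominator yields OSI 0.
#' Visual responsiveness is assessed with a one-way ANOVA across all
#' conditions (directions plus blank, when provided).
#'
#' @param responses Per-trial response values.
#' @param direction Per-trial stimulus direction in degrees (`0, 45, ...,
#'   315`); use `NA` for blank (gray screen) trials.
#' @return List: `directions`, `tuning_curve` (mean per direction),
#'   `orientations`, `folded` (orientation curve), `po` (degrees), `oo`
#'   (degrees), `po_resp`, `oo_resp` (rectified), `osi`, `p_visual` (`NA`
#'   when no blank/insufficient replication for the test).
#' @export
tuning_and_osi <- function(responses, direction) {
  stopifnot(length(responses) == length(direction))
  is_blank <- is.na(direction)
  dirs <- sort(unique(direction[!is_blank]))
  if (any(tabulate(match(direction[!is_blank], dirs)) < 2)) {
    stop("need at least 2 trials per direction")
  }
  curve <- vapply(dirs, function(d) mean(responses[!is_blank & direction == d]),
                  numeric(1))
  orients <- sort(unique(dirs %% 180))
  folded <- vapply(orients, function(o) mean(curve[dirs %% 180 == o]),
                   numeric(1))
  rect <- pmax(folded, 0)
  ipo <- which.max(rect)
  po <- orients[ipo]
  oo <- (po + 90) %% 180
  ioo <- which(orients == oo)
  po_resp <- rect[ipo]
  oo_resp <- if (length(ioo)) rect[ioo] else 0
  osi <- if (po_resp + oo_resp > 0) (po_resp - oo_resp) / (po_resp + oo_resp) else 0
  cond <- ifelse(is_blank, "blank", as.character(direction))
  p_visual <- NA_real_
  if (length(unique(cond)) > 1 && all(table(cond) >= 2)) {
    # suppress the "perfect fit" warning that exact synthetic data triggers
    p_visual <- suppressWarnings(
      stats::anova(stats::lm(responses ~ factor(cond)))[["Pr(>F)"]][1])
  }
  list(directions = dirs, tuning_curve = curve,
       orientations = orients, folded = folded,
       po = po, oo = oo, po_resp = po_resp, oo_resp = oo_resp,
       osi = osi, p_visual = p_visual)
}

#' OSI of an orientation-folded response pair or curve
#'
#' Small helper used by both cell-level and ensemble-level summaries:
#' rectifies the folded curve, takes the peak and its orthogonal response
#' and returns `(PO - OO) / (PO + OO)` (0 when the denominator vanishes).
#'
#' @param folded Folded orientation responses (one per orientation level,
#'   levels evenly spaced over `[0, 180)`).
#' @param orientations Orientation levels in degrees.
#' @return List `osi`, `po` (degrees).
#' @export
osi_from_folded <- function(folded, orientations) {
  rect <- pmax(folded, 0)
  ipo <- which.max(rect)
  po <- orientations[ipo]
  ioo <- which(orientations == (po + 90) %% 180)
  po_r <- rect[ipo]
  oo_r <- if (length(ioo)) rect[ioo] else 0
  osi <- if (po_r + oo_r > 0) (po_r - oo_r) / (po_r + oo_r) else 0
  list(osi = osi, po = po)
}

#' Fold an 8-direction tuning curve into 4 orientations
#'
#' Opposite directions are averaged.
#'
#' @param curve Mean responses for directions `0, 45, ..., 315` (length 8).
#' @param directions The direction grid (default `seq(0, 315, by = 45)`).
#' @return List `orientations` (degrees) and `folded` responses.
#' @export
fold_directions <- function(curve, directions = seq(0, 315, by = 45)) {
  stopifnot(length(curve) == length(directions))
  orients <- sort(unique(directions %% 180))
  folded <- vapply(orients, function(o) mean(curve[directions %% 180 == o]),
                   numeric(1))
  list(orientations = orients, folded = folded)
}
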