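#' Bin responses by distance
#'
#' Contiguous bins of the given width starting at 0 (edges `0, w, 2w, ...`).
#' Empty bins are kept as `NA` means, not zeros.
#'
#' @param distance,response Numeric vectors of equal length.
#' @param bin_width Bin width in um (default 15).
#' @param max_distance Upper edge; defaults to cover the largest distance.
#' @return A `distance_curve` data frame: `bin_lo`, `bin_hi`, `bin_center`,
#'   `mean`, `sem` (sample SD / sqrt(n), `NA` for n < 2), `n`.
#' @export
bin_distance_response <- function(distance, response, bin_width = 15,
                                  max_distance = NULL) {
  ok <- is.finite(distance) & is.finite(response)
  distance <- distance[ok]
  response <- response[ok]
  if (is.null(max_distance)) {
    max_distance <- bin_width * ceiling(max(distance) / bin_width + 1e-9)
  }
  edges <- seq(0, max_distance, by = bin_width)
  if (edges[length(edges)] < max_distance) edges <- c(edges, max_distance)
  idx <- findInterval(distance, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  n <- tabulate(idx, nbins = nb)
  mean_v <- rep(NA_real_, nb)
  sem_v <- rep(NA_real_, nb)
  for (b in which(n > 0)) {
    v <- response[idx == b]
    mean_v[b] <- mean(v)
    if (length(v) > 1) sem_v[b] <- stats::sd(v) / sqrt(length(v))
  }
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    bin_center = (edges[-length(edges)] + edges[-1]) / 2,
                    mean = mean_v, sem = sem_v, n = n)
  class(out) <- c("distance_curve", "data.frame")
  out
}

#' Distance-resolved response curve of a filtered dataset
#'
#' Averages each included (cell, ensemble) pair's response across its
#' included trials, attaches the pair's minimal 3D distance to any attempted
#' target, and bins by distance (15 um default). Optionally splits the
#' population by relative orientation preference (iso 0, oblique 45, ortho
#' 90 and untuned), restricting the split to visually responsive, tuned
#' cells.
#'
#' @param pairs A pair table as returned by [pair_responses()] (columns
#'   `response`, `min_distance` and, for grouped curves, `delta_theta`).
#' @param bin_width Bin width, um.
#' @param group `NULL` for a single pooled curve, or `"delta_theta"` to
#'   split by relative tuning.
#' @param max_distance Optional upper distance edge, um.
#' @return A `distance_curve` (pooled) or a named list of `distance_curve`s
#'   keyed by group level.
#' @export
distance_response_curve <- function(pairs, bin_width = 15, group = NULL,
                                    max_distance = NULL) {
  if (is.null(group)) {
    return(bin_distance_response(pairs$min_distance, pairs$response,
                                 bin_width, max_distance))
  }
  stopifnot(group %in% names(pairs))
  lv <- split(seq_len(nrow(pairs)), pairs[[group]])
  lapply(lv, function(i) {
    bin_distance_response(pairs$min_distance[i], pairs$response[i],
                          bin_width, max_distance)
  })
}
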