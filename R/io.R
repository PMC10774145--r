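#' Write a photostimulation dataset to plain CSV files
#'
#' One CSV per table (`cells.csv`, `ensembles.csv`, `targets.csv`,
#' `trials.csv`, `responses.csv`), readable by any toolchain.
#'
#' @param dataset A [stim_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "stim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("cells", "ensembles", "targets", "trials", "responses")) {
    utils::write.csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a photostimulation dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV tables.
#' @return A [stim_dataset()].
#' @export
read_dataset <- function(dir) {
  rd <- function(nm) utils::read.csv(file.path(dir, paste0(nm, ".csv")))
  stim_dataset(cells = rd("cells"), ensembles = rd("ensembles"),
               targets = rd("targets"), trials = rd("trials"),
               responses = rd("responses"))
}
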