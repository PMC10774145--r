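#' Physiological point-spread-function width from offset responses
#'
#' Fits a Gaussian to evoked responses measured while digitally offsetting
#' the stimulation hologram from the target (one axis at a time), aligns to
#' the fitted peak and reports the full width at half maximum
#' (`FWHM = 2 sqrt(2 ln 2) sigma`) and its half (HWHM).
#'
#' @param offset Hologram offsets along one axis, um.
#' @param response Evoked response at each offset.
#' @param fit_center If `TRUE` (default) the peak location is a free
#'   parameter; otherwise the peak is fixed at offset 0.
#' @return List: `sigma`, `fwhm`, `hwhm`, `amplitude`, `center` (um).
#' @export
ppsf_fit <- function(offset, response, fit_center = TRUE) {
  stopifnot(length(offset) == length(response))
  if (length(offset) < 4) stop("too few offsets for a PPSF fit")
  a0 <- max(response)
  mu0 <- offset[which.max(response)]
  s0 <- max(diff(range(offset)) / 4, 1e-3)
  fit <- tryCatch({
    if (fit_center) {
      minpack.lm::nlsLM(response ~ A * exp(-(offset - mu)^2 / (2 * s^2)),
                        start = list(A = a0, mu = mu0, s = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(response ~ A * exp(-offset^2 / (2 * s^2)),
                        start = list(A = a0, s = s0),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) stop("PPSF Gaussian fit did not converge")
  co <- stats::coef(fit)
  sigma <- abs(co[["s"]])
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  list(sigma = sigma, fwhm = fwhm, hwhm = fwhm / 2,
       amplitude = co[["A"]],
       center = if (fit_center) co[["mu"]] else 0)
}
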