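#' Govardovskii A1 visual-pigment absorbance template
#'
#' Evaluates the standard A1 (11-cis-retinal) visual-pigment absorbance
#' template on a wavelength grid: the alpha band as a function of the
#' normalized inverse wavelength `x = lambda_max / lambda`, optionally plus
#' the short-wavelength beta band (a Gaussian whose position and width are
#' linear in `lambda_max`). The returned vector is normalized so its maximum
#' over the grid is exactly 1, attained within one grid step of `lambda_max`.
#'
#' This template serves two roles in the package: simulation ground truth
#' for [simulate_measurement()] and an independent oracle for the
#' smoothing-spline lambda-max estimator, which never sees the closed form.
#'
#' @param lambda_max peak absorbance wavelength in nm; supported range
#'   330--600 nm (the A1 alpha-band parameterization's validated range).
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param beta_band include the beta band? Default: on for pigments with
#'   `lambda_max < 500` nm, where the beta band is spectrally distinct.
#' @return numeric vector of normalized absorbances, same length as
#'   `wavelengths`, maximum exactly 1.
#' @examples
#' wl <- 250:700
#' s <- govardovskii_template(443, wl)
#' wl[which.max(s)]
#' @export
govardovskii_template <- function(lambda_max, wavelengths,
                                  beta_band = lambda_max < 500) {
  stopifnot(is.numeric(lambda_max), length(lambda_max) == 1L,
            is.numeric(wavelengths))
  if (is.na(lambda_max) || lambda_max < 330 || lambda_max > 600)
    stop_input("lambda_max must lie in [330, 600] nm, got ", lambda_max)
  if (length(wavelengths) < 2L || anyNA(wavelengths) ||
      any(diff(wavelengths) <= 0))
    stop_input("wavelengths must be a strictly increasing numeric vector")

  x <- lambda_max / wavelengths
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  s <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
              exp(-14.9 * (1.104 - x)) + 0.674)
  if (isTRUE(beta_band)) {
    lm_beta <- 189 + 0.315 * lambda_max
    bw_beta <- -40.5 + 0.195 * lambda_max
    s <- s + 0.26 * exp(-((wavelengths - lm_beta) / bw_beta)^2)
  }
  s / max(s)
}
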