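#' Parameters for simulated pigment absorbance scans
#'
#' Describes the generative model for one reconstructed-pigment measurement:
#' each dark scan is
#' `baseline + protein peak + alpha_amplitude * template(lambda_max) + noise`
#' and each post-bleach (light) scan replaces the bleached fraction of the
#' pigment by a free-retinal-like photoproduct template near 380 nm. Noise is
#' independent Gaussian per wavelength point per scan.
#'
#' Defaults emulate a low-expression cone-opsin reconstruction: pigment
#' alpha-band amplitude 0.015 AU with a 280-nm protein peak ten times
#' higher (the 10:1 protein-to-pigment ratio seen for poorly expressing
#' cone pigments), flat baseline, full bleach, 8 replicates, and a noise SD
#' calibrated so per-replicate lambda-max scatter lands in the 1--15 nm
#' range typical of such measurements (see the methods vignette).
#'
#' @param lambda_max true pigment peak, nm.
#' @param alpha_amplitude alpha-band amplitude, AU.
#' @param beta_band include beta band in the pigment template? Default on
#'   below 500 nm.
#' @param protein_peak_amplitude amplitude of the 280-nm protein peak, AU.
#' @param baseline_offset,baseline_slope flat offset (AU) and linear drift
#'   (AU/nm) of the baseline. Default drift 0.
#' @param bleach_product_lambda_max peak of the bleaching-product template,
#'   nm (free-retinal-like, default 380).
#' @param bleach_fraction proportion of pigment bleached in light scans,
#'   in `[0, 1]`.
#' @param noise_sd Gaussian noise SD per point, AU; `>= 0`.
#' @param n_replicates number of dark scans (and of light scans), `>= 1`.
#' @param wavelength_grid scan grid, nm; default 250--700 nm for pigments
#'   at or below 500 nm and 250--750 nm above (the two scan ranges used for
#'   SWS2- and LWS-class pigments).
#' @param seed optional RNG seed for reproducibility.
#' @return an object of class `pigment_template_params`.
#' @export
pigment_template_params <- function(lambda_max,
                                    alpha_amplitude = 0.015,
                                    beta_band = lambda_max < 500,
                                    protein_peak_amplitude = 10 * alpha_amplitude,
                                    baseline_offset = 0.02,
                                    baseline_slope = 0,
                                    bleach_product_lambda_max = 380,
                                    bleach_fraction = 1,
                                    noise_sd = 0.0015,
                                    n_replicates = 8L,
                                    wavelength_grid = NULL,
                                    seed = NULL) {
  if (is.null(wavelength_grid))
    wavelength_grid <- seq(250, if (lambda_max > 500) 750 else 700, by = 1)
  if (lambda_max < min(wavelength_grid) || lambda_max > max(wavelength_grid))
    stop_input("lambda_max must lie within the wavelength grid")
  if (bleach_fraction < 0 || bleach_fraction > 1)
    stop_input("bleach_fraction must be in [0, 1]")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop_input("n_replicates must be >= 1")
  structure(list(lambda_max = lambda_max,
                 alpha_amplitude = alpha_amplitude,
                 beta_band = isTRUE(beta_band),
                 protein_peak_amplitude = protein_peak_amplitude,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope,
                 bleach_product_lambda_max = bleach_product_lambda_max,
                 bleach_fraction = bleach_fraction,
                 noise_sd = noise_sd,
                 n_replicates = n_replicates,
                 wavelength_grid = as.numeric(wavelength_grid),
                 seed = seed),
            class = "pigment_template_params")
}

#' Simulate a replicated dark/light pigment measurement
#'
#' Draws `n_replicates` dark scans and `n_replicates` light scans from the
#' generative model described in [pigment_template_params()]. With
#' `noise_sd = 0` and `bleach_fraction = 1`, `dark - light` equals
#' `alpha_amplitude * (pigment template - bleach-product template)` exactly;
#' results are bit-reproducible for a fixed `seed`.
#'
#' @param params a `pigment_template_params` object.
#' @return a [spectral_measurement()] whose label records the true peak;
#'   the truth is also attached as attribute `"truth"`.
#' @export
simulate_measurement <- function(params) {
  stopifnot(inherits(params, "pigment_template_params"))
  p <- params
  wl <- p$wavelength_grid
  pig <- govardovskii_template(p$lambda_max, wl, p$beta_band)
  prod <- govardovskii_template(p$bleach_product_lambda_max, wl,
                                beta_band = FALSE)
  baseline <- p$baseline_offset + p$baseline_slope * (wl - wl[1L]) +
    p$protein_peak_amplitude * exp(-0.5 * ((wl - 280) / 20)^2)
  dark_clean <- baseline + p$alpha_amplitude * pig
  light_clean <- baseline + p$alpha_amplitude *
    ((1 - p$bleach_fraction) * pig + p$bleach_fraction * prod)

  with_seed(p$seed, {
    dark <- lapply(seq_len(p$n_replicates), function(i)
      spectrum(wl, dark_clean + rnorm(length(wl), 0, p$noise_sd), "dark", i))
    light <- lapply(seq_len(p$n_replicates), function(i)
      spectrum(wl, light_clean + rnorm(length(wl), 0, p$noise_sd), "light", i))
    m <- spectral_measurement(sprintf("sim_%gnm", p$lambda_max), dark, light)
    attr(m, "truth") <- list(lambda_max = p$lambda_max,
                             dark_clean = dark_clean,
                             light_clean = light_clean)
    m
  })
}
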