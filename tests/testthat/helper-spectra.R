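# In-code fixtures: analytic lineshapes on controllable grids.

# Single Lorentzian on a uniform decreasing ppm grid. points_per_fwhm
# controls digital resolution; span_fwhm the window half-width in FWHMs.
lorentzSpectrum <- function(fwhm_Hz = 1, center_ppm = 5, area = 1,
                            points_per_fwhm = 64, span_fwhm = 40,
                            freq_MHz = 600, baseline = function(p) 0) {
  step <- fwhm_Hz / points_per_fwhm / freq_MHz
  half <- span_fwhm * fwhm_Hz / freq_MHz
  ppm <- seq(center_ppm + half, center_ppm - half, by = -step)
  y <- lorentzianProfile(ppm, center_ppm, fwhm_Hz, area, freq_MHz) +
    vapply(ppm, baseline, numeric(1))
  spectrum1D(ppm, y, acquisitionParams(spectrometer_frequency_MHz = freq_MHz))
}

# Gaussian peak of given FWHM (for lineshape-agnostic width checks).
gaussSpectrum <- function(fwhm_Hz = 2, center_ppm = 5, height = 1,
                          points_per_fwhm = 64, span_fwhm = 10,
                          freq_MHz = 600) {
  step <- fwhm_Hz / points_per_fwhm / freq_MHz
  half <- span_fwhm * fwhm_Hz / freq_MHz
  ppm <- seq(center_ppm + half, center_ppm - half, by = -step)
  sigma_Hz <- fwhm_Hz / (2 * sqrt(2 * log(2)))
  y <- height * exp(-((ppm - center_ppm) * freq_MHz)^2 / (2 * sigma_Hz^2))
  spectrum1D(ppm, y, acquisitionParams(spectrometer_frequency_MHz = freq_MHz))
}

# True total concentrations of the plasma-like mixture, named by metabolite.
plasmaTruth <- function() {
  mix <- plasmaMixture()
  stats::setNames(vapply(mix, function(m) m@total_conc_mM, numeric(1)),
                  vapply(mix, function(m) m@name, character(1)))
}
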