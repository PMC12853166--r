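test_that("baseline correction removes constants and tilted baselines", {
  s <- spectrum1D(seq(5, 4, by = -0.001), rep(3.2, 1001))
  flat <- baselineCorrect(s, 0L)
  expect_equal(intensity(flat), rep(0, 1001))

  # Lorentzian on a sloped baseline: generation parameters are the oracle
  peak <- lorentzSpectrum(fwhm_Hz = 1, span_fwhm = 10, points_per_fwhm = 32,
                          baseline = function(p) 0.4 * p - 1.5)
  apex_true <- max(lorentzianProfile(chemicalShift(peak), 5, 1, 1, 600))
  corr <- baselineCorrect(peak, 1L)
  resid <- intensity(corr) -
    lorentzianProfile(chemicalShift(corr), 5, 1, 1, 600)
  expect_lt(sqrt(mean(resid^2)), 0.01 * apex_true)
  expect_lt(abs(max(intensity(corr)) - apex_true) / apex_true, 0.01)

  # pure peak far from the window edges is barely perturbed
  pure <- lorentzSpectrum(fwhm_Hz = 1, span_fwhm = 10, points_per_fwhm = 32)
  corr2 <- baselineCorrect(pure, 1L)
  expect_lt(abs(max(intensity(corr2)) - max(intensity(pure))) /
              max(intensity(pure)), 0.01)

  expect_error(baselineCorrect(spectrum1D(c(1, 0.9, 0.8), c(0, 1, 0)), 5L),
               class = "cpmgInputError")
})

test_that("direct half-height FWHM is accurate and lineshape-agnostic", {
  # Lorentzians across the working linewidth range
  for (fw in c(0.5, 1, 2, 5)) {
    s <- lorentzSpectrum(fwhm_Hz = fw, points_per_fwhm = 64, span_fwhm = 10)
    m <- measureFwhmDirect(s, 5)
    expect_lt(abs(fwhmHz(m) - fw) / fw, 0.01)
    expect_identical(m@method, "direct")
    expect_identical(m@fit_residual_rms, 0)
  }
  # a Gaussian of FWHM 2 Hz measures 2 Hz: only the half-height span matters
  g <- gaussSpectrum(fwhm_Hz = 2)
  expect_lt(abs(fwhmHz(measureFwhmDirect(g, 5)) - 2) / 2, 0.01)
})

test_that("direct FWHM fails cleanly on truncated or absent peaks", {
  # flank cut 0.4 FWHM from the center never crosses half height
  s <- lorentzSpectrum(fwhm_Hz = 1, points_per_fwhm = 64, span_fwhm = 10)
  cut <- extractRegion(s, 5 + 0.4 * 1 / 600, 5 - 10 / 600)
  expect_error(measureFwhmDirect(cut, 5), class = "cpmgTruncatedPeakError")

  flat <- spectrum1D(seq(6, 4, by = -0.001), rep(0, 2001))
  expect_error(measureFwhmDirect(flat, 5), class = "cpmgPeakNotFoundError")

  # coarse digitization (< 8 points per FWHM) is refused
  coarse <- lorentzSpectrum(fwhm_Hz = 1, points_per_fwhm = 5, span_fwhm = 10)
  expect_error(measureFwhmDirect(coarse, 5), class = "cpmgInputError")
})

test_that("deconvolution recovers single and overlapping Lorentzians", {
  s <- lorentzSpectrum(fwhm_Hz = 1.2, center_ppm = 5, area = 2,
                       points_per_fwhm = 32, span_fwhm = 20)
  # initial guess off by ~20 percent in every parameter
  fit <- deconvolve(s, list(lorentzian(5 + 0.2 * 1.2 / 600, 1.2 * 1.2, 2.4)))
  expect_length(fit, 1L)
  expect_lt(abs(fit[[1]]@center_ppm - 5) * 600 / 1.2, 1e-3)
  expect_lt(abs(fwhmHz(fit[[1]]) - 1.2) / 1.2, 1e-3)
  expect_lt(abs(peakArea(fit[[1]]) - 2) / 2, 1e-3)

  # two lines separated by 1.5 x mean FWHM, unequal heights
  fw <- c(1.0, 1.4); sep <- 1.5 * mean(fw) / 600
  ppm <- seq(5 + 30 / 600, 5 - 30 / 600, by = -1 / 64 / 600)
  y <- lorentzianProfile(ppm, 5, fw[1], 1, 600) +
    lorentzianProfile(ppm, 5 + sep, fw[2], 0.6, 600)
  s2 <- spectrum1D(ppm, y)
  fit2 <- deconvolve(s2, list(lorentzian(5 - 0.3 / 600, 1.1, 0.8),
                              lorentzian(5 + sep + 0.3 / 600, 1.2, 0.8)))
  expect_length(fit2, 2L)
  expect_lt(abs(fwhmHz(fit2[[1]]) - fw[1]) / fw[1], 0.02)
  expect_lt(abs(fwhmHz(fit2[[2]]) - fw[2]) / fw[2], 0.02)

  expect_error(deconvolve(s, list()), class = "cpmgInputError")
})

test_that("deconvolution is scale-equivariant and agrees with direct FWHM", {
  s <- lorentzSpectrum(fwhm_Hz = 0.9, area = 1.7, points_per_fwhm = 32,
                       span_fwhm = 20)
  k <- 37.5
  s_scaled <- spectrum1D(chemicalShift(s), k * intensity(s),
                         acquisition(s))
  f1 <- deconvolve(s, list(lorentzian(5, 1, 1)))
  f2 <- deconvolve(s_scaled, list(lorentzian(5, 1, k)))
  expect_equal(peakArea(f2[[1]]), k * peakArea(f1[[1]]), tolerance = 1e-6)
  expect_equal(fwhmHz(f2[[1]]), fwhmHz(f1[[1]]), tolerance = 1e-6)
  expect_equal(f2[[1]]@center_ppm, f1[[1]]@center_ppm, tolerance = 1e-9)

  # direct and deconvolved widths agree on isolated noiseless Lorentzians
  for (fw in c(0.5, 1.5, 3, 5)) {
    sp <- lorentzSpectrum(fwhm_Hz = fw, points_per_fwhm = 64, span_fwhm = 15)
    direct <- fwhmHz(measureFwhmDirect(sp, 5))
    dec <- fwhmHz(deconvolve(sp, list(lorentzian(5, fw * 1.2, 1.2)))[[1]])
    expect_lt(abs(direct - dec) / dec, 0.02)
  }
})

test_that("close initial guesses merge onto a single component", {
  s <- lorentzSpectrum(fwhm_Hz = 1, area = 1, points_per_fwhm = 32,
                       span_fwhm = 20)
  fit <- deconvolve(s, list(lorentzian(5 - 0.01 / 600, 1, 0.5),
                            lorentzian(5 + 0.01 / 600, 1, 0.5)))
  expect_length(fit, 1L)
  expect_lt(abs(peakArea(fit[[1]]) - 1) / 1, 0.01)
})

test_that("integration matches the analytic Lorentzian tail integral", {
  s <- lorentzSpectrum(fwhm_Hz = 1, area = 1, points_per_fwhm = 64,
                       span_fwhm = 25)
  got <- integrateSignal(s, 5 + 20 / 600, 5 - 20 / 600)
  expected <- 1 - (2 / pi) * atan(1 / 40)  # mass within +/- 20 FWHM
  expect_lt(abs(got - expected) / expected, 0.005)

  # zero region integrates to zero; doubling intensities doubles the area
  z <- spectrum1D(seq(6, 4, by = -0.01), rep(0, 201))
  expect_equal(integrateSignal(z, 5.5, 4.5), 0)
  s2 <- spectrum1D(chemicalShift(s), 2 * intensity(s), acquisition(s))
  expect_equal(integrateSignal(s2, 5 + 20 / 600, 5 - 20 / 600), 2 * got)

  # additive over adjacent windows sharing one edge point
  left <- integrateSignal(s, 5 + 20 / 600, 5)
  right <- integrateSignal(s, 5, 5 - 20 / 600)
  expect_equal(left + right, got, tolerance = 1e-12)

  expect_error(integrateSignal(s, 7, 6), class = "cpmgInputError")
})

test_that("multiplet convention picks the tallest resolved component", {
  comps <- list(lorentzian(5.00, 1.0, 1.0),    # height 2/pi
                lorentzian(5.01, 0.5, 0.9))    # taller: 2*0.9/(pi*0.5)
  expect_equal(tallestComponent(comps)@center_ppm, 5.01)
  tab <- peakTable(list(peakMeasurement("x", 1.23, 4.5)))
  expect_identical(names(tab),
                   c("signal_id", "center_ppm", "fwhm_Hz", "area", "method",
                     "residual"))
})
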