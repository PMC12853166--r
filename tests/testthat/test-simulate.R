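test_that("bound fraction solves the 1:1 mass balance exactly", {
  expect_equal(boundFraction(2.5, 0, 0.5), 0)
  # stoichiometric limit: protein excess with vanishing Kd binds everything
  expect_gt(boundFraction(0.1, 10, 1e-9), 1 - 1e-6)

  # brute-force bisection on the complex concentration as oracle
  bisect <- function(L, P, Kd) {
    lo <- 0; hi <- min(L, P)
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if ((L - mid) * (P - mid) - Kd * mid > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2 / L
  }
  for (case in list(c(2.5, 0.27, 0.27), c(6.025, 0.135, 0.27),
                    c(0.09, 0.27, 2.4))) {
    expect_equal(boundFraction(case[1], case[2], case[3]),
                 bisect(case[1], case[2], case[3]), tolerance = 1e-9)
  }
})

test_that("bound fraction is bounded, monotone in protein, anti-monotone in Kd", {
  P <- seq(0, 0.3, by = 0.02)
  f <- boundFraction(2.5, P, 0.27)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) >= 0))
  kd <- c(0.05, 0.1, 0.5, 1, 5)
  g <- vapply(kd, function(k) boundFraction(2.5, 0.27, k), numeric(1))
  expect_true(all(diff(g) <= 0))
})

test_that("fast-exchange linewidth is the population average", {
  b <- bindingModel(0.27, 1, 9)
  expect_equal(observedFwhm(0, b), 1)
  expect_equal(observedFwhm(1, b), 9)
  expect_equal(observedFwhm(0.5, b), 5)
  expect_error(observedFwhm(1.1, b), class = "cpmgInputError")
})

test_that("CPMG loss is exponential in the excess relaxation rate", {
  expect_equal(cpmgLossFactor(0.78, 0.78), 1)
  # scalar evaluation of the stated closed form at the documented case
  expect_equal(cpmgLossFactor(1.40, 0.78, 0.1805),
               exp(0.1805 * pi * 0.62))
  # the linearization 1 + 0.567 * broadening deviates quadratically; at a
  # 0.62 Hz broadening the exponential sits ~5.2 percent above it
  expect_lt(abs(cpmgLossFactor(1.40, 0.78, 0.1805) -
                  (1 + 0.567 * 0.62)) / (1 + 0.567 * 0.62), 0.06)
  broad <- seq(0, 2, by = 0.1)
  expect_true(all(diff(cpmgLossFactor(0.78 + broad, 0.78)) > 0))
  expect_error(cpmgLossFactor(0.7, 0.78), class = "cpmgInputError")
})

test_that("simulated spectra honor the requested linewidths and are seed-reproducible", {
  grid <- defaultPpmGrid(1.5, -0.3)
  nb <- metaboliteSpec("probe", 1, data.frame(ppm = 0.5, protons = 3),
                       binding = NULL, fwhm_free_Hz = 1.1)
  spec <- sampleSpec(list(nb), shim_extra_fwhm_Hz = 0.2, noise_sd = 0,
                     internal_standard = internalStandard(signal_ppm = 1.2))
  s <- simulateSpectrum(spec, grid)
  m <- measureFwhmDirect(extractRegion(s, 0.55, 0.45), 0.5)
  expect_lt(abs(fwhmHz(m) - 1.3) / 1.3, 0.01)  # free + shim

  # identical seeds give bit-identical spectra (with noise on)
  specn <- sampleSpec(list(nb), shim_extra_fwhm_Hz = 0.2, noise_sd = 0.01,
                      internal_standard = internalStandard(signal_ppm = 1.2),
                      seed = 11L)
  s1 <- simulateSpectrum(specn, grid)
  s2 <- simulateSpectrum(specn, grid)
  expect_identical(intensity(s1), intensity(s2))
  s3 <- simulateSpectrum(sampleSpec(list(nb), shim_extra_fwhm_Hz = 0.2,
                                    noise_sd = 0.01,
                                    internal_standard = internalStandard(signal_ppm = 1.2),
                                    seed = 12L), grid)
  expect_false(identical(intensity(s1), intensity(s3)))

  # a grid coarser than 8 points per FWHM is refused
  expect_error(simulateSpectrum(spec, defaultPpmGrid(1.5, -0.3, step_ppm = 4e-4)),
               class = "cpmgInputError")
})

test_that("zero-protein spectra show no signal loss", {
  grid <- defaultPpmGrid()
  base <- tspTitrationSample()
  s0a <- simulateSpectrum(base, grid)
  base@seed <- 99L
  s0b <- simulateSpectrum(base, grid)
  a1 <- integrateSignal(s0a, 0.05, -0.05)
  a2 <- integrateSignal(s0b, 0.05, -0.05)
  expect_equal(signalLossFactor(a1, a2), 1, tolerance = 1e-6)
})

test_that("titrations broaden monotonically and linearly in protein molarity", {
  spectra <- simulateTitration(tspMetabolite(), hsaTitrationLevels(),
                               tspTitrationSample())
  expect_length(spectra, 14L)
  fw <- vapply(spectra, function(s)
    fwhmHz(measureSignal(s, 0, signal_id = "TSP")), numeric(1))
  expect_true(all(diff(fw) > 0))
  # ligand >> protein regime: linewidth vs protein molarity is linear
  P_mM <- hsaTitrationLevels() / 66478 * 1000
  expect_gt(summary(lm(fw ~ P_mM))$r.squared, 0.99)

  expect_error(simulateTitration(tspMetabolite(), numeric(0)),
               class = "cpmgInputError")
})

test_that("fitted titration calibration matches an OLS-on-exponential oracle", {
  spectra <- simulateTitration(tspMetabolite(), hsaTitrationLevels(),
                               tspTitrationSample())
  cal <- calibrateFromTitration(spectra)
  expect_equal(cal$pairs$loss_factor[1], 1)
  expect_true(all(diff(cal$pairs$loss_factor) > 0))

  # oracle: generating parameters -> true broadenings -> exact exponential
  # loss factors -> ordinary least squares on those points
  tsp <- tspMetabolite()
  x_true <- boundFraction(6.025, hsaTitrationLevels() / 66478 * 1000, 0.27) *
    (tsp@binding@fwhm_bound_Hz - tsp@binding@fwhm_free_Hz)
  y_true <- exp(0.1805 * pi * x_true)
  oracle <- lm(y_true ~ x_true)
  # measured linewidths carry a small (<1%) fit bias that the slope
  # amplifies, so the fitted slope tracks the oracle to a few percent
  expect_lt(abs(coef(cal$model)[["slope_per_Hz"]] - coef(oracle)[[2]]) /
              coef(oracle)[[2]], 0.04)
  expect_lt(abs(coef(cal$model)[["intercept"]] - coef(oracle)[[1]]), 0.01)
  expect_gt(fitR2(cal$model), 0.99)
})

test_that("kdFromBroadening inverts the isotherm", {
  kd <- kdFromBroadening(0.5, 1.455, 0.2707, 15)
  f <- boundFraction(1.455, 0.2707, kd)
  expect_equal(f * 15, 0.5, tolerance = 1e-9)
  expect_error(kdFromBroadening(20, 1, 0.27, 15), class = "cpmgInputError")
})
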