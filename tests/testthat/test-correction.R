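test_that("the four-step correction chain reproduces the documented TSP case", {
  S_c <- shimCorrection(0.80, 0.70)
  expect_equal(S_c, 0.10)
  L_sMc <- applyShim(1.50, S_c)
  expect_equal(L_sMc, 1.40)
  L_sMb <- lineBroadening(L_sMc, 0.78)
  expect_equal(L_sMb, 0.62)
  C_b <- correctionFactor(publishedCalibration(), L_sMb)
  expect_equal(round(C_b, 2), 1.35)
  total <- totalConcentration(4.45, round(C_b, 2))
  expect_lt(abs(total - 6.008), 5e-4 + 1e-9)

  # the composed correctSample path produces the same chain
  res <- correctSample(
    list(peakMeasurement("TSP", 1.50, 1)),
    shim_ref = peakMeasurement("formate", 0.80, 1),
    library = readSignalLibrary(),
    free_concs = c(TSP = 4.45))
  expect_equal(res$S_c_Hz, 0.10)
  expect_equal(res$L_sMc_Hz, 1.40)
  expect_equal(res$L_sMb_Hz, 0.62)
  expect_equal(round(res$C_b, 2), 1.35)
  expect_lt(abs(res$free_conc_mM * round(res$C_b, 2) - 6.008), 5e-4 + 1e-9)
})

test_that("shim correction passes negatives through; shim application rejects nonpositive widths", {
  expect_equal(shimCorrection(0.65, 0.70), -0.05)
  for (x in c(0.1, 0.7, 3)) expect_equal(shimCorrection(x, x), 0)
  expect_error(shimCorrection(-1, 0.7), class = "cpmgInputError")
  expect_equal(applyShim(1.3, 0), 1.3)
  expect_error(applyShim(0.5, 0.6), class = "cpmgInconsistentShimError")
})

test_that("line broadening clamps negative differences to zero with a diagnostic", {
  expect_equal(lineBroadening(0.78, 0.78), 0)
  expect_message(out <- lineBroadening(0.70, 0.78), "clamped")
  expect_equal(out, 0)
  expect_equal(lineBroadening(1.40, 0.78), 0.62)
})

test_that("the published calibration evaluates verbatim, with an optional floor", {
  pub <- publishedCalibration()
  expect_identical(correctionFactor(pub, 0), 0.9984)
  expect_equal(correctionFactor(pub, 1.0), 1.5654)
  expect_identical(correctionFactor(pub, 0, floor_factor_at_one = TRUE), 1)
  expect_error(correctionFactor(pub, -0.1), class = "cpmgInputError")
  # strictly increasing in the broadening for positive slope
  x <- seq(0, 3, by = 0.1)
  expect_true(all(diff(correctionFactor(pub, x)) > 0))
})

test_that("signal-loss factors are area quotients", {
  expect_equal(round(signalLossFactor(5.062, 1.709), 3), 2.962)
  expect_equal(round(signalLossFactor(0.636, 0.255), 3), 2.494)
  expect_equal(signalLossFactor(3.3, 3.3), 1)
  expect_error(signalLossFactor(0, 1), class = "cpmgInputError")
})

test_that("calibration fitting recovers exact lines to machine precision", {
  x <- c(0, 0.1, 0.25, 0.62, 0.9, 1.4)
  exact <- fitCalibration(data.frame(L_sMb_Hz = x,
                                     loss_factor = 0.567 * x + 0.9984))
  expect_lt(abs(coef(exact)[["slope_per_Hz"]] - 0.567) / 0.567, 1e-9)
  expect_lt(abs(coef(exact)[["intercept"]] - 0.9984) / 0.9984, 1e-9)
  expect_equal(fitR2(exact), 1)

  two <- fitCalibration(data.frame(L_sMb_Hz = c(0, 1, 0.5),
                                   loss_factor = c(1, 2, 1.5)))
  expect_equal(unname(coef(two)), c(1, 1))

  expect_error(fitCalibration(data.frame(L_sMb_Hz = c(1, 1, 1),
                                         loss_factor = c(1, 2, 3))),
               class = "cpmgFitError")
  expect_error(fitCalibration(data.frame(L_sMb_Hz = c(0, 1),
                                         loss_factor = c(1, 2))),
               class = "cpmgInputError")
})

test_that("noisy titration pairs recover the generating slope within 3 standard errors", {
  set.seed(42)
  x <- seq(0, 0.9, length.out = 14)
  y <- 0.567 * x + 0.9984 + rnorm(14, sd = 0.02)
  fit <- fitCalibration(data.frame(L_sMb_Hz = x, loss_factor = y))
  b <- coef(fit)[["slope_per_Hz"]]
  # standard OLS slope SE computed from first principles as the oracle
  yhat <- b * x + coef(fit)[["intercept"]]
  se <- sqrt(sum((y - yhat)^2) / 12) / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(b - 0.567), 3 * se)
})

test_that("shim offsets common to all signals cancel exactly in the factors", {
  lib <- readSignalLibrary()
  base <- correctSample(
    list(peakMeasurement("TSP", 1.50, 1), peakMeasurement("glucose", 1.10, 1)),
    shim_ref = peakMeasurement("formate", 0.80, 1),
    library = lib, free_concs = c(TSP = 4.45, glucose = 5.0))
  for (delta in c(0.05, 0.37, 1.0)) {
    shifted <- correctSample(
      list(peakMeasurement("TSP", 1.50 + delta, 1),
           peakMeasurement("glucose", 1.10 + delta, 1)),
      shim_ref = peakMeasurement("formate", 0.80 + delta, 1),
      library = lib, free_concs = c(TSP = 4.45, glucose = 5.0))
    expect_lt(max(abs(shifted$C_b - base$C_b)), 1e-9)
    expect_lt(max(abs(shifted$L_sMb_Hz - base$L_sMb_Hz)), 1e-9)
    expect_lt(max(abs(shifted$total_conc_mM - base$total_conc_mM)), 1e-9)
  }
})

test_that("correctSample is permutation-invariant, handles empty input, and reports missing metabolites", {
  lib <- readSignalLibrary()
  shim <- peakMeasurement("formate", 0.80, 1)
  ms <- list(peakMeasurement("TSP", 1.50, 1),
             peakMeasurement("glucose", 1.30, 2),
             peakMeasurement("alanine", 1.05, 3))
  fc <- c(TSP = 4.45, glucose = 5, alanine = 0.25)
  a <- correctSample(ms, shim, lib, free_concs = fc)
  b <- correctSample(rev(ms), shim, lib, free_concs = fc)
  expect_equal(a[order(a$metabolite), ], b[order(b$metabolite), ],
               ignore_attr = TRUE)

  expect_equal(nrow(correctSample(list(), shim, lib)), 0L)

  err <- expect_error(
    correctSample(list(peakMeasurement("unobtainium", 1, 1)), shim, lib),
    class = "cpmgLookupError")
  expect_match(conditionMessage(err), "unobtainium")
})

test_that("when every linewidth sits at its library optimum all factors equal the intercept", {
  lib <- readSignalLibrary()
  ms <- list(peakMeasurement("TSP", 0.78, 1),
             peakMeasurement("glucose", 0.92, 1))
  res <- suppressMessages(correctSample(
    ms, peakMeasurement("formate", 0.70, 1), lib,
    free_concs = c(TSP = 2, glucose = 3)))
  expect_equal(res$S_c_Hz, c(0, 0))
  expect_equal(res$C_b, c(0.9984, 0.9984))
  expect_equal(res$total_conc_mM, c(2, 3) * 0.9984)
})

test_that("calibration models serialize and restore", {
  m <- calibrationModel(0.61, 1.001, 0.987, "fitted")
  f <- tempfile(fileext = ".json")
  writeCalibration(m, f)
  r <- readCalibration(f)
  expect_equal(coef(r), coef(m))
  expect_equal(fitR2(r), 0.987)
  expect_identical(r@provenance, "fitted")
  # the published model round-trips its NA fit_r2
  f2 <- tempfile(fileext = ".json")
  writeCalibration(publishedCalibration(), f2)
  expect_true(is.na(fitR2(readCalibration(f2))))
})

test_that("report rounding follows the linewidth/factor conventions", {
  df <- data.frame(L_sM_Hz = 1.23456, C_b = 1.23456, total_conc_mM = 1.23456)
  out <- reportRounding(df)
  expect_equal(out$L_sM_Hz, 1.23)
  expect_equal(out$C_b, 1.235)
  expect_equal(out$total_conc_mM, 1.235)
})
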