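test_that("two-column text parses, resorts ascending axes, and fills default metadata", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("8.40\t0.0", "8.39\t1.0", "8.38\t0.0"), f)
  s <- readSpectrum(f)
  expect_s4_class(s, "Spectrum1D")
  expect_identical(chemicalShift(s), c(8.40, 8.39, 8.38))
  expect_identical(intensity(s), c(0, 1, 0))
  expect_equal(hzPerPpm(s), 600)  # default metadata
  expect_equal(acquisition(s)@total_echo_time_s, 0.08)

  # ascending file gives the identical spectrum after the re-sort
  f2 <- tempfile(fileext = ".txt")
  writeLines(c("8.38,0.0", "8.39,1.0", "8.40,0.0"), f2)
  s2 <- readSpectrum(f2)
  expect_identical(chemicalShift(s2), chemicalShift(s))
  expect_identical(intensity(s2), intensity(s))

  # header metadata is honored when present
  f3 <- tempfile(fileext = ".txt")
  writeLines(c("# spectrometer_frequency_MHz: 500", "1.0\t0", "0.9\t1"), f3)
  expect_equal(hzPerPpm(readSpectrum(f3)), 500)
})

test_that("format errors name the offending line; short files are rejected", {
  f <- tempfile()
  writeLines(c("8.40\t0.0", "not-a-number\tx", "8.38\t0.0"), f)
  err <- expect_error(readSpectrum(f), class = "cpmgFormatError")
  expect_match(conditionMessage(err), "line 2")
  f2 <- tempfile()
  writeLines("8.40\t0.0", f2)
  expect_error(readSpectrum(f2), class = "cpmgInputError")
  expect_error(readSpectrum(tempfile()), class = "cpmgInputError")
})

test_that("internal_record round trip is bit-exact including metadata", {
  acq <- acquisitionParams(spectrometer_frequency_MHz = 600.25,
                           temperature_K = 310)
  ppm <- seq(9, 0, length.out = 257) + 1e-9 * sin(1:257)
  set.seed(7)
  s <- spectrum1D(ppm, rnorm(257), acquisition = acq, label = "round trip")
  f <- tempfile()
  writeSpectrum(s, f, "internal_record")
  r <- readSpectrum(f, "internal_record")
  expect_identical(chemicalShift(r), chemicalShift(s))
  expect_identical(intensity(r), intensity(s))
  expect_equal(acquisition(r), acquisition(s))
  expect_identical(specLabel(r), specLabel(s))

  # two_column_text is documented lossy: metadata reverts to defaults
  f2 <- tempfile()
  writeSpectrum(s, f2, "two_column_text")
  r2 <- readSpectrum(f2, "two_column_text")
  expect_equal(hzPerPpm(r2), 600)
  expect_identical(chemicalShift(r2), chemicalShift(s))

  # minimal 2-point spectrum writes a valid 2-line data file
  s3 <- spectrum1D(c(1, 0), c(0, 0))
  f3 <- tempfile()
  writeSpectrum(s3, f3, "two_column_text")
  expect_length(readLines(f3), 2L)
})

test_that("extractRegion uses closed windows and preserves metadata", {
  grid <- (1000:0) / 100  # 10 .. 0 ppm, 1001 uniform points
  s <- spectrum1D(grid, seq_along(grid), label = "grid")
  sub <- extractRegion(s, 4.0, 3.0)
  expect_equal(length(chemicalShift(sub)),
               sum(grid >= 3 & grid <= 4))  # closed interval: 101 points
  expect_equal(length(chemicalShift(sub)), 101L)
  expect_identical(specLabel(sub), "grid")

  # identity on the full axis, idempotence on a window
  full <- extractRegion(s, 10, 0)
  expect_identical(chemicalShift(full), chemicalShift(s))
  expect_identical(chemicalShift(extractRegion(sub, 4.0, 3.0)),
                   chemicalShift(sub))

  expect_error(extractRegion(s, 3.0, 4.0), class = "cpmgInputError")
  expect_error(extractRegion(s, 20, 15), class = "cpmgInputError")
  # a window holding a single grid point violates the length-2 invariant
  expect_error(extractRegion(s, 5.001, 4.999), class = "cpmgInputError")
})

test_that("hzPerPpm equals the spectrometer frequency", {
  for (mhz in c(600, 600.25, 1)) {
    s <- spectrum1D(c(1, 0), c(0, 0),
                    acquisitionParams(spectrometer_frequency_MHz = mhz))
    expect_equal(hzPerPpm(s), mhz)
    expect_gt(hzPerPpm(s), 0)
  }
})

test_that("acquisition validity enforces echo-train timing consistency", {
  expect_error(acquisitionParams(total_echo_time_s = 0.08,
                                 echo_spacing_s = 3e-4, n_echoes = 64L),
               "disagrees")
  # the 80 ms total vs 300 us x 128 loops is accepted (within 10%)
  expect_s4_class(acquisitionParams(), "AcquisitionParams")
  expect_error(acquisitionParams(spectrometer_frequency_MHz = -1))
  expect_error(spectrum1D(c(1, 1), c(0, 0)))  # non-monotone axis
})
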