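#' @include fixtures.R
NULL

#' Measure one signal in a spectrum
#'
#' Extracts a window around the signal, baseline-corrects it, and measures
#' linewidth and area either by Lorentzian deconvolution (default; the
#' area is the fitted component's total area, insensitive to window
#' truncation) or by direct half-height analysis with trapezoidal
#' integration.
#'
#' @param spectrum a [Spectrum1D-class].
#' @param center_ppm approximate signal position.
#' @param signal_id identifier for the result.
#' @param method \code{"deconvolved"} or \code{"direct"}.
#' @param halfwidth_ppm half-width of the analysis window (default 0.04
#'   ppm).
#' @param baseline_order polynomial baseline order (default 1).
#' @param fwhm_guess_Hz initial linewidth guess for the fit (default 1).
#' @return A [PeakMeasurement-class].
#' @export
measureSignal <- function(spectrum, center_ppm, signal_id = "peak",
                          method = c("deconvolved", "direct"),
                          halfwidth_ppm = 0.04, baseline_order = 1L,
                          fwhm_guess_Hz = 1) {
  method <- match.arg(method)
  region <- extractRegion(spectrum, center_ppm + halfwidth_ppm,
                          center_ppm - halfwidth_ppm)
  region <- baselineCorrect(region, baseline_order)
  if (method == "direct")
    return(measureFwhmDirect(region, center_ppm, signal_id = signal_id))
  apex <- max(region@intensity)
  guess <- lorentzian(center_ppm, fwhm_guess_Hz,
                      max(apex * pi * fwhm_guess_Hz / 2, 1e-9))
  comps <- deconvolve(region, list(guess))
  ## single-line window: the fitted component nearest the requested center
  ctrs <- vapply(comps, function(cc) cc@center_ppm, numeric(1L))
  cc <- comps[[which.min(abs(ctrs - center_ppm))]]
  peakMeasurement(signal_id, cc@fwhm_Hz, cc@area, method = "deconvolved",
                  fit_residual_rms = attr(comps, "fit_residual_rms"))
}

## Cluster target positions so signals whose analysis windows would overlap
## are deconvolved jointly (crowded-region handling); returns a list of
## integer index vectors.
.groupTargets <- function(ppms, halfwidth_ppm) {
  ord <- order(ppms)
  groups <- list(ord[1L])
  if (length(ord) > 1L) for (i in ord[-1L]) {
    last <- groups[[length(groups)]]
    if (ppms[i] - ppms[last[length(last)]] < 3 * halfwidth_ppm)
      groups[[length(groups)]] <- c(last, i)
    else groups <- c(groups, i)
  }
  groups
}

## Jointly deconvolve a group of signals sharing one region; returns a list
## of PeakMeasurement in the group's order.
.measureGroup <- function(spectrum, ppms, ids, halfwidth_ppm = 0.04,
                          baseline_order = 1L, fwhm_guess_Hz = 1) {
  region <- extractRegion(spectrum, max(ppms) + halfwidth_ppm,
                          min(ppms) - halfwidth_ppm)
  region <- baselineCorrect(region, baseline_order)
  apex <- max(region@intensity)
  init <- lapply(ppms, function(p)
    lorentzian(p, fwhm_guess_Hz, max(apex * pi * fwhm_guess_Hz / 2, 1e-9)))
  comps <- deconvolve(region, init)
  rms <- attr(comps, "fit_residual_rms")
  ctrs <- vapply(comps, function(cc) cc@center_ppm, numeric(1L))
  lapply(seq_along(ppms), function(i) {
    cc <- comps[[which.min(abs(ctrs - ppms[i]))]]
    peakMeasurement(ids[i], cc@fwhm_Hz, cc@area, method = "deconvolved",
                    fit_residual_rms = rms)
  })
}

## Measure every target (plus the standard) with crowded-region grouping;
## returns a named list of PeakMeasurement keyed by metabolite.
.measureTargets <- function(spectrum, targets, halfwidth_ppm = 0.04) {
  groups <- .groupTargets(targets$ppm, halfwidth_ppm)
  out <- vector("list", nrow(targets))
  for (g in groups) {
    ms <- if (length(g) == 1L)
      list(measureSignal(spectrum, targets$ppm[g],
                         signal_id = targets$metabolite[g],
                         halfwidth_ppm = halfwidth_ppm))
    else .measureGroup(spectrum, targets$ppm[g], targets$metabolite[g],
                       halfwidth_ppm)
    out[g] <- ms
  }
  names(out) <- targets$metabolite
  out
}

#' Measure optimal (protein-free) linewidths into a signal library
#'
#' Runs [measureSignal()] on a protein-free, well-shimmed reference
#' spectrum for every target signal plus the shim reference, and returns a
#' reference-signal library data.frame suitable for [correctSample()].
#'
#' @param reference_spectrum protein-free [Spectrum1D-class].
#' @param targets data.frame with columns \code{metabolite, ppm, protons}.
#' @param std an [InternalStandard-class] (appended as the shim/quant
#'   reference row).
#' @return data.frame with the [readSignalLibrary()] columns.
#' @export
measureOptimalLinewidths <- function(reference_spectrum, targets,
                                     std = internalStandard()) {
  meas <- .measureTargets(reference_spectrum, targets)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    data.frame(metabolite = targets$metabolite[i], signal_ppm = targets$ppm[i],
               multiplicity = "s", protons = as.integer(targets$protons[i]),
               optimal_fwhm_Hz = fwhmHz(meas[[i]]), stringsAsFactors = FALSE)
  })
  ms <- measureSignal(reference_spectrum, std@signal_ppm, signal_id = std@name)
  rows[[length(rows) + 1L]] <- data.frame(
    metabolite = std@name, signal_ppm = std@signal_ppm, multiplicity = "s",
    protons = std@protons, optimal_fwhm_Hz = fwhmHz(ms),
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Fit the loss-factor calibration from a titration series
#'
#' For every spectrum of a protein titration this measures the shim
#' reference and the titrated compound's signal, computes shim-corrected
#' line broadenings against the zero-protein level, takes loss factors as
#' zero-protein area over level area, and fits the calibration line by
#' ordinary least squares.
#'
#' The first spectrum in the list must be the zero-protein level; it
#' supplies the optimal linewidths \eqn{L_{oF}} and \eqn{L_{oM}} and the
#' maximum area.
#'
#' @param spectra list of [Spectrum1D-class], zero-protein level first.
#' @param signal_ppm position of the titrated compound's signal (default
#'   0 ppm, TSP).
#' @param std_ppm position of the shim-reference signal (default 8.44 ppm,
#'   formate).
#' @param signal_id,std_id identifiers used in measurements.
#' @return list with elements \code{model} (a [CalibrationModel-class]),
#'   \code{pairs} (data.frame of \code{L_sMb_Hz}, \code{loss_factor} per
#'   level) and \code{optimal} (named c(L_oF, L_oM), Hz).
#' @export
calibrateFromTitration <- function(spectra, signal_ppm = 0.0, std_ppm = 8.44,
                                   signal_id = "TSP", std_id = "formate") {
  if (length(spectra) < 3L)
    stopInput("at least 3 titration spectra are required")
  meas <- lapply(spectra, function(s) list(
    std = measureSignal(s, std_ppm, signal_id = std_id),
    sig = measureSignal(s, signal_ppm, signal_id = signal_id)))
  L_oF <- fwhmHz(meas[[1L]]$std)
  L_oM <- fwhmHz(meas[[1L]]$sig)
  area0 <- peakArea(meas[[1L]]$sig) / peakArea(meas[[1L]]$std)
  pairs <- do.call(rbind, lapply(meas, function(m) {
    S_c <- shimCorrection(fwhmHz(m$std), L_oF)
    L_sMc <- applyShim(fwhmHz(m$sig), S_c)
    L_sMb <- suppressMessages(lineBroadening(L_sMc, L_oM))
    rel_area <- peakArea(m$sig) / peakArea(m$std)
    data.frame(L_sMb_Hz = L_sMb, loss_factor = signalLossFactor(area0, rel_area))
  }))
  list(model = fitCalibration(pairs), pairs = pairs,
       optimal = c(L_oF = L_oF, L_oM = L_oM))
}

#' Quantify a sample spectrum: free and total concentrations
#'
#' The composed pipeline on one spectrum: measures the internal-standard
#' signal (shim reference and concentration reference in one), measures
#' each target signal, converts areas to free concentrations via
#' [concentrationFromAreas()], and applies the linewidth correction chain
#' via [correctSample()].
#'
#' A warning is issued when the spectrum's acquisition temperature differs
#' from 298 K, since library linewidths measured at another temperature
#' may not transfer.
#'
#' @param spectrum a [Spectrum1D-class].
#' @param targets data.frame with columns \code{metabolite, ppm, protons}.
#' @param library reference-signal library (see [readSignalLibrary()]).
#' @param model a [CalibrationModel-class].
#' @param std an [InternalStandard-class] of known concentration.
#' @param floor_factor_at_one passed to [correctionFactor()].
#' @return The [correctSample()] data.frame with free and total
#'   concentrations filled in.
#' @export
quantifySpectrum <- function(spectrum, targets, library,
                             model = publishedCalibration(),
                             std = internalStandard(),
                             floor_factor_at_one = FALSE) {
  if (abs(spectrum@acquisition@temperature_K - 298) > 0.5)
    warning(sprintf(
      "spectrum acquired at %.0f K; library linewidths are referenced at 298 K and may not transfer",
      spectrum@acquisition@temperature_K), call. = FALSE)
  std_m <- measureSignal(spectrum, std@signal_ppm, signal_id = std@name)
  meas <- .measureTargets(spectrum, targets)
  free <- vapply(seq_along(meas), function(i)
    concentrationFromAreas(peakArea(meas[[i]]),
                           as.integer(targets$protons[i]), std,
                           peakArea(std_m)), numeric(1L))
  names(free) <- targets$metabolite
  correctSample(meas, shim_ref = std_m, library = library, model = model,
                free_concs = free, shim_metabolite = std@name,
                floor_factor_at_one = floor_factor_at_one)
}
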