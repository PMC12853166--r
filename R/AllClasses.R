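## Condition constructors: every package error carries a subclass so callers
## (and the command-line wrapper) can map failure modes to distinct exit codes.

cpmgError <- function(message, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "cpmgError", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

stopInput    <- function(msg, ...) stop(cpmgError(msg, "cpmgInputError", ...))
stopFormat   <- function(msg, ...) stop(cpmgError(msg, "cpmgFormatError", ...))
stopFit      <- function(msg, ...) stop(cpmgError(msg, "cpmgFitError", ...))
stopPipeline <- function(msg, ...) stop(cpmgError(msg, "cpmgPipelineError", ...))
stopConfig   <- function(msg, ...) stop(cpmgError(msg, "cpmgConfigError", ...))

#' Acquisition metadata for a processed 1D spectrum
#'
#' Holds the spectrometer settings needed to interpret a processed 1D
#' \eqn{^1}H CPMG spectrum: the spectrometer frequency (which fixes the
#' Hz-per-ppm scale), temperature, the CPMG echo-train timing, and the
#' exponential line broadening applied during processing.
#'
#' The CPMG echo train acts as a \eqn{T_2} relaxation filter: its total
#' duration (\code{total_echo_time_s}) controls how strongly fast-relaxing
#' (protein-bound) magnetization is attenuated. Validity requires
#' \code{total_echo_time_s} to agree with
#' \code{2 * echo_spacing_s * n_echoes} within 10\% when all three are set,
#' since echo trains are commonly quoted with rounded totals.
#'
#' @slot spectrometer_frequency_MHz positive number; 1 ppm spans this many Hz.
#' @slot temperature_K positive number, sample temperature.
#' @slot total_echo_time_s nonnegative number, CPMG echo-train duration.
#' @slot echo_spacing_s nonnegative number, half-echo spacing tau.
#' @slot n_echoes nonnegative integer, number of echo loops.
#' @slot relaxation_delay_s nonnegative number, inter-scan relaxation delay.
#' @slot processing_line_broadening_Hz nonnegative number, exponential
#'   apodization applied during processing.
#' @seealso [acquisitionParams()], [Spectrum1D-class]
#' @exportClass AcquisitionParams
setClass("AcquisitionParams",
  representation(
    spectrometer_frequency_MHz   = "numeric",
    temperature_K                = "numeric",
    total_echo_time_s            = "numeric",
    echo_spacing_s               = "numeric",
    n_echoes                     = "integer",
    relaxation_delay_s           = "numeric",
    processing_line_broadening_Hz = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@spectrometer_frequency_MHz) ||
      object@spectrometer_frequency_MHz <= 0)
    msg <- c(msg, "spectrometer_frequency_MHz must be a single positive number")
  if (!one(object@temperature_K) || object@temperature_K <= 0)
    msg <- c(msg, "temperature_K must be a single positive number")
  for (s in c("total_echo_time_s", "echo_spacing_s", "relaxation_delay_s",
              "processing_line_broadening_Hz")) {
    v <- slot(object, s)
    if (!one(v) || v < 0) msg <- c(msg, paste(s, "must be a single nonnegative number"))
  }
  if (length(object@n_echoes) != 1L || is.na(object@n_echoes) || object@n_echoes < 0L)
    msg <- c(msg, "n_echoes must be a single nonnegative integer")
  if (length(msg) == 0L &&
      object@total_echo_time_s > 0 && object@echo_spacing_s > 0 &&
      object@n_echoes > 0L) {
    expect <- 2 * object@echo_spacing_s * as.numeric(object@n_echoes)
    if (abs(object@total_echo_time_s - expect) > 0.1 * object@total_echo_time_s)
      msg <- c(msg, sprintf(
        "total_echo_time_s (%.4g) disagrees with 2 * echo_spacing_s * n_echoes (%.4g) by more than 10%%",
        object@total_echo_time_s, expect))
  }
  if (length(msg)) msg else TRUE
})

#' Construct acquisition metadata
#'
#' Defaults reproduce a typical 600 MHz CPMG acquisition at 298 K with an
#' 80 ms echo train (300 us half-echo spacing, 128 loops) and 0.3 Hz
#' processing line broadening; these defaults are also what the spectrum
#' readers assume when a file carries no metadata.
#'
#' @param spectrometer_frequency_MHz spectrometer frequency in MHz.
#' @param temperature_K sample temperature in kelvin.
#' @param total_echo_time_s total CPMG echo-train duration in seconds.
#' @param echo_spacing_s half-echo spacing in seconds.
#' @param n_echoes number of echo loops.
#' @param relaxation_delay_s inter-scan relaxation delay in seconds.
#' @param processing_line_broadening_Hz exponential apodization in Hz.
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams()
#' acquisitionParams(spectrometer_frequency_MHz = 500)
#' @export
acquisitionParams <- function(spectrometer_frequency_MHz = 600,
                              temperature_K = 298,
                              total_echo_time_s = 0.08,
                              echo_spacing_s = 3e-4,
                              n_echoes = 128L,
                              relaxation_delay_s = 4,
                              processing_line_broadening_Hz = 0.3) {
  new("AcquisitionParams",
      spectrometer_frequency_MHz = as.numeric(spectrometer_frequency_MHz),
      temperature_K = as.numeric(temperature_K),
      total_echo_time_s = as.numeric(total_echo_time_s),
      echo_spacing_s = as.numeric(echo_spacing_s),
      n_echoes = as.integer(n_echoes),
      relaxation_delay_s = as.numeric(relaxation_delay_s),
      processing_line_broadening_Hz = as.numeric(processing_line_broadening_Hz))
}

#' Processed 1D real NMR spectrum
#'
#' A chemical-shift axis in ppm (stored high-to-low, the NMR display
#' convention), matching intensities in arbitrary units, acquisition
#' metadata, and a free-text provenance label. All linewidth and area
#' measurements in the package act on objects of this class.
#'
#' @slot ppm strictly decreasing numeric vector of chemical shifts (ppm).
#' @slot intensity numeric vector, same length as \code{ppm}.
#' @slot acquisition an [AcquisitionParams-class] object.
#' @slot label single character string, free-text provenance.
#' @seealso [spectrum1D()], [readSpectrum()], [extractRegion()]
#' @exportClass Spectrum1D
setClass("Spectrum1D",
  representation(
    ppm = "numeric",
    intensity = "numeric",
    acquisition = "AcquisitionParams",
    label = "character"
  )
)

setValidity("Spectrum1D", function(object) {
  msg <- character()
  n <- length(object@ppm)
  if (n < 2L) msg <- c(msg, "spectrum must have at least 2 points")
  if (length(object@intensity) != n)
    msg <- c(msg, "ppm and intensity must have equal length")
  if (anyNA(object@ppm) || any(!is.finite(object@ppm)))
    msg <- c(msg, "ppm axis must be finite")
  if (n >= 2L && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing (high to low ppm)")
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a 1D spectrum
#'
#' If the axis is supplied in ascending ppm order it is reversed (together
#' with the intensities) to the decreasing-display convention.
#'
#' @param ppm numeric chemical-shift axis in ppm, strictly monotone.
#' @param intensity numeric intensities, same length as \code{ppm}.
#' @param acquisition an [AcquisitionParams-class]; defaults to
#'   [acquisitionParams()].
#' @param label free-text provenance string.
#' @return A [Spectrum1D-class] object.
#' @examples
#' s <- spectrum1D(c(8.40, 8.39, 8.38), c(0, 1, 0))
#' hzPerPpm(s)
#' @export
spectrum1D <- function(ppm, intensity, acquisition = acquisitionParams(),
                       label = "") {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) >= 2L && all(diff(ppm) > 0)) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  new("Spectrum1D", ppm = ppm, intensity = intensity,
      acquisition = acquisition, label = as.character(label)[1L])
}

#' Single Lorentzian line component
#'
#' The natural NMR lineshape: a Lorentzian with FWHM \eqn{= 1/(\pi T_2)}.
#' Areas are in intensity-times-Hz units, consistent with
#' [integrateSignal()].
#'
#' @slot center_ppm peak position in ppm.
#' @slot fwhm_Hz positive full width at half maximum in Hz.
#' @slot area positive integrated area (intensity x Hz).
#' @seealso [lorentzian()], [deconvolve()]
#' @exportClass LorentzianComponent
setClass("LorentzianComponent",
  representation(center_ppm = "numeric", fwhm_Hz = "numeric", area = "numeric"))

setValidity("LorentzianComponent", function(object) {
  msg <- character()
  if (length(object@center_ppm) != 1L || !is.finite(object@center_ppm))
    msg <- c(msg, "center_ppm must be a single finite number")
  if (length(object@fwhm_Hz) != 1L || !is.finite(object@fwhm_Hz) ||
      object@fwhm_Hz <= 0)
    msg <- c(msg, "fwhm_Hz must be a single positive number")
  if (length(object@area) != 1L || !is.finite(object@area) || object@area <= 0)
    msg <- c(msg, "area must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname LorentzianComponent-class
#' @param center_ppm peak position in ppm.
#' @param fwhm_Hz full width at half maximum in Hz.
#' @param area integrated area (intensity x Hz).
#' @return A [LorentzianComponent-class] object.
#' @export
lorentzian <- function(center_ppm, fwhm_Hz, area) {
  new("LorentzianComponent", center_ppm = as.numeric(center_ppm),
      fwhm_Hz = as.numeric(fwhm_Hz), area = as.numeric(area))
}

#' A measured peak: linewidth and area for one signal
#'
#' Result of either direct half-height analysis ([measureFwhmDirect()]) or
#' Lorentzian deconvolution. Direct measurements carry a zero fit residual
#' by definition.
#'
#' @slot signal_id character, identifies the signal (typically the
#'   metabolite name).
#' @slot fwhm_Hz positive linewidth in Hz.
#' @slot area nonnegative integrated area.
#' @slot method \code{"direct"} or \code{"deconvolved"}.
#' @slot fit_residual_rms nonnegative; 0 for direct measurements.
#' @exportClass PeakMeasurement
setClass("PeakMeasurement",
  representation(signal_id = "character", fwhm_Hz = "numeric",
                 area = "numeric", method = "character",
                 fit_residual_rms = "numeric"))

setValidity("PeakMeasurement", function(object) {
  msg <- character()
  if (length(object@fwhm_Hz) != 1L || !is.finite(object@fwhm_Hz) ||
      object@fwhm_Hz <= 0)
    msg <- c(msg, "fwhm_Hz must be a single positive number")
  if (length(object@area) != 1L || !is.finite(object@area) || object@area < 0)
    msg <- c(msg, "area must be a single nonnegative number")
  if (!object@method %in% c("direct", "deconvolved"))
    msg <- c(msg, "method must be 'direct' or 'deconvolved'")
  if (length(object@fit_residual_rms) != 1L || object@fit_residual_rms < 0)
    msg <- c(msg, "fit_residual_rms must be a single nonnegative number")
  if (identical(object@method, "direct") && object@fit_residual_rms != 0)
    msg <- c(msg, "direct measurements must have fit_residual_rms = 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PeakMeasurement-class
#' @param signal_id signal identifier.
#' @param fwhm_Hz linewidth in Hz.
#' @param area integrated area.
#' @param method \code{"direct"} or \code{"deconvolved"}.
#' @param fit_residual_rms root-mean-square fit residual (0 for direct).
#' @return A [PeakMeasurement-class] object.
#' @export
peakMeasurement <- function(signal_id, fwhm_Hz, area,
                            method = c("direct", "deconvolved"),
                            fit_residual_rms = 0) {
  method <- match.arg(method)
  new("PeakMeasurement", signal_id = as.character(signal_id)[1L],
      fwhm_Hz = as.numeric(fwhm_Hz), area = as.numeric(area),
      method = method, fit_residual_rms = as.numeric(fit_residual_rms))
}

#' Linear calibration between signal-loss factor and line broadening
#'
#' The correction factor is \eqn{C_b = slope \cdot L_{sMb} + intercept},
#' where \eqn{L_{sMb}} is the protein-induced line broadening in Hz. The
#' published model has slope 0.567 per Hz and intercept 0.9984; user-fitted
#' models from titration data are interchangeable.
#'
#' @slot slope_per_Hz positive slope in 1/Hz.
#' @slot intercept dimensionless intercept (loss factor at zero broadening).
#' @slot fit_r2 coefficient of determination of the fit, or \code{NA} for
#'   the published model.
#' @slot provenance character, e.g. \code{"published"} or \code{"fitted"}.
#' @seealso [publishedCalibration()], [fitCalibration()],
#'   [correctionFactor()]
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  representation(slope_per_Hz = "numeric", intercept = "numeric",
                 fit_r2 = "numeric", provenance = "character"))

setValidity("CalibrationModel", function(object) {
  msg <- character()
  if (length(object@slope_per_Hz) != 1L || !is.finite(object@slope_per_Hz) ||
      object@slope_per_Hz <= 0)
    msg <- c(msg, "slope_per_Hz must be a single positive number (loss grows with broadening)")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (length(object@fit_r2) != 1L ||
      (!is.na(object@fit_r2) && (object@fit_r2 < 0 || object@fit_r2 > 1)))
    msg <- c(msg, "fit_r2 must be in [0, 1] or NA")
  if (length(msg)) msg else TRUE
})

#' @rdname CalibrationModel-class
#' @param slope_per_Hz slope in 1/Hz.
#' @param intercept dimensionless intercept.
#' @param fit_r2 fit R-squared or \code{NA}.
#' @param provenance provenance tag.
#' @return A [CalibrationModel-class] object.
#' @export
calibrationModel <- function(slope_per_Hz, intercept, fit_r2 = NA_real_,
                             provenance = "user") {
  new("CalibrationModel", slope_per_Hz = as.numeric(slope_per_Hz),
      intercept = as.numeric(intercept), fit_r2 = as.numeric(fit_r2),
      provenance = as.character(provenance)[1L])
}

#' Internal concentration reference standard
#'
#' Defaults to formate (formic acid), which does not bind to protein and is
#' therefore also used as the shim reference: one proton, singlet near
#' 8.44 ppm.
#'
#' @slot name standard name.
#' @slot concentration_mM positive known concentration in mM.
#' @slot protons positive integer, protons contributing to the signal.
#' @slot signal_ppm chemical shift of the reference signal.
#' @seealso [concentrationFromAreas()]
#' @exportClass InternalStandard
setClass("InternalStandard",
  representation(name = "character", concentration_mM = "numeric",
                 protons = "integer", signal_ppm = "numeric"))

setValidity("InternalStandard", function(object) {
  msg <- character()
  if (length(object@concentration_mM) != 1L || !is.finite(object@concentration_mM) ||
      object@concentration_mM <= 0)
    msg <- c(msg, "concentration_mM must be a single positive number")
  if (length(object@protons) != 1L || is.na(object@protons) || object@protons < 1L)
    msg <- c(msg, "protons must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @rdname InternalStandard-class
#' @param name standard name.
#' @param concentration_mM known concentration in mM.
#' @param protons protons contributing to the signal.
#' @param signal_ppm chemical shift of the signal in ppm.
#' @return An [InternalStandard-class] object.
#' @export
internalStandard <- function(name = "formate", concentration_mM = 6.0,
                             protons = 1L, signal_ppm = 8.44) {
  new("InternalStandard", name = as.character(name)[1L],
      concentration_mM = as.numeric(concentration_mM),
      protons = as.integer(protons), signal_ppm = as.numeric(signal_ppm))
}

#' Single-site protein binding model for a metabolite
#'
#' 1:1 binding with dissociation constant \code{Kd_mM}; the free and bound
#' states have fixed linewidths, and under fast exchange the observed
#' signal is their population-weighted average. Bound linewidths exceed
#' free linewidths because protein-bound small molecules inherit the short
#' \eqn{T_2} of the protein.
#'
#' @slot Kd_mM positive dissociation constant in mM.
#' @slot fwhm_free_Hz positive linewidth of the free state in Hz.
#' @slot fwhm_bound_Hz linewidth of the bound state in Hz; must exceed
#'   \code{fwhm_free_Hz}.
#' @seealso [boundFraction()], [observedFwhm()]
#' @exportClass BindingModel
setClass("BindingModel",
  representation(Kd_mM = "numeric", fwhm_free_Hz = "numeric",
                 fwhm_bound_Hz = "numeric"))

setValidity("BindingModel", function(object) {
  msg <- character()
  if (length(object@Kd_mM) != 1L || !is.finite(object@Kd_mM) || object@Kd_mM <= 0)
    msg <- c(msg, "Kd_mM must be a single positive number")
  if (length(object@fwhm_free_Hz) != 1L || object@fwhm_free_Hz <= 0)
    msg <- c(msg, "fwhm_free_Hz must be positive")
  if (length(object@fwhm_bound_Hz) != 1L ||
      object@fwhm_bound_Hz <= object@fwhm_free_Hz)
    msg <- c(msg, "fwhm_bound_Hz must exceed fwhm_free_Hz")
  if (length(msg)) msg else TRUE
})

#' @rdname BindingModel-class
#' @param Kd_mM dissociation constant in mM.
#' @param fwhm_free_Hz free-state linewidth in Hz.
#' @param fwhm_bound_Hz bound-state linewidth in Hz.
#' @return A [BindingModel-class] object.
#' @export
bindingModel <- function(Kd_mM, fwhm_free_Hz, fwhm_bound_Hz) {
  new("BindingModel", Kd_mM = as.numeric(Kd_mM),
      fwhm_free_Hz = as.numeric(fwhm_free_Hz),
      fwhm_bound_Hz = as.numeric(fwhm_bound_Hz))
}

setClassUnion("BindingModelOrNULL", c("BindingModel", "NULL"))

#' Simulated metabolite description
#'
#' A metabolite of known total concentration with one or more singlet
#' signals and an optional protein-binding model. Non-binders render at
#' their free linewidth with no CPMG attenuation.
#'
#' @slot name metabolite name.
#' @slot total_conc_mM positive total (free + bound) concentration in mM.
#' @slot signals data.frame with columns \code{ppm} and \code{protons}.
#' @slot binding a [BindingModel-class] or \code{NULL} for a non-binder.
#' @slot fwhm_free_Hz linewidth used when \code{binding} is \code{NULL}
#'   (ignored otherwise; the binding model carries its own free linewidth).
#' @exportClass MetaboliteSpec
setClass("MetaboliteSpec",
  representation(name = "character", total_conc_mM = "numeric",
                 signals = "data.frame", binding = "BindingModelOrNULL",
                 fwhm_free_Hz = "numeric"))

setValidity("MetaboliteSpec", function(object) {
  msg <- character()
  if (length(object@total_conc_mM) != 1L || !is.finite(object@total_conc_mM) ||
      object@total_conc_mM <= 0)
    msg <- c(msg, "total_conc_mM must be a single positive number")
  if (nrow(object@signals) < 1L ||
      !all(c("ppm", "protons") %in% names(object@signals)))
    msg <- c(msg, "signals must be a data.frame with >= 1 row and columns ppm, protons")
  if (length(object@fwhm_free_Hz) != 1L || object@fwhm_free_Hz <= 0)
    msg <- c(msg, "fwhm_free_Hz must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname MetaboliteSpec-class
#' @param name metabolite name.
#' @param total_conc_mM total concentration in mM.
#' @param signals data.frame with columns \code{ppm}, \code{protons}.
#' @param binding optional [BindingModel-class].
#' @param fwhm_free_Hz linewidth for non-binders, Hz.
#' @return A [MetaboliteSpec-class] object.
#' @export
metaboliteSpec <- function(name, total_conc_mM, signals, binding = NULL,
                           fwhm_free_Hz = 0.78) {
  if (is.numeric(signals) && length(signals) == 2L)
    signals <- data.frame(ppm = signals[1L], protons = signals[2L])
  new("MetaboliteSpec", name = as.character(name)[1L],
      total_conc_mM = as.numeric(total_conc_mM),
      signals = as.data.frame(signals), binding = binding,
      fwhm_free_Hz = as.numeric(fwhm_free_Hz))
}

#' Full description of a simulated proteinaceous sample
#'
#' Everything [simulateSpectrum()] needs: the metabolite mixture, the
#' protein level, the internal standard, shim degradation, noise, baseline,
#' the effective CPMG echo time governing the loss model, and the random
#' seed. Protein molarity is \code{protein_g_per_L / protein_MW_g_per_mol}.
#'
#' @slot metabolites list of [MetaboliteSpec-class] objects.
#' @slot protein_g_per_L nonnegative protein concentration in g/L.
#' @slot protein_MW_g_per_mol protein molecular weight; default 66478
#'   (human serum albumin).
#' @slot internal_standard an [InternalStandard-class] (non-binding).
#' @slot internal_standard_fwhm_Hz protein-free linewidth of the standard.
#' @slot shim_extra_fwhm_Hz uniform additional broadening applied to every
#'   signal (shim degradation).
#' @slot noise_sd additive Gaussian noise standard deviation.
#' @slot baseline numeric(2): (slope per ppm, offset).
#' @slot effective_echo_time_s effective relaxation-filter duration used by
#'   the exponential loss model.
#' @slot seed integer random seed; recorded in generated spectrum labels.
#' @seealso [sampleSpec()], [simulateSpectrum()], [simulateTitration()]
#' @exportClass SampleSpec
setClass("SampleSpec",
  representation(metabolites = "list", protein_g_per_L = "numeric",
                 protein_MW_g_per_mol = "numeric",
                 internal_standard = "InternalStandard",
                 internal_standard_fwhm_Hz = "numeric",
                 shim_extra_fwhm_Hz = "numeric", noise_sd = "numeric",
                 baseline = "numeric", effective_echo_time_s = "numeric",
                 seed = "integer"))

setValidity("SampleSpec", function(object) {
  msg <- character()
  if (!all(vapply(object@metabolites, is, logical(1L), "MetaboliteSpec")))
    msg <- c(msg, "metabolites must all be MetaboliteSpec objects")
  if (object@protein_g_per_L < 0) msg <- c(msg, "protein_g_per_L must be >= 0")
  if (object@protein_MW_g_per_mol <= 0)
    msg <- c(msg, "protein_MW_g_per_mol must be positive")
  if (object@internal_standard_fwhm_Hz <= 0)
    msg <- c(msg, "internal_standard_fwhm_Hz must be positive")
  if (object@shim_extra_fwhm_Hz < 0) msg <- c(msg, "shim_extra_fwhm_Hz must be >= 0")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (length(object@baseline) != 2L) msg <- c(msg, "baseline must be numeric(2): (slope, offset)")
  if (object@effective_echo_time_s <= 0)
    msg <- c(msg, "effective_echo_time_s must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SampleSpec-class
#' @param metabolites list of [MetaboliteSpec-class] objects.
#' @param protein_g_per_L protein concentration in g/L.
#' @param protein_MW_g_per_mol protein molecular weight in g/mol.
#' @param internal_standard an [InternalStandard-class].
#' @param internal_standard_fwhm_Hz protein-free standard linewidth, Hz.
#' @param shim_extra_fwhm_Hz uniform shim broadening, Hz.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param baseline numeric(2): slope (per ppm) and offset.
#' @param effective_echo_time_s effective echo time in seconds. The default
#'   0.1805 s makes the small-broadening linearization of the loss model
#'   reproduce the published calibration slope (0.567/Hz); the physical
#'   80 ms echo train is available by passing \code{0.08}.
#' @param seed integer random seed.
#' @return A [SampleSpec-class] object.
#' @export
sampleSpec <- function(metabolites, protein_g_per_L = 0,
                       protein_MW_g_per_mol = 66478,
                       internal_standard = internalStandard(),
                       internal_standard_fwhm_Hz = 0.70,
                       shim_extra_fwhm_Hz = 0, noise_sd = 0,
                       baseline = c(0, 0), effective_echo_time_s = 0.1805,
                       seed = 1L) {
  if (is(metabolites, "MetaboliteSpec")) metabolites <- list(metabolites)
  new("SampleSpec", metabolites = metabolites,
      protein_g_per_L = as.numeric(protein_g_per_L),
      protein_MW_g_per_mol = as.numeric(protein_MW_g_per_mol),
      internal_standard = internal_standard,
      internal_standard_fwhm_Hz = as.numeric(internal_standard_fwhm_Hz),
      shim_extra_fwhm_Hz = as.numeric(shim_extra_fwhm_Hz),
      noise_sd = as.numeric(noise_sd), baseline = as.numeric(baseline),
      effective_echo_time_s = as.numeric(effective_echo_time_s),
      seed = as.integer(seed))
}

#' Bland-Altman agreement summary
#'
#' Pairwise differences between two methods: mean bias, its sample
#' standard deviation, and the 95\% limits of agreement at
#' \code{mean +/- 1.96 sd}. Per-pair (mean, difference) points are kept for
#' plotting.
#'
#' @slot n number of pairs.
#' @slot mean_diff mean of differences (a - b).
#' @slot sd_diff sample standard deviation of differences.
#' @slot loa_low,loa_high limits of agreement, mean +/- 1.96 sd.
#' @slot points data.frame with columns \code{mean} and \code{diff}.
#' @seealso [blandAltman()]
#' @exportClass BlandAltmanSummary
setClass("BlandAltmanSummary",
  representation(n = "integer", mean_diff = "numeric", sd_diff = "numeric",
                 loa_low = "numeric", loa_high = "numeric",
                 points = "data.frame"))

setValidity("BlandAltmanSummary", function(object) {
  msg <- character()
  tol <- 1e-8 * max(1, abs(object@mean_diff), object@sd_diff)
  if (abs(object@loa_low - (object@mean_diff - 1.96 * object@sd_diff)) > tol ||
      abs(object@loa_high - (object@mean_diff + 1.96 * object@sd_diff)) > tol)
    msg <- c(msg, "limits of agreement must equal mean_diff +/- 1.96 * sd_diff")
  if (object@loa_low > object@mean_diff || object@mean_diff > object@loa_high)
    msg <- c(msg, "mean_diff must lie between the limits of agreement")
  if (length(msg)) msg else TRUE
})
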