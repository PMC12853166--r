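#' @include AllClasses.R
NULL

#' Hz spanned by one ppm on a spectrum's axis
#'
#' By definition of the ppm scale, a shift of 1 ppm corresponds to a
#' frequency interval equal to the spectrometer frequency in MHz expressed
#' in Hz (600 MHz instrument: 1 ppm = 600 Hz). Used to convert linewidths
#' and integrals from the ppm axis to Hz.
#'
#' @param object a [Spectrum1D-class].
#' @return A positive number: Hz per ppm.
#' @examples
#' hzPerPpm(spectrum1D(c(1, 0), c(0, 0)))
#' @export
setGeneric("hzPerPpm", function(object) standardGeneric("hzPerPpm"))

#' Extract a closed ppm window from a spectrum
#'
#' @param object a [Spectrum1D-class].
#' @param ppm_high,ppm_low window bounds in ppm, \code{ppm_high > ppm_low};
#'   points with \code{ppm_low <= ppm <= ppm_high} are kept (closed
#'   interval, edge ties included).
#' @return A [Spectrum1D-class] restricted to the window, metadata
#'   preserved.
#' @export
setGeneric("extractRegion",
           function(object, ppm_high, ppm_low) standardGeneric("extractRegion"))

#' Write a spectrum to disk
#'
#' @param object a [Spectrum1D-class].
#' @param path output file path.
#' @param dialect \code{"internal_record"} (lossless, keeps metadata) or
#'   \code{"two_column_text"} (data only; metadata dropped).
#' @return Invisibly, \code{path}.
#' @seealso [readSpectrum()]
#' @export
setGeneric("writeSpectrum",
           function(object, path, dialect = c("internal_record", "two_column_text"))
             standardGeneric("writeSpectrum"))

## ---- accessors -------------------------------------------------------------

#' @describeIn Spectrum1D-class chemical-shift axis (ppm, decreasing).
#' @param object,x a \code{Spectrum1D}.
#' @export
setGeneric("chemicalShift", function(object) standardGeneric("chemicalShift"))

#' @describeIn Spectrum1D-class intensity vector.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @describeIn Spectrum1D-class acquisition metadata.
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))

#' @describeIn Spectrum1D-class provenance label.
#' @export
setGeneric("specLabel", function(object) standardGeneric("specLabel"))

#' @describeIn PeakMeasurement-class linewidth in Hz (also defined for
#'   \code{LorentzianComponent}).
#' @param object a measurement or component.
#' @export
setGeneric("fwhmHz", function(object) standardGeneric("fwhmHz"))

#' @describeIn PeakMeasurement-class integrated signal area (also defined
#'   for \code{LorentzianComponent}).
#' @export
setGeneric("peakArea", function(object) standardGeneric("peakArea"))

setMethod("chemicalShift", "Spectrum1D", function(object) object@ppm)
setMethod("intensity", "Spectrum1D", function(object) object@intensity)
setMethod("acquisition", "Spectrum1D", function(object) object@acquisition)
setMethod("specLabel", "Spectrum1D", function(object) object@label)

setMethod("hzPerPpm", "Spectrum1D", function(object)
  object@acquisition@spectrometer_frequency_MHz)

setMethod("fwhmHz", "PeakMeasurement", function(object) object@fwhm_Hz)
setMethod("fwhmHz", "LorentzianComponent", function(object) object@fwhm_Hz)
setMethod("peakArea", "PeakMeasurement", function(object) object@area)
setMethod("peakArea", "LorentzianComponent", function(object) object@area)

#' @describeIn CalibrationModel-class intercept and slope, named as
#'   \code{c(intercept, slope_per_Hz)}.
#' @param object a \code{CalibrationModel}.
#' @param ... unused.
#' @export
setMethod("coef", "CalibrationModel", function(object, ...)
  c(intercept = object@intercept, slope_per_Hz = object@slope_per_Hz))

#' @describeIn CalibrationModel-class fit R-squared (\code{NA} for the
#'   published model).
#' @export
setGeneric("fitR2", function(object) standardGeneric("fitR2"))
setMethod("fitR2", "CalibrationModel", function(object) object@fit_r2)

## ---- show ------------------------------------------------------------------

setMethod("show", "Spectrum1D", function(object) {
  cat(sprintf("Spectrum1D: %d points, %.4f .. %.4f ppm @ %.2f MHz",
              length(object@ppm), object@ppm[1L],
              object@ppm[length(object@ppm)],
              object@acquisition@spectrometer_frequency_MHz))
  if (nzchar(object@label)) cat(" [", object@label, "]", sep = "")
  cat("\n")
})

setMethod("show", "PeakMeasurement", function(object) {
  cat(sprintf("PeakMeasurement '%s': FWHM %.3f Hz, area %.4g (%s)\n",
              object@signal_id, object@fwhm_Hz, object@area, object@method))
})

setMethod("show", "LorentzianComponent", function(object) {
  cat(sprintf("Lorentzian @ %.4f ppm: FWHM %.3f Hz, area %.4g\n",
              object@center_ppm, object@fwhm_Hz, object@area))
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel (%s): loss = %.4g * broadening[Hz] + %.4g",
              object@provenance, object@slope_per_Hz, object@intercept))
  if (!is.na(object@fit_r2)) cat(sprintf("  (R2 = %.4f)", object@fit_r2))
  cat("\n")
})

setMethod("show", "BindingModel", function(object) {
  cat(sprintf("BindingModel: Kd %.3g mM, FWHM free %.3g Hz -> bound %.3g Hz\n",
              object@Kd_mM, object@fwhm_free_Hz, object@fwhm_bound_Hz))
})

setMethod("show", "SampleSpec", function(object) {
  cat(sprintf(
    "SampleSpec: %d metabolite(s), %.3g g/L protein, shim +%.3g Hz, noise sd %.3g, seed %d\n",
    length(object@metabolites), object@protein_g_per_L,
    object@shim_extra_fwhm_Hz, object@noise_sd, object@seed))
})

setMethod("show", "BlandAltmanSummary", function(object) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.4g, SD %.4g, limits of agreement [%.4g, %.4g]\n",
    object@n, object@mean_diff, object@sd_diff, object@loa_low,
    object@loa_high))
})
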