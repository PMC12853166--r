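#' @include peakfit.R
NULL

#' The published loss-factor calibration
#'
#' Linear relation between the signal-loss factor and the protein-induced
#' line broadening: slope 0.567 per Hz, intercept 0.9984. The intercept is
#' honored verbatim (slightly below 1 by construction of the fit); see
#' [correctionFactor()] for the optional flooring switch.
#'
#' @return A [CalibrationModel-class] with provenance \code{"published"}.
#' @examples
#' coef(publishedCalibration())
#' @export
publishedCalibration <- function() {
  calibrationModel(slope_per_Hz = 0.567, intercept = 0.9984,
                   fit_r2 = NA_real_, provenance = "published")
}

#' Shim correction from the non-binding reference signal
#'
#' The shim correction \eqn{S_c} is the excess linewidth of the
#' non-binding reference (formic acid by default) in the sample relative to
#' its linewidth in an optimally shimmed protein-free reference spectrum:
#' \eqn{S_c = L_{sF} - L_{oF}}. It may be negative if the sample is better
#' shimmed than the reference, and is passed through unclamped.
#'
#' @param L_sF_Hz measured reference linewidth in the sample, Hz (> 0).
#' @param L_oF_Hz optimal (protein-free) reference linewidth, Hz (> 0).
#' @return The shim correction in Hz.
#' @examples
#' shimCorrection(0.80, 0.70)  # 0.10 Hz
#' @export
shimCorrection <- function(L_sF_Hz, L_oF_Hz) {
  if (!is.numeric(L_sF_Hz) || !is.numeric(L_oF_Hz) ||
      any(L_sF_Hz <= 0) || any(L_oF_Hz <= 0))
    stopInput("linewidths must be positive")
  L_sF_Hz - L_oF_Hz
}

#' Apply the shim correction to a measured metabolite linewidth
#'
#' \eqn{L_{sMc} = L_{sM} - S_c}. A nonpositive result signals an
#' inconsistent measurement (the metabolite line cannot be narrower than
#' the field inhomogeneity accounts for) and raises an error.
#'
#' @param L_sM_Hz measured metabolite linewidth, Hz (> 0).
#' @param S_c_Hz shim correction from [shimCorrection()], Hz.
#' @return The shim-corrected linewidth in Hz.
#' @examples
#' applyShim(1.50, 0.10)  # 1.40 Hz
#' @export
applyShim <- function(L_sM_Hz, S_c_Hz) {
  if (!is.numeric(L_sM_Hz) || any(L_sM_Hz <= 0))
    stopInput("L_sM_Hz must be positive")
  out <- L_sM_Hz - S_c_Hz
  if (any(out <= 0))
    stop(cpmgError(
      "shim-corrected linewidth is nonpositive: shim reference and metabolite measurements are inconsistent",
      c("cpmgInconsistentShimError", "cpmgInputError")))
  out
}

#' Protein-induced line broadening
#'
#' \eqn{L_{sMb} = L_{sMc} - L_{oM}}: the shim-corrected linewidth minus the
#' metabolite's optimal protein-free linewidth. Negative differences are
#' measurement noise around zero binding; they clamp to 0 with a
#' diagnostic message.
#'
#' @param L_sMc_Hz shim-corrected linewidth, Hz (> 0).
#' @param L_oM_Hz optimal protein-free linewidth of the metabolite, Hz
#'   (> 0).
#' @return The nonnegative line broadening in Hz.
#' @examples
#' lineBroadening(1.40, 0.78)  # 0.62 Hz
#' @export
lineBroadening <- function(L_sMc_Hz, L_oM_Hz) {
  if (!is.numeric(L_sMc_Hz) || !is.numeric(L_oM_Hz) ||
      any(L_sMc_Hz <= 0) || any(L_oM_Hz <= 0))
    stopInput("linewidths must be positive")
  out <- L_sMc_Hz - L_oM_Hz
  if (any(out < 0)) {
    message(sprintf(
      "lineBroadening: %d value(s) below the optimal linewidth clamped to 0",
      sum(out < 0)))
    out <- pmax(out, 0)
  }
  out
}

#' Correction factor from line broadening
#'
#' Evaluates the linear calibration \eqn{C_b = slope \cdot L_{sMb} +
#' intercept}. With the published model and zero broadening this returns
#' exactly 0.9984; by default the factor is not floored at 1 so the
#' published intercept is honored verbatim. Set
#' \code{floor_factor_at_one = TRUE} for the alternative convention in
#' which a factor below 1 (meaning "no loss") is reported as 1.
#'
#' @param model a [CalibrationModel-class].
#' @param L_sMb_Hz nonnegative line broadening in Hz.
#' @param floor_factor_at_one logical; floor the factor at 1 (default
#'   \code{FALSE}).
#' @return The correction factor \eqn{C_b} (dimensionless).
#' @examples
#' correctionFactor(publishedCalibration(), 0.62)  # ~1.35
#' @export
correctionFactor <- function(model, L_sMb_Hz, floor_factor_at_one = FALSE) {
  stopifnot(is(model, "CalibrationModel"))
  if (!is.numeric(L_sMb_Hz) || any(L_sMb_Hz < 0))
    stopInput("L_sMb_Hz must be nonnegative")
  out <- model@slope_per_Hz * L_sMb_Hz + model@intercept
  if (floor_factor_at_one) out <- pmax(out, 1)
  out
}

#' Total concentration from free concentration and correction factor
#'
#' \eqn{C_t = C_f \cdot C_b}: the CPMG-measured free concentration scaled
#' by the linewidth-derived correction factor.
#'
#' @param free_conc_mM nonnegative free concentration in mM.
#' @param C_b positive correction factor.
#' @return Total concentration in mM.
#' @examples
#' totalConcentration(4.45, 1.35)  # 6.008 mM (rounded to 3 decimals)
#' @export
totalConcentration <- function(free_conc_mM, C_b) {
  if (!is.numeric(C_b) || any(C_b <= 0))
    stopInput("C_b must be positive")
  if (!is.numeric(free_conc_mM) || any(free_conc_mM < 0))
    stopInput("free_conc_mM must be nonnegative")
  free_conc_mM * C_b
}

#' Signal-loss factor
#'
#' Area of a signal measured without protein divided by its area in the
#' presence of protein under the CPMG filter. A factor of 1 means no loss
#' (no binding).
#'
#' @param area_without_protein,area_with_protein positive signal areas in
#'   consistent units.
#' @return The loss factor (dimensionless).
#' @examples
#' signalLossFactor(5.062, 1.709)  # ~2.962
#' @export
signalLossFactor <- function(area_without_protein, area_with_protein) {
  if (!is.numeric(area_without_protein) || !is.numeric(area_with_protein) ||
      any(area_without_protein <= 0) || any(area_with_protein <= 0))
    stopInput("areas must be positive")
  area_without_protein / area_with_protein
}

#' Fit the loss-factor versus line-broadening calibration
#'
#' Ordinary unweighted least squares of \code{loss_factor} on
#' \code{L_sMb_Hz} over titration pairs, as used to establish the
#' published line.
#'
#' @param pairs data.frame (or coercible) with columns \code{L_sMb_Hz} and
#'   \code{loss_factor}; at least 3 rows, broadenings not all identical.
#' @return A [CalibrationModel-class] with \code{fit_r2} and provenance
#'   \code{"fitted"}.
#' @examples
#' x <- c(0, 0.3, 0.6, 0.9)
#' fitCalibration(data.frame(L_sMb_Hz = x, loss_factor = 0.567 * x + 0.9984))
#' @export
fitCalibration <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("L_sMb_Hz", "loss_factor") %in% names(pairs))) {
    if (ncol(pairs) >= 2L) names(pairs)[1:2] <- c("L_sMb_Hz", "loss_factor")
    else stopInput("pairs must have columns L_sMb_Hz and loss_factor")
  }
  if (nrow(pairs) < 3L) stopInput("at least 3 calibration pairs are required")
  x <- pairs$L_sMb_Hz; y <- pairs$loss_factor
  if (max(x) - min(x) <= .Machine$double.eps * max(1, abs(max(x))))
    stop(cpmgError("degenerate design: all broadenings identical",
                   c("cpmgDegenerateFitError", "cpmgFitError")))
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  ## exact-line input is legitimate here; silence the perfect-fit warning
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (cf[2L] <= 0)
    stop(cpmgError("fitted slope is nonpositive; loss must grow with broadening",
                   "cpmgFitError"))
  calibrationModel(slope_per_Hz = unname(cf[2L]), intercept = unname(cf[1L]),
                   fit_r2 = r2, provenance = "fitted")
}

#' Read a reference-signal library
#'
#' CSV with columns \code{metabolite, signal_ppm, multiplicity, protons,
#' optimal_fwhm_Hz}; one row per reference signal, holding each
#' metabolite's optimal protein-free linewidth \eqn{L_{oM}} (and, for the
#' shim reference, \eqn{L_{oF}}). The packaged default library
#' (\code{system.file("extdata", "reference_signals.csv", package =
#' "CPMGcorrect")}) holds the documented TSP (0.78 Hz) and formate
#' (0.70 Hz) values plus synthetic placeholder rows that users should
#' replace with linewidths measured on their own instrument.
#'
#' @param path CSV file; defaults to the packaged library.
#' @return A validated \code{data.frame}.
#' @export
readSignalLibrary <- function(path = system.file("extdata",
                                                 "reference_signals.csv",
                                                 package = "CPMGcorrect")) {
  lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "signal_ppm", "multiplicity", "protons",
            "optimal_fwhm_Hz")
  if (!all(need %in% names(lib)))
    stopFormat(paste("signal library must have columns:",
                     paste(need, collapse = ", ")))
  if (any(lib$optimal_fwhm_Hz <= 0) || any(lib$protons < 1))
    stopInput("library linewidths must be positive and protons >= 1")
  lib
}

.libraryLookup <- function(library, metabolite) {
  hit <- which(tolower(library$metabolite) == tolower(metabolite))
  if (!length(hit))
    stop(cpmgError(sprintf("metabolite '%s' not found in the signal library",
                           metabolite),
                   c("cpmgLookupError", "cpmgInputError")))
  library[hit[1L], ]
}

#' Run the full linewidth correction for a sample
#'
#' Composes the four algorithm steps per metabolite: shim correction from
#' the non-binding reference ([shimCorrection()]), shim-corrected
#' linewidth ([applyShim()]), protein line broadening against the library
#' optimum ([lineBroadening()]), correction factor ([correctionFactor()]),
#' and - when a free concentration is supplied - the total concentration
#' ([totalConcentration()]).
#'
#' @param measurements list of [PeakMeasurement-class] objects for the
#'   metabolites of interest (signal_id must match a library metabolite).
#' @param shim_ref a [PeakMeasurement-class] of the shim-reference signal
#'   (formate by default).
#' @param library reference-signal data.frame from [readSignalLibrary()].
#' @param model a [CalibrationModel-class]; default the published one.
#' @param free_concs optional named numeric vector of free concentrations
#'   in mM (names = metabolites).
#' @param shim_metabolite library name of the shim reference (default
#'   \code{"formate"}).
#' @param floor_factor_at_one passed to [correctionFactor()].
#' @return A \code{data.frame} with one row per measurement and columns
#'   \code{metabolite, L_sM_Hz, S_c_Hz, L_sMc_Hz, L_sMb_Hz, C_b,
#'   free_conc_mM, total_conc_mM} (concentrations \code{NA} when no free
#'   concentration was supplied). Full precision; see [reportRounding()]
#'   for display rounding.
#' @examples
#' lib <- readSignalLibrary()
#' res <- correctSample(
#'   list(peakMeasurement("TSP", 1.50, 1)),
#'   shim_ref = peakMeasurement("formate", 0.80, 1),
#'   library = lib, free_concs = c(TSP = 4.45))
#' res$total_conc_mM  # 6.008 mM (3 decimals)
#' @export
correctSample <- function(measurements, shim_ref, library = readSignalLibrary(),
                          model = publishedCalibration(), free_concs = NULL,
                          shim_metabolite = "formate",
                          floor_factor_at_one = FALSE) {
  if (!is.list(measurements))
    stopInput("measurements must be a list of PeakMeasurement objects")
  empty <- data.frame(metabolite = character(), L_sM_Hz = numeric(),
                      S_c_Hz = numeric(), L_sMc_Hz = numeric(),
                      L_sMb_Hz = numeric(), C_b = numeric(),
                      free_conc_mM = numeric(), total_conc_mM = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(measurements)) return(empty)
  stopifnot(is(shim_ref, "PeakMeasurement"), is(model, "CalibrationModel"))

  L_oF <- .libraryLookup(library, shim_metabolite)$optimal_fwhm_Hz
  S_c <- shimCorrection(fwhmHz(shim_ref), L_oF)

  rows <- lapply(measurements, function(m) {
    entry <- .libraryLookup(library, m@signal_id)
    L_sMc <- applyShim(fwhmHz(m), S_c)
    L_sMb <- lineBroadening(L_sMc, entry$optimal_fwhm_Hz)
    C_b <- correctionFactor(model, L_sMb, floor_factor_at_one)
    free <- if (!is.null(free_concs) && m@signal_id %in% names(free_concs))
      unname(free_concs[[m@signal_id]]) else NA_real_
    total <- if (is.na(free)) NA_real_ else totalConcentration(free, C_b)
    data.frame(metabolite = m@signal_id, L_sM_Hz = fwhmHz(m), S_c_Hz = S_c,
               L_sMc_Hz = L_sMc, L_sMb_Hz = L_sMb, C_b = C_b,
               free_conc_mM = free, total_conc_mM = total,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Round a correction result for reporting
#'
#' Report policy: linewidths to 2 decimals, factors and concentrations to
#' 3 decimals. Internal computations always use full precision; this is a
#' display convention only.
#'
#' @param result data.frame from [correctSample()].
#' @return The rounded data.frame.
#' @export
reportRounding <- function(result) {
  for (col in c("L_sM_Hz", "S_c_Hz", "L_sMc_Hz", "L_sMb_Hz"))
    if (col %in% names(result)) result[[col]] <- round(result[[col]], 2L)
  for (col in c("C_b", "free_conc_mM", "total_conc_mM", "ratio", "quotient"))
    if (col %in% names(result)) result[[col]] <- round(result[[col]], 3L)
  result
}

#' Serialize / restore a calibration model
#'
#' Models are stored as a small JSON record with slope, intercept, fit R2
#' and provenance.
#'
#' @param model a [CalibrationModel-class].
#' @param path output (input) file path.
#' @return \code{writeCalibration} invisibly returns \code{path};
#'   \code{readCalibration} returns a [CalibrationModel-class].
#' @export
writeCalibration <- function(model, path) {
  stopifnot(is(model, "CalibrationModel"))
  jsonlite::write_json(
    list(slope_per_Hz = model@slope_per_Hz, intercept = model@intercept,
         fit_r2 = model@fit_r2, provenance = model@provenance),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) stopInput(sprintf("file not found: '%s'", path))
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibrationModel(rec$slope_per_Hz, rec$intercept,
                   if (is.null(rec$fit_r2)) NA_real_ else rec$fit_r2,
                   rec$provenance)
}
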