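#' @include simulate.R
NULL

#' The 14-level human serum albumin titration series
#'
#' Protein levels (g/L) of the calibration titration design: 0, 0.015,
#' 0.03, 0.15, 0.3, 0.9, 1.5, 3, 4.5, 6, 9, 12, 15, 18. With the default
#' albumin molecular weight (66478 g/mol) the top level is 0.271 mM.
#'
#' @return Numeric vector of 14 protein levels in g/L.
#' @export
hsaTitrationLevels <- function() {
  c(0, 0.015, 0.03, 0.15, 0.3, 0.9, 1.5, 3, 4.5, 6, 9, 12, 15, 18)
}

#' TSP as the titrated calibration compound
#'
#' TSP (the chemical-shift reference, 9 equivalent protons at 0 ppm) binds
#' moderately to albumin. The default binding model (Kd 0.27 mM, free
#' linewidth 0.78 Hz, bound linewidth 22 Hz) produces line broadenings
#' from 0 to about 0.91 Hz across the default titration - the regime in
#' which the exponential CPMG loss is well approximated by the linear
#' calibration. Bound-state linewidths and Kd values are synthetic,
#' plausible-by-physics choices, not measured constants.
#'
#' @param total_conc_mM TSP concentration (default 6.025 mM).
#' @param binding a [BindingModel-class].
#' @return A [MetaboliteSpec-class].
#' @export
tspMetabolite <- function(total_conc_mM = 6.025,
                          binding = bindingModel(Kd_mM = 0.27,
                                                 fwhm_free_Hz = 0.78,
                                                 fwhm_bound_Hz = 22)) {
  metaboliteSpec("TSP", total_conc_mM,
                 data.frame(ppm = 0.0, protons = 9), binding = binding)
}

#' Template sample for the TSP titration
#'
#' TSP plus the formate internal standard (6.0 mM, 1 proton at 8.44 ppm,
#' protein-free linewidth 0.70 Hz), a mild shim degradation of 0.05 Hz,
#' and no noise or baseline unless requested.
#'
#' @param noise_sd Gaussian noise SD (default 0, noiseless).
#' @param shim_extra_fwhm_Hz uniform shim broadening (default 0.05 Hz).
#' @param seed integer seed.
#' @return A [SampleSpec-class].
#' @export
tspTitrationSample <- function(noise_sd = 0, shim_extra_fwhm_Hz = 0.05,
                               seed = 1L) {
  sampleSpec(list(tspMetabolite()), protein_g_per_L = 0,
             internal_standard = internalStandard(),
             internal_standard_fwhm_Hz = 0.70,
             shim_extra_fwhm_Hz = shim_extra_fwhm_Hz,
             noise_sd = noise_sd, seed = seed)
}

#' Default simulation axis
#'
#' High-to-low ppm grid covering the formate (8.44 ppm) through TSP
#' (0 ppm) window at 0.045 Hz per point on a 600 MHz axis - comparable to
#' a generously zero-filled processed spectrum, and fine enough to sample
#' sub-Hz linewidths with more than 8 points per FWHM.
#'
#' @param ppm_high,ppm_low axis limits in ppm.
#' @param step_ppm grid spacing in ppm (default 7.5e-5, i.e. 0.045 Hz at
#'   600 MHz).
#' @return Strictly decreasing numeric vector.
#' @export
defaultPpmGrid <- function(ppm_high = 8.7, ppm_low = -0.3, step_ppm = 7.5e-5) {
  seq(ppm_high, ppm_low, by = -step_ppm)
}

#' Dissociation constant reproducing a target line broadening
#'
#' Inverts the 1:1 isotherm: given the ligand and protein totals, the
#' free-to-bound linewidth gap and a desired observed broadening, returns
#' the Kd for which [boundFraction()] times the gap equals the target.
#' Used to construct simulation fixtures whose correction factors match a
#' prescribed spread.
#'
#' @param target_broadening_Hz desired observed broadening (Hz, > 0).
#' @param ligand_total_mM total metabolite concentration.
#' @param protein_total_mM total protein concentration.
#' @param delta_fwhm_Hz bound-minus-free linewidth gap (Hz).
#' @return Kd in mM.
#' @export
kdFromBroadening <- function(target_broadening_Hz, ligand_total_mM,
                             protein_total_mM, delta_fwhm_Hz = 15) {
  f <- target_broadening_Hz / delta_fwhm_Hz
  if (f <= 0 || f >= 1) stopInput("target broadening must be in (0, delta_fwhm)")
  complex <- f * ligand_total_mM
  if (complex >= protein_total_mM)
    stopInput("target broadening not reachable: required complex exceeds the protein pool")
  (ligand_total_mM - complex) * (protein_total_mM - complex) / complex
}

## Plasma-like mixture blueprint: 16 metabolites with singlet positions,
## proton counts, protein-free linewidths, total concentrations and the
## correction factor each metabolite should exhibit at 18 g/L albumin.
## Totals and factors follow typical pooled-plasma values; Kd is backed out
## of the 1:1 isotherm at build time, bound linewidths sit a fixed 15 Hz
## above the free ones. Synthetic fixture values, not measured constants.
.plasmaBlueprint <- function() {
  data.frame(
    metabolite = c("acetate", "alanine", "citrate", "creatine", "creatinine",
                   "glucose", "glycine", "isoleucine", "lactate", "leucine",
                   "lysine", "phenylalanine", "pyruvate", "threonine",
                   "tyrosine", "valine"),
    ppm = c(1.92, 1.48, 2.54, 3.04, 4.06, 5.23, 3.56, 1.01, 1.33, 0.96,
            1.72, 7.37, 2.37, 4.25, 6.90, 1.10),
    protons = c(3L, 3L, 2L, 3L, 2L, 1L, 2L, 3L, 3L, 6L, 2L, 2L, 3L, 1L, 2L,
                6L),
    fwhm_free_Hz = c(0.82, 0.85, 0.95, 0.88, 0.86, 0.92, 0.84, 0.90, 0.87,
                     0.89, 0.93, 0.91, 0.86, 0.94, 0.88, 0.90),
    total_mM = c(0.047, 0.298, 0.111, 0.028, 0.090, 6.525, 0.204, 0.091,
                 1.455, 0.150, 0.110, 0.069, 0.081, 0.128, 0.071, 0.256),
    factor = c(1.154, 1.133, 1.074, 1.066, 1.252, 1.120, 1.115, 1.166,
               1.155, 1.163, 1.395, 1.417, 1.218, 1.086, 1.310, 1.106),
    stringsAsFactors = FALSE)
}

#' Plasma-like 16-metabolite simulation mixture
#'
#' A synthetic pooled-plasma analog: 16 common plasma metabolites at
#' realistic total concentrations, each with a 1:1 albumin-binding model
#' whose Kd is chosen so that, at \code{protein_g_per_L} albumin, the
#' metabolite shows a prescribed correction factor between about 1.07 and
#' 1.42 (line broadenings of roughly 0.1-0.75 Hz). All binding constants
#' are synthetic fixture values.
#'
#' @param protein_g_per_L albumin level the factors are anchored to
#'   (default 18 g/L).
#' @param protein_MW_g_per_mol albumin molecular weight.
#' @param delta_fwhm_Hz bound-minus-free linewidth gap (default 15 Hz).
#' @return A list of [MetaboliteSpec-class] objects.
#' @seealso [plasmaSampleSpec()]
#' @export
plasmaMixture <- function(protein_g_per_L = 18, protein_MW_g_per_mol = 66478,
                          delta_fwhm_Hz = 15) {
  bp <- .plasmaBlueprint()
  P_mM <- protein_g_per_L / protein_MW_g_per_mol * 1000
  slope <- coef(publishedCalibration())[["slope_per_Hz"]]
  icpt <- coef(publishedCalibration())[["intercept"]]
  lapply(seq_len(nrow(bp)), function(i) {
    broadening <- (bp$factor[i] - icpt) / slope
    kd <- kdFromBroadening(broadening, bp$total_mM[i], P_mM, delta_fwhm_Hz)
    metaboliteSpec(
      bp$metabolite[i], bp$total_mM[i],
      data.frame(ppm = bp$ppm[i], protons = bp$protons[i]),
      binding = bindingModel(kd, bp$fwhm_free_Hz[i],
                             bp$fwhm_free_Hz[i] + delta_fwhm_Hz))
  })
}

#' Plasma-like sample specification
#'
#' [plasmaMixture()] plus the formate standard at a given protein level,
#' shim degradation and noise.
#'
#' @param protein_g_per_L albumin level (default 18 g/L).
#' @param shim_extra_fwhm_Hz uniform shim broadening (default 0.15 Hz).
#' @param noise_sd Gaussian noise SD (default 0).
#' @param seed integer seed.
#' @return A [SampleSpec-class].
#' @export
plasmaSampleSpec <- function(protein_g_per_L = 18, shim_extra_fwhm_Hz = 0.15,
                             noise_sd = 0, seed = 2L) {
  sampleSpec(plasmaMixture(protein_g_per_L = 18),
             protein_g_per_L = protein_g_per_L,
             internal_standard = internalStandard(),
             internal_standard_fwhm_Hz = 0.70,
             shim_extra_fwhm_Hz = shim_extra_fwhm_Hz, noise_sd = noise_sd,
             seed = seed)
}

#' Quantification targets of the plasma-like mixture
#'
#' @return data.frame with columns \code{metabolite, ppm, protons} for
#'   [quantifySpectrum()].
#' @export
plasmaTargets <- function() {
  bp <- .plasmaBlueprint()
  data.frame(metabolite = bp$metabolite, ppm = bp$ppm, protons = bp$protons,
             stringsAsFactors = FALSE)
}
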