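#' @include quantify.R
NULL

#' Bound fraction under 1:1 binding with ligand depletion
#'
#' Exact solution of the single-site mass balance. With total ligand
#' \eqn{L}, total protein \eqn{P} and dissociation constant \eqn{K_d}, the
#' complex concentration is the smaller root of
#' \eqn{C^2 - (L + P + K_d) C + L P = 0} and the bound fraction is
#' \eqn{f = C / L}. Continuous in all arguments; a fixed-stoichiometry
#' linear model is deliberately not used.
#'
#' @param ligand_total_mM positive total ligand (metabolite) concentration.
#' @param protein_total_mM nonnegative total protein concentration.
#' @param Kd_mM positive dissociation constant.
#' @return Bound fraction in [0, 1].
#' @examples
#' boundFraction(6.025, 0.27, 0.27)
#' @export
boundFraction <- function(ligand_total_mM, protein_total_mM, Kd_mM) {
  if (any(ligand_total_mM <= 0)) stopInput("ligand_total_mM must be positive")
  if (any(protein_total_mM < 0)) stopInput("protein_total_mM must be nonnegative")
  if (any(Kd_mM <= 0)) stopInput("Kd_mM must be positive")
  b <- ligand_total_mM + protein_total_mM + Kd_mM
  complex <- (b - sqrt(b * b - 4 * ligand_total_mM * protein_total_mM)) / 2
  pmin(pmax(complex / ligand_total_mM, 0), 1)
}

#' Observed linewidth under fast exchange
#'
#' When binding and release are fast on the NMR timescale, one
#' population-averaged signal is observed with linewidth
#' \eqn{(1 - f)\,\Gamma_{free} + f\,\Gamma_{bound}}.
#'
#' @param f bound fraction in [0, 1].
#' @param binding a [BindingModel-class].
#' @return Observed FWHM in Hz.
#' @export
observedFwhm <- function(f, binding) {
  stopifnot(is(binding, "BindingModel"))
  if (any(f < 0) || any(f > 1)) stopInput("f must be in [0, 1]")
  (1 - f) * binding@fwhm_free_Hz + f * binding@fwhm_bound_Hz
}

#' CPMG signal-loss factor from exchange-averaged relaxation
#'
#' Bound molecules inherit the protein's fast transverse relaxation and
#' are attenuated during the echo train. The simulator uses a
#' mono-exponential loss in the exchange-averaged excess relaxation rate
#' \eqn{\pi\,(\Gamma_{obs} - \Gamma_{free})} over an effective echo time
#' \eqn{T_{eff}}:
#' \deqn{loss = \exp(T_{eff}\,\pi\,(\Gamma_{obs} - \Gamma_{free}))}
#' which equals the area ratio no-protein / with-protein for the simulated
#' signal. For small broadenings this linearizes to
#' \eqn{1 + T_{eff}\,\pi\,\Delta\Gamma}; the default \eqn{T_{eff} =
#' 0.1805} s makes that linear slope equal the published calibration slope
#' of 0.567 per Hz.
#'
#' @param observed_fwhm_Hz observed linewidth, Hz (>= free linewidth).
#' @param fwhm_free_Hz free-state linewidth, Hz.
#' @param effective_echo_time_s positive effective echo time in seconds.
#' @return Loss factor >= 1, strictly increasing in the broadening.
#' @examples
#' cpmgLossFactor(1.40, 0.78, 0.1805)  # ~1.42 for 0.62 Hz broadening
#' @export
cpmgLossFactor <- function(observed_fwhm_Hz, fwhm_free_Hz,
                           effective_echo_time_s = 0.1805) {
  if (any(effective_echo_time_s <= 0))
    stopInput("effective_echo_time_s must be positive")
  if (any(observed_fwhm_Hz < fwhm_free_Hz))
    stopInput("observed linewidth must be >= the free linewidth")
  exp(effective_echo_time_s * pi * (observed_fwhm_Hz - fwhm_free_Hz))
}

## run fn with a private, seeded RNG stream, restoring the caller's state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Render a sample as a synthetic CPMG spectrum
#'
#' For every metabolite signal the simulator computes the bound fraction
#' (1:1 isotherm), the fast-exchange linewidth, and the CPMG loss factor;
#' the signal is rendered as a Lorentzian with area proportional to
#' \code{concentration x protons / loss} and FWHM equal to the observed
#' linewidth plus the sample's shim degradation. The non-binding internal
#' standard renders at its protein-free linewidth plus shim only. A linear
#' baseline and seeded Gaussian noise are added last; spectra are
#' bit-reproducible given the seed.
#'
#' @param spec a [SampleSpec-class].
#' @param ppm_grid strictly decreasing ppm axis covering every signal; an
#'   ascending grid is reversed. Must sample the narrowest rendered line
#'   with at least 8 points per FWHM.
#' @param acquisition acquisition metadata stamped on the result.
#' @return A [Spectrum1D-class]; the label records the seed.
#' @seealso [simulateTitration()], [defaultPpmGrid()]
#' @export
simulateSpectrum <- function(spec, ppm_grid,
                             acquisition = acquisitionParams()) {
  stopifnot(is(spec, "SampleSpec"))
  ppm_grid <- as.numeric(ppm_grid)
  if (length(ppm_grid) >= 2L && all(diff(ppm_grid) > 0))
    ppm_grid <- rev(ppm_grid)
  if (any(diff(ppm_grid) >= 0)) stopInput("ppm_grid must be strictly monotone")
  nu <- acquisition@spectrometer_frequency_MHz
  step_Hz <- max(abs(diff(ppm_grid))) * nu

  P_mM <- spec@protein_g_per_L / spec@protein_MW_g_per_mol * 1000

  ## per-signal rendering parameters
  lines <- list()
  for (m in spec@metabolites) {
    if (is.null(m@binding)) {
      fw_obs <- m@fwhm_free_Hz
      loss <- 1
    } else {
      f <- boundFraction(m@total_conc_mM, P_mM, m@binding@Kd_mM)
      fw_obs <- observedFwhm(f, m@binding)
      loss <- cpmgLossFactor(fw_obs, m@binding@fwhm_free_Hz,
                             spec@effective_echo_time_s)
    }
    for (i in seq_len(nrow(m@signals))) {
      lines[[length(lines) + 1L]] <- list(
        ppm = m@signals$ppm[i],
        fwhm = fw_obs + spec@shim_extra_fwhm_Hz,
        area = m@total_conc_mM * m@signals$protons[i] / loss)
    }
  }
  std <- spec@internal_standard
  lines[[length(lines) + 1L]] <- list(
    ppm = std@signal_ppm,
    fwhm = spec@internal_standard_fwhm_Hz + spec@shim_extra_fwhm_Hz,
    area = std@concentration_mM * as.numeric(std@protons))

  fwhms <- vapply(lines, `[[`, numeric(1L), "fwhm")
  if (min(fwhms) / step_Hz < 8)
    stopInput(sprintf(
      "grid too coarse: %.3g Hz/point gives %.1f points per narrowest FWHM (>= 8 required)",
      step_Hz, min(fwhms) / step_Hz))
  centers <- vapply(lines, `[[`, numeric(1L), "ppm")
  margin <- 10 * fwhms / nu
  if (any(centers + margin > ppm_grid[1L]) ||
      any(centers - margin < ppm_grid[length(ppm_grid)]))
    stopInput("ppm_grid must cover every signal position +/- 10 FWHM")

  y <- numeric(length(ppm_grid))
  for (ln in lines)
    y <- y + lorentzianProfile(ppm_grid, ln$ppm, ln$fwhm, ln$area, nu)
  y <- y + spec@baseline[1L] * ppm_grid + spec@baseline[2L]
  if (spec@noise_sd > 0)
    y <- y + .withSeed(spec@seed,
                       function() stats::rnorm(length(y), sd = spec@noise_sd))

  new("Spectrum1D", ppm = ppm_grid, intensity = y, acquisition = acquisition,
      label = sprintf("simulated (seed %d, protein %.4g g/L)",
                      spec@seed, spec@protein_g_per_L))
}

#' Simulate a protein titration series
#'
#' One spectrum per protein level with everything else held fixed (the
#' default level list is [hsaTitrationLevels()], the 14-step human serum
#' albumin series from 0 to 18 g/L). Paired with the zero-protein
#' spectrum, the series yields (line broadening, loss factor) calibration
#' pairs. Each level uses its own derived seed so noise realizations are
#' independent but reproducible.
#'
#' @param metabolite a [MetaboliteSpec-class] (the titrated compound).
#' @param protein_levels_g_per_L nonnegative numeric vector of protein
#'   levels.
#' @param base a [SampleSpec-class] template supplying standard, shim,
#'   noise, baseline, echo time and seed.
#' @param ppm_grid axis passed to [simulateSpectrum()]; default
#'   [defaultPpmGrid()].
#' @param acquisition acquisition metadata for the rendered spectra.
#' @return A list of [Spectrum1D-class], one per level, named by level.
#' @export
simulateTitration <- function(metabolite,
                              protein_levels_g_per_L = hsaTitrationLevels(),
                              base = tspTitrationSample(),
                              ppm_grid = defaultPpmGrid(),
                              acquisition = acquisitionParams()) {
  stopifnot(is(metabolite, "MetaboliteSpec"), is(base, "SampleSpec"))
  if (!length(protein_levels_g_per_L)) stopInput("empty protein level list")
  if (any(protein_levels_g_per_L < 0)) stopInput("protein levels must be nonnegative")
  out <- vector("list", length(protein_levels_g_per_L))
  for (i in seq_along(protein_levels_g_per_L)) {
    spec <- base
    spec@metabolites <- list(metabolite)
    spec@protein_g_per_L <- as.numeric(protein_levels_g_per_L[i])
    spec@seed <- base@seed + i * 1000L
    out[[i]] <- simulateSpectrum(spec, ppm_grid, acquisition)
  }
  names(out) <- sprintf("%g", protein_levels_g_per_L)
  out
}
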