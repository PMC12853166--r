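#' @include spectra-io.R
NULL

#' Evaluate a Lorentzian lineshape on a ppm axis
#'
#' The natural NMR lineshape. With area \eqn{A} (intensity x Hz) and FWHM
#' \eqn{\Gamma} (Hz), the profile is
#' \deqn{I(\delta) = \frac{2A}{\pi\Gamma}\,
#'   \frac{1}{1 + [2(\delta - \delta_0)\,\nu/\Gamma]^2}}
#' where \eqn{\nu} is the Hz-per-ppm scale, so its integral over frequency
#' equals \eqn{A} and its apex height is \eqn{2A/(\pi\Gamma)}.
#'
#' @param ppm numeric axis in ppm.
#' @param center_ppm peak position in ppm.
#' @param fwhm_Hz full width at half maximum in Hz.
#' @param area integrated area in intensity x Hz.
#' @param hz_per_ppm Hz spanned by 1 ppm (the spectrometer frequency in MHz).
#' @return Numeric vector of intensities.
#' @export
lorentzianProfile <- function(ppm, center_ppm, fwhm_Hz, area, hz_per_ppm) {
  x <- 2 * (ppm - center_ppm) * hz_per_ppm / fwhm_Hz
  (2 * area / (pi * fwhm_Hz)) / (1 + x * x)
}

#' Polynomial baseline correction of a spectral region
#'
#' Fits a polynomial of the given order to baseline support points - the
#' outermost 10\% of grid points on each edge of the window, where an
#' isolated signal has decayed - and subtracts it across the whole region.
#' Order 0 removes a constant offset, order 1 a tilted baseline, and so on.
#'
#' @param region a [Spectrum1D-class], typically a narrow window around one
#'   signal with signal-free edges.
#' @param order small nonnegative integer polynomial order.
#' @return The baseline-corrected [Spectrum1D-class] (axis unchanged).
#' @export
baselineCorrect <- function(region, order = 1L) {
  stopifnot(is(region, "Spectrum1D"))
  order <- as.integer(order)
  if (order < 0L) stopInput("order must be nonnegative")
  n <- length(region@ppm)
  if (n <= order + 1L)
    stopInput(sprintf("polynomial order %d too high for a %d-point region", order, n))
  edge <- ceiling(0.1 * n)
  support <- c(seq_len(edge), seq(n - edge + 1L, n))
  support <- unique(support[support >= 1L & support <= n])
  if (length(support) < order + 1L)
    stopInput("too few baseline support points for the requested order")
  x <- region@ppm[support]; y <- region@intensity[support]
  if (order == 0L) {
    base <- rep(mean(y), n)
  } else {
    fit <- stats::lm(y ~ stats::poly(x, degree = order, raw = TRUE))
    base <- as.numeric(cbind(1, stats::poly(region@ppm, degree = order, raw = TRUE)) %*%
                         stats::coef(fit))
  }
  new("Spectrum1D", ppm = region@ppm, intensity = region@intensity - base,
      acquisition = region@acquisition, label = region@label)
}

#' Measure a peak's FWHM by direct half-height analysis
#'
#' Mirrors interactive "peak width" tools: the apex is refined by a
#' three-point parabola through the samples around the discrete maximum,
#' and the two half-height crossings are located by linear interpolation
#' between bracketing samples. The method is lineshape-agnostic; the region
#' should be baseline-corrected first.
#'
#' @param region a baseline-corrected [Spectrum1D-class] containing the
#'   peak.
#' @param approx_center_ppm approximate peak position; a local maximum is
#'   searched within \code{search_halfwidth_ppm} of it.
#' @param signal_id identifier recorded on the result.
#' @param search_halfwidth_ppm half-width of the apex search window
#'   (default 0.02 ppm).
#' @return A [PeakMeasurement-class] with \code{method = "direct"} and the
#'   trapezoidal area of the whole region.
#' @section Errors: a \code{cpmgPeakNotFoundError} if no local maximum lies
#'   in the search window; a \code{cpmgTruncatedPeakError} if a flank never
#'   crosses half height inside the region; a \code{cpmgInputError} if
#'   fewer than 8 grid points span the half-height width (insufficient
#'   digital resolution).
#' @export
measureFwhmDirect <- function(region, approx_center_ppm, signal_id = "peak",
                              search_halfwidth_ppm = 0.02) {
  stopifnot(is(region, "Spectrum1D"))
  ppm <- region@ppm; y <- region@intensity
  n <- length(ppm)
  inwin <- which(abs(ppm - approx_center_ppm) <= search_halfwidth_ppm)
  ## local maxima of the region that fall inside the search window
  cand <- inwin[inwin > 1L & inwin < n]
  ## a local maximum needs nonzero prominence on at least one side, so flat
  ## regions never yield a spurious apex
  cand <- cand[(y[cand] >= y[cand - 1L] & y[cand] >= y[cand + 1L]) &
                 (y[cand] > y[cand - 1L] | y[cand] > y[cand + 1L])]
  if (!length(cand))
    stop(cpmgError(sprintf("no local maximum within %.3g ppm of %.4f ppm",
                           search_halfwidth_ppm, approx_center_ppm),
                   c("cpmgPeakNotFoundError", "cpmgInputError")))
  i <- cand[which.max(y[cand])]

  ## apex refinement: parabola through the 3 samples around the maximum
  x3 <- ppm[(i - 1L):(i + 1L)]; y3 <- y[(i - 1L):(i + 1L)]
  cf <- solve(cbind(1, x3 - ppm[i], (x3 - ppm[i])^2), y3)
  apex_h <- if (abs(cf[3L]) > 0) cf[1L] - cf[2L]^2 / (4 * cf[3L]) else y[i]
  if (!is.finite(apex_h) || apex_h < y[i]) apex_h <- y[i]  # degenerate parabola
  half <- apex_h / 2

  cross <- function(idx_seq) {
    prev <- i
    for (j in idx_seq) {
      if (y[j] < half) {
        ## linear interpolation between samples j (below) and prev (above)
        return(ppm[j] + (half - y[j]) * (ppm[prev] - ppm[j]) / (y[prev] - y[j]))
      }
      prev <- j
    }
    stop(cpmgError("peak flank never crosses half height inside the region (truncated peak)",
                   c("cpmgTruncatedPeakError", "cpmgInputError")))
  }
  left  <- cross(seq(i - 1L, 1L))       # toward higher ppm
  right <- cross(seq(i + 1L, n))        # toward lower ppm
  fwhm_ppm <- left - right
  fwhm_Hz <- fwhm_ppm * hzPerPpm(region)

  n_span <- sum(ppm <= left & ppm >= right)
  if (n_span < 8L)
    stopInput(sprintf(
      "only %d grid points across the half-height span (>= 8 required): insufficient digital resolution",
      n_span))

  area <- .trapzHz(ppm, y, hzPerPpm(region))
  peakMeasurement(signal_id, fwhm_Hz, max(area, 0), method = "direct")
}

## trapezoidal integral on a decreasing ppm axis, in intensity x Hz units
.trapzHz <- function(ppm, y, hz_per_ppm) {
  dx <- -diff(ppm) * hz_per_ppm
  sum(dx * (y[-length(y)] + y[-1L]) / 2)
}

#' Integrate a spectral window
#'
#' Sign-preserving trapezoidal integral of a baseline-corrected region over
#' a closed ppm window, reported in intensity x Hz units.
#'
#' @param region a baseline-corrected [Spectrum1D-class].
#' @param ppm_high,ppm_low integration bounds, \code{ppm_high > ppm_low};
#'   the window must lie inside the region.
#' @return The integral (intensity x Hz).
#' @export
integrateSignal <- function(region, ppm_high, ppm_low) {
  stopifnot(is(region, "Spectrum1D"))
  if (ppm_high <= ppm_low) stopInput("ppm_high must exceed ppm_low")
  pmax_ <- region@ppm[1L]; pmin_ <- region@ppm[length(region@ppm)]
  if (ppm_high > pmax_ + 1e-12 || ppm_low < pmin_ - 1e-12)
    stopInput(sprintf("window [%g, %g] extends outside the region [%g, %g]",
                      ppm_low, ppm_high, pmin_, pmax_))
  keep <- region@ppm <= ppm_high & region@ppm >= ppm_low
  if (sum(keep) < 2L) stopInput("window contains fewer than 2 grid points")
  .trapzHz(region@ppm[keep], region@intensity[keep], hzPerPpm(region))
}

#' Lorentzian deconvolution of a spectral region
#'
#' Nonlinear least squares (Levenberg-Marquardt, via \pkg{minpack.lm}) of a
#' sum of Lorentzian components, optionally plus a local linear baseline,
#' against the region. Lorentzians are the natural lineshape here: uniform
#' exponential apodization during processing only adds a constant
#' Lorentzian broadening, preserving the family.
#'
#' Components whose converged centers differ by less than 0.1 of their mean
#' FWHM are considered duplicates of one line: they are merged
#' (area-weighted center, summed area) and the reduced model is refitted
#' once.
#'
#' For multiplets no splitting model is fitted; the recommended convention
#' is to take the linewidth of the tallest resolved component of the
#' multiplet (see [tallestComponent()]).
#'
#' @param region a [Spectrum1D-class], baseline-corrected unless
#'   \code{baseline = "linear"}.
#' @param initial list of [LorentzianComponent-class] initial guesses (one
#'   per line).
#' @param baseline \code{"none"} or \code{"linear"} (adds a fitted local
#'   linear baseline term).
#' @param max_iter iteration cap (default 500).
#' @param ftol relative residual convergence tolerance (default 1e-10).
#' @return A list of converged [LorentzianComponent-class] objects sorted
#'   by center, with attributes \code{fit_residual_rms} (root mean square
#'   residual) and \code{baseline} (fitted \code{c(slope, offset)} or
#'   \code{NULL}).
#' @section Errors: \code{cpmgFitError} on non-convergence within the
#'   iteration cap (carries the best-so-far components in its
#'   \code{components} field); \code{cpmgDegenerateFitError} if a component
#'   collapses to zero area.
#' @export
deconvolve <- function(region, initial, baseline = c("none", "linear"),
                       max_iter = 500L, ftol = 1e-10) {
  stopifnot(is(region, "Spectrum1D"))
  baseline <- match.arg(baseline)
  if (!is.list(initial) || length(initial) == 0L)
    stopInput("at least one initial LorentzianComponent guess is required")
  if (!all(vapply(initial, is, logical(1L), "LorentzianComponent")))
    stopInput("initial must be a list of LorentzianComponent objects")

  fit1 <- .fitLorentzians(region, initial, baseline, max_iter, ftol)

  ## merge components that converged onto the same line, then refit once
  merged <- .mergeClose(fit1$components, hzPerPpm(region))
  if (length(merged) < length(fit1$components))
    fit1 <- .fitLorentzians(region, merged, baseline, max_iter, ftol)

  comps <- fit1$components
  areas <- vapply(comps, peakArea, numeric(1L))
  if (any(areas < 1e-6 * max(areas)))
    stop(cpmgError("a component collapsed to zero area during the fit",
                   c("cpmgDegenerateFitError", "cpmgFitError")))
  ord <- order(vapply(comps, function(cc) cc@center_ppm, numeric(1L)))
  out <- comps[ord]
  attr(out, "fit_residual_rms") <- fit1$rms
  attr(out, "baseline") <- fit1$baseline
  out
}

.fitLorentzians <- function(region, initial, baseline, max_iter, ftol) {
  ppm <- region@ppm; y <- region@intensity
  nu <- hzPerPpm(region)
  k <- length(initial)
  p0 <- unlist(lapply(initial, function(cc) c(cc@center_ppm, cc@fwhm_Hz, cc@area)))
  lower <- rep(c(-Inf, 0.01, 1e-12), k)
  upper <- rep(c(Inf, Inf, Inf), k)
  if (baseline == "linear") {
    p0 <- c(p0, 0, 0)
    lower <- c(lower, -Inf, -Inf); upper <- c(upper, Inf, Inf)
  }
  mid <- mean(range(ppm))
  model <- function(p) {
    m <- numeric(length(ppm))
    for (j in seq_len(k)) {
      b <- (j - 1L) * 3L
      m <- m + lorentzianProfile(ppm, p[b + 1L], p[b + 2L], p[b + 3L], nu)
    }
    if (baseline == "linear") m <- m + p[3L * k + 1L] * (ppm - mid) + p[3L * k + 2L]
    m
  }
  res <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper,
    fn = function(p) model(p) - y,
    control = minpack.lm::nls.lm.control(
      maxiter = min(as.integer(max_iter), 1024L), ftol = ftol, ptol = ftol))
  comps <- lapply(seq_len(k), function(j) {
    b <- (j - 1L) * 3L
    lorentzian(res$par[b + 1L], max(res$par[b + 2L], 0.01),
               max(res$par[b + 3L], 1e-12))
  })
  rms <- sqrt(mean(res$fvec^2))
  if (res$info == 0L || res$info == 5L)
    stop(cpmgError(
      sprintf("deconvolution did not converge within %d iterations (residual RMS %.4g)",
              max_iter, rms),
      "cpmgFitError", components = comps, residual_rms = rms))
  list(components = comps, rms = rms,
       baseline = if (baseline == "linear")
         c(slope = res$par[3L * k + 1L], offset = res$par[3L * k + 2L]) else NULL)
}

.mergeClose <- function(comps, nu) {
  if (length(comps) < 2L) return(comps)
  ord <- order(vapply(comps, function(cc) cc@center_ppm, numeric(1L)))
  comps <- comps[ord]
  out <- list(comps[[1L]])
  for (cc in comps[-1L]) {
    last <- out[[length(out)]]
    mean_fwhm <- (last@fwhm_Hz + cc@fwhm_Hz) / 2
    if (abs(cc@center_ppm - last@center_ppm) * nu < 0.1 * mean_fwhm) {
      a <- last@area + cc@area
      ctr <- (last@center_ppm * last@area + cc@center_ppm * cc@area) / a
      out[[length(out)]] <- lorentzian(ctr, mean_fwhm, a)
    } else out <- c(out, cc)
  }
  out
}

#' Tallest component of a deconvolved multiplet
#'
#' Multiplet linewidths are taken from the tallest resolved component after
#' deconvolution (a Lorentzian's apex height is \code{2 * area / (pi *
#' fwhm)}), since no splitting model is fitted.
#'
#' @param components list of [LorentzianComponent-class] objects as
#'   returned by [deconvolve()].
#' @return The single tallest [LorentzianComponent-class].
#' @export
tallestComponent <- function(components) {
  if (!length(components)) stopInput("empty component list")
  heights <- vapply(components, function(cc) 2 * cc@area / (pi * cc@fwhm_Hz),
                    numeric(1L))
  components[[which.max(heights)]]
}

#' Export peak measurements as a data frame
#'
#' One CSV-ready row per measurement: \code{signal_id, center_ppm, fwhm_Hz,
#' area, method, residual}.
#'
#' @param measurements list of [PeakMeasurement-class] objects.
#' @param centers_ppm optional numeric vector of peak positions to record.
#' @return A \code{data.frame}.
#' @export
peakTable <- function(measurements, centers_ppm = NA_real_) {
  data.frame(
    signal_id = vapply(measurements, function(m) m@signal_id, character(1L)),
    center_ppm = rep_len(centers_ppm, length(measurements)),
    fwhm_Hz = vapply(measurements, fwhmHz, numeric(1L)),
    area = vapply(measurements, peakArea, numeric(1L)),
    method = vapply(measurements, function(m) m@method, character(1L)),
    residual = vapply(measurements, function(m) m@fit_residual_rms, numeric(1L)),
    stringsAsFactors = FALSE)
}
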