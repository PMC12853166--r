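#' @include correction.R
NULL

#' Concentration from signal areas via the internal standard
#'
#' Standard internal-standard relation: per-proton area of the analyte
#' relative to the per-proton area of the standard of known concentration,
#' \deqn{C_M = C_{std} \cdot \frac{A_M / n_M}{A_{std} / n_{std}}}
#' Under a CPMG filter this yields the \emph{free} concentration of a
#' protein-binding analyte.
#'
#' @param area_m positive analyte signal area.
#' @param protons_m positive integer, protons contributing to the analyte
#'   signal.
#' @param std an [InternalStandard-class].
#' @param area_std positive standard signal area (same units).
#' @return Concentration in mM.
#' @examples
#' concentrationFromAreas(9, 9L, internalStandard(concentration_mM = 6), 1)
#' @export
concentrationFromAreas <- function(area_m, protons_m, std, area_std) {
  stopifnot(is(std, "InternalStandard"))
  if (!is.numeric(area_m) || any(area_m <= 0) ||
      !is.numeric(area_std) || any(area_std <= 0))
    stopInput("areas must be positive")
  protons_m <- as.integer(protons_m)
  if (any(is.na(protons_m)) || any(protons_m < 1L))
    stopInput("protons_m must be a positive integer")
  std@concentration_mM * (area_m / protons_m) /
    (area_std / as.numeric(std@protons))
}

#' Lower limit of quantification from a dilution series
#'
#' The LLOQ is the lowest concentration level in a (geometric) dilution
#' series whose replicate relative standard deviation (sample SD / mean)
#' is below 20\%. Each level needs at least 3 replicates; the sample
#' (n - 1) standard deviation is used because replicate counts are small.
#'
#' Two readings of "lowest qualifying level" are available:
#' \code{"literal"} (default) returns the lowest concentration that
#' qualifies even if an intermediate level fails (non-monotone noise);
#' \code{"monotone"} requires the level and every level above it to
#' qualify.
#'
#' @param series list of levels, each a list/record with elements
#'   \code{conc_mM} and \code{areas} (numeric replicates, length >= 3).
#'   A data.frame with columns \code{conc_mM} and \code{area} (long
#'   format, one replicate per row) is also accepted.
#' @param rsd_threshold qualifying RSD bound (default 0.20).
#' @param mode \code{"literal"} or \code{"monotone"}.
#' @return The LLOQ in mM, or \code{NA_real_} if no level qualifies.
#' @examples
#' series <- list(list(conc_mM = 0.005, areas = c(1.0, 1.1, 0.95)),
#'                list(conc_mM = 0.001, areas = c(0.5, 1.5, 0.2)))
#' lloqFromDilution(series)  # 0.005
#' @export
lloqFromDilution <- function(series, rsd_threshold = 0.20,
                             mode = c("literal", "monotone")) {
  mode <- match.arg(mode)
  if (is.data.frame(series)) {
    if (!all(c("conc_mM", "area") %in% names(series)))
      stopInput("data.frame series needs columns conc_mM and area")
    series <- lapply(split(series$area, series$conc_mM),
                     function(a) list(areas = a))
    for (i in seq_along(series))
      series[[i]]$conc_mM <- as.numeric(names(series)[i])
    series <- unname(series)
  }
  if (!length(series)) stopInput("empty dilution series")
  conc <- vapply(series, function(l) as.numeric(l$conc_mM), numeric(1L))
  rsd <- vapply(series, function(l) {
    a <- as.numeric(l$areas)
    if (length(a) < 3L)
      stopInput("each dilution level needs at least 3 replicates")
    stats::sd(a) / mean(a)
  }, numeric(1L))
  ord <- order(conc)
  conc <- conc[ord]; rsd <- rsd[ord]
  ok <- rsd < rsd_threshold
  if (mode == "monotone") {
    ## qualify only if every level from this one upward qualifies
    ok <- rev(cumprod(rev(ok)) > 0)
  }
  if (!any(ok)) return(NA_real_)
  conc[which(ok)[1L]]
}
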