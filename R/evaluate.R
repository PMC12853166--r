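#' @include pipeline.R
NULL

#' Bland-Altman agreement analysis
#'
#' Classical method-comparison summary: per-pair differences
#' \code{a - b}, their mean (bias) and sample standard deviation, and the
#' 95\% limits of agreement at \code{mean +/- 1.96 sd}. Per-pair
#' (mean, difference) points are retained for plotting difference versus
#' mean.
#'
#' @param a,b numeric vectors of paired measurements (two methods), or
#'   \code{a} may be a two-column matrix/data.frame with \code{b} missing.
#' @return A [BlandAltmanSummary-class].
#' @examples
#' blandAltman(c(1, 2, 3), c(1.1, 1.9, 3.0))
#' @export
blandAltman <- function(a, b) {
  if (missing(b)) {
    ab <- as.data.frame(a)
    if (ncol(ab) < 2L) stopInput("need two paired columns")
    b <- ab[[2L]]; a <- ab[[1L]]
  }
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stopInput("a and b must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L) stopInput("at least 2 complete pairs are required")
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  new("BlandAltmanSummary", n = length(d), mean_diff = m, sd_diff = s,
      loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
      points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Agreement table: reference/test ratios versus algorithm factors
#'
#' Reproduces the validation-table arithmetic: for each metabolite the
#' ratio of a reference value (e.g. concentration after protein
#' precipitation, or a certified value) to the test value (the CPMG free
#' concentration), and the quotient of that ratio over the
#' linewidth-derived correction factor. Quotients near 1 indicate that the
#' algorithm's factor explains the free-to-total gap.
#'
#' @param rows_in data.frame with columns \code{metabolite,
#'   reference_value, test_value, algorithm_factor} (all values positive).
#' @return data.frame adding full-precision \code{ratio}
#'   (reference/test) and \code{quotient} (ratio/factor); use
#'   [reportRounding()] for the 3-decimal report convention.
#' @examples
#' agreementTable(data.frame(metabolite = "glucose", reference_value = 6.525,
#'                           test_value = 5.647, algorithm_factor = 1.120))
#' @export
agreementTable <- function(rows_in) {
  rows_in <- as.data.frame(rows_in)
  need <- c("metabolite", "reference_value", "test_value", "algorithm_factor")
  if (!all(need %in% names(rows_in)))
    stopInput(paste("rows_in must have columns:", paste(need, collapse = ", ")))
  if (any(rows_in$reference_value <= 0) || any(rows_in$test_value <= 0) ||
      any(rows_in$algorithm_factor <= 0))
    stopInput("all values must be positive")
  rows_in$ratio <- rows_in$reference_value / rows_in$test_value
  rows_in$quotient <- rows_in$ratio / rows_in$algorithm_factor
  rows_in
}

#' Packaged validation-table fixtures
#'
#' Transcriptions of the three printed validation tables shipped with the
#' package so the report arithmetic is testable offline:
#' \describe{
#'   \item{\code{"synthetic"}}{12 compounds, signal areas with and without
#'     albumin in a synthetic matrix (columns \code{reference_value} =
#'     area without albumin, \code{test_value} = area with albumin).}
#'   \item{\code{"plasma"}}{16 metabolites, free CPMG versus
#'     protein-precipitated concentrations in pooled plasma.}
#'   \item{\code{"nist"}}{11 metabolites, free CPMG versus certified
#'     reference-plasma concentrations.}
#' }
#' Each fixture also carries the printed \code{ratio_printed} and
#' \code{quotient_printed} columns for cross-checking.
#'
#' @param name \code{"synthetic"}, \code{"plasma"} or \code{"nist"}.
#' @return data.frame ready for [agreementTable()].
#' @export
agreementFixture <- function(name = c("synthetic", "plasma", "nist")) {
  name <- match.arg(name)
  file <- c(synthetic = "table_synthetic.csv", plasma = "table_plasma.csv",
            nist = "table_nist.csv")[[name]]
  path <- system.file("extdata", file, package = "CPMGcorrect")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
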