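#' @include AllGenerics.R
NULL

## Header keys shared by both text dialects; order fixed for stable output.
.acqKeys <- c("spectrometer_frequency_MHz", "temperature_K",
              "total_echo_time_s", "echo_spacing_s", "n_echoes",
              "relaxation_delay_s", "processing_line_broadening_Hz")

.fmt17 <- function(x) sprintf("%.17g", x)  # round-trips doubles bit-exactly

#' Read a processed 1D spectrum from a text file
#'
#' Two dialects are supported. \code{two_column_text} is the interchange
#' format: UTF-8 lines of \code{ppm<TAB or comma>intensity}, optionally
#' preceded by \code{# key: value} header lines; any acquisition metadata
#' not present in the header is filled with the defaults of
#' [acquisitionParams()] (600 MHz, 298 K, 80 ms echo train).
#' \code{internal_record} is the same layout but always carries the full
#' metadata header and full-precision (\code{\%.17g}) numbers, so
#' write/read round trips are bit-exact.
#'
#' Files with an ascending ppm axis are re-sorted to the decreasing
#' display convention.
#'
#' @param path file to read.
#' @param dialect \code{"two_column_text"} or \code{"internal_record"}.
#' @return A [Spectrum1D-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("8.40\t0", "8.39\t1", "8.38\t0"), f)
#' readSpectrum(f)
#' @seealso [writeSpectrum()]
#' @export
readSpectrum <- function(path, dialect = c("two_column_text", "internal_record")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopInput(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)

  meta <- list()
  label <- ""
  is_header <- grepl("^\\s*#", lines)
  for (h in lines[is_header]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) {
      key <- m[2L]; val <- trimws(m[3L])
      if (key == "label") label <- val
      else if (key %in% .acqKeys) meta[[key]] <- val
    }
  }
  if (dialect == "internal_record" && !length(meta) && label == "" &&
      !any(is_header))
    stopFormat("internal_record file has no metadata header")

  data_idx <- which(!is_header & nzchar(trimws(lines)))
  if (length(data_idx) < 2L)
    stopInput(sprintf("'%s': fewer than 2 data points", path))

  ## vectorized parse: tab, comma or whitespace separated pairs
  parts <- strsplit(trimws(lines[data_idx]), "[\t, ]+", perl = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stopFormat(sprintf("'%s' line %d: cannot parse '%s' as 'ppm<sep>intensity'",
                       path, data_idx[bad[1L]], lines[data_idx[bad[1L]]]))
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  if (anyNA(vals)) {
    bad1 <- data_idx[ceiling(which(is.na(vals))[1L] / 2)]
    stopFormat(sprintf("'%s' line %d: cannot parse '%s' as 'ppm<sep>intensity'",
                       path, bad1, lines[bad1]))
  }
  ppm <- vals[c(TRUE, FALSE)]
  intens <- vals[c(FALSE, TRUE)]

  acq <- acquisitionParams()
  for (key in names(meta)) {
    v <- if (key == "n_echoes") as.integer(meta[[key]]) else as.numeric(meta[[key]])
    if (is.na(v)) stopFormat(sprintf("'%s': bad header value for %s", path, key))
    slot(acq, key) <- v
  }
  validObject(acq)
  spectrum1D(ppm, intens, acquisition = acq, label = label)
}

#' @rdname writeSpectrum
setMethod("writeSpectrum", "Spectrum1D",
  function(object, path, dialect = c("internal_record", "two_column_text")) {
    dialect <- match.arg(dialect)
    out <- character()
    if (dialect == "internal_record") {
      out <- c(out, "# format: CPMGcorrect internal_record v1",
               paste0("# label: ", object@label))
      for (key in .acqKeys) {
        v <- slot(object@acquisition, key)
        out <- c(out, sprintf("# %s: %s", key,
                              if (key == "n_echoes") as.character(v) else .fmt17(v)))
      }
    }
    out <- c(out, paste(.fmt17(object@ppm), .fmt17(object@intensity), sep = "\t"))
    ok <- tryCatch({ writeLines(out, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stopInput(sprintf("cannot write to '%s'", path))
    invisible(path)
  })

#' @rdname extractRegion
setMethod("extractRegion", "Spectrum1D", function(object, ppm_high, ppm_low) {
  if (!is.numeric(ppm_high) || !is.numeric(ppm_low) || ppm_high <= ppm_low)
    stopInput("ppm_high must exceed ppm_low")
  keep <- object@ppm <= ppm_high & object@ppm >= ppm_low
  if (!any(keep))
    stopInput(sprintf("window [%g, %g] ppm does not overlap the axis", ppm_low, ppm_high))
  if (sum(keep) < 2L)
    stopInput("window contains fewer than 2 grid points")
  new("Spectrum1D", ppm = object@ppm[keep], intensity = object@intensity[keep],
      acquisition = object@acquisition, label = object@label)
})
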