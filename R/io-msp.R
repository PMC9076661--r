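#' Read spectra from an MSP (NIST-style text library) file
#'
#' Parses records of `Key: value` header lines followed by `Num Peaks: k`
#' and exactly `k` peak lines (`m/z intensity`, whitespace- or
#' semicolon-separated). Records are separated by blank lines or by the next
#' `Name:` line. `NAME` supplies the spectrum identifier, `PRECURSORMZ` (or
#' `PRECURSOR_MZ`/`PrecursorMZ`) the precursor m/z. A record whose declared
#' peak count does not match the parsed peaks is a format error; a record
#' with no precursor m/z is skipped with a warning. An empty stream yields an
#' empty list.
#'
#' @param source path to an MSP file, or a character vector of lines.
#' @return A list of [fragmentation_spectrum()] objects.
#' @seealso [read_mgf()]
#' @export
read_msp <- function(source) {
  lines <- .as_lines(source)
  n <- length(lines)
  spectra <- list()
  i <- 1L
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) {
      i <- i + 1L
      next
    }
    # header lines until "Num Peaks:"
    meta <- list()
    record_line <- i
    npeaks <- NA_integer_
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (!nzchar(line)) break
      m <- regmatches(line, regexec("^([^:]+):[ \t]*(.*)$", line))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("MSP format error at line %d: expected 'Key: value', got '%s'",
                     i, line), call. = FALSE)
      }
      key <- toupper(gsub("[ _]", "", m[[2]]))
      value <- m[[3]]
      i <- i + 1L
      if (key == "NUMPEAKS") {
        npeaks <- suppressWarnings(as.integer(value))
        if (is.na(npeaks) || npeaks < 1L) {
          stop(sprintf("MSP format error at line %d: bad peak count '%s'",
                       i - 1L, value), call. = FALSE)
        }
        break
      }
      meta[[key]] <- value
    }
    if (is.na(npeaks)) {
      stop(sprintf("MSP format error: record starting at line %d has no 'Num Peaks'",
                   record_line), call. = FALSE)
    }
    mz <- numeric()
    intensity <- numeric()
    have_intensity <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (!nzchar(line)) break
      if (grepl("^[A-Za-z]", line)) break  # next record's header
      tokens <- strsplit(gsub(";", " ", line), "[ \t]+")[[1]]
      v <- suppressWarnings(as.numeric(tokens))
      if (length(v) < 1L || is.na(v[[1]])) {
        stop(sprintf("MSP format error at line %d: unparsable peak line '%s'",
                     i, line), call. = FALSE)
      }
      mz <- c(mz, v[[1]])
      if (length(v) >= 2L && !is.na(v[[2]])) {
        have_intensity <- TRUE
        intensity <- c(intensity, v[[2]])
      } else {
        intensity <- c(intensity, 0)
      }
      i <- i + 1L
    }
    if (length(mz) != npeaks) {
      stop(sprintf(
        "MSP format error: record starting at line %d declares %d peaks but has %d",
        record_line, npeaks, length(mz)
      ), call. = FALSE)
    }
    prec_key <- intersect(c("PRECURSORMZ", "PRECURSORM/Z", "PEPMASS"),
                          names(meta))
    if (length(prec_key) == 0L) {
      warning(sprintf(
        "MSP record starting at line %d has no PRECURSORMZ; skipped",
        record_line
      ), call. = FALSE)
      next
    }
    pepmass <- suppressWarnings(as.numeric(meta[[prec_key[[1]]]]))
    if (is.na(pepmass)) {
      warning(sprintf(
        "MSP record starting at line %d has unparsable PRECURSORMZ; skipped",
        record_line
      ), call. = FALSE)
      next
    }
    id <- if (!is.null(meta$NAME)) meta$NAME else as.character(length(spectra) + 1L)
    adduct <- ""
    for (k in c("ADDUCT", "PRECURSORTYPE")) {
      if (!is.null(meta[[k]])) adduct <- meta[[k]]
    }
    spectra[[length(spectra) + 1L]] <- fragmentation_spectrum(
      mz = mz,
      precursor_mz = pepmass,
      intensity = if (have_intensity) intensity else NULL,
      spectrum_id = id,
      adduct = adduct,
      metadata = meta[setdiff(names(meta),
                              c("NAME", prec_key, "ADDUCT", "PRECURSORTYPE"))]
    )
  }
  spectra
}
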