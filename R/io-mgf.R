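#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` supplies the precursor
#' m/z (a trailing intensity token is ignored), `TITLE` supplies the spectrum
#' identifier when present (otherwise a running index is used), `ADDUCT` the
#' adduct label, and any other `KEY=VALUE` header lines are preserved
#' verbatim in `metadata`. Peak lines are `m/z [intensity]`; peaks are
#' canonicalized (sorted ascending, non-positive m/z dropped). An empty
#' stream yields an empty list.
#'
#' @param source path to an MGF file, or a character vector of lines.
#' @return A list of [fragmentation_spectrum()] objects.
#' @seealso [write_mgf()], [read_msp()]
#' @export
read_mgf <- function(source) {
  lines <- .as_lines(source)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  idx <- 0L
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || startsWith(line, "#")) {
      i <- i + 1L
      next
    }
    if (line != "BEGIN IONS") {
      stop(sprintf("MGF format error at line %d: expected BEGIN IONS, got '%s'",
                   i, line), call. = FALSE)
    }
    begin_line <- i
    i <- i + 1L
    meta <- list()
    mz <- numeric()
    intensity <- numeric()
    have_intensity <- FALSE
    closed <- FALSE
    while (i <= n) {
      line <- trimws(lines[[i]])
      if (line == "END IONS") {
        closed <- TRUE
        i <- i + 1L
        break
      }
      if (!nzchar(line)) {
        i <- i + 1L
        next
      }
      if (grepl("=", line, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", line))
        value <- sub("^[^=]*=", "", line)
        meta[[key]] <- value
      } else {
        tokens <- strsplit(line, "[ \t]+")[[1]]
        v <- suppressWarnings(as.numeric(tokens))
        if (length(v) < 1L || anyNA(v[seq_len(min(2L, length(v)))])) {
          stop(sprintf("MGF format error at line %d: unparsable peak line '%s'",
                       i, line), call. = FALSE)
        }
        mz <- c(mz, v[[1]])
        if (length(v) >= 2L) {
          have_intensity <- TRUE
          intensity <- c(intensity, v[[2]])
        } else {
          intensity <- c(intensity, 0)
        }
      }
      i <- i + 1L
    }
    if (!closed) {
      stop(sprintf("MGF format error: block starting at line %d has no END IONS",
                   begin_line), call. = FALSE)
    }
    if (is.null(meta$PEPMASS)) {
      stop(sprintf("MGF format error: block starting at line %d has no PEPMASS",
                   begin_line), call. = FALSE)
    }
    if (length(mz) == 0L) {
      stop(sprintf("MGF format error: block starting at line %d has no peaks",
                   begin_line), call. = FALSE)
    }
    idx <- idx + 1L
    pepmass <- suppressWarnings(
      as.numeric(strsplit(trimws(meta$PEPMASS), "[ \t]+")[[1]][[1]])
    )
    if (is.na(pepmass)) {
      stop(sprintf("MGF format error: block starting at line %d has unparsable PEPMASS",
                   begin_line), call. = FALSE)
    }
    id <- if (!is.null(meta$TITLE)) meta$TITLE else as.character(idx)
    adduct <- if (!is.null(meta$ADDUCT)) meta$ADDUCT else ""
    spectra[[idx]] <- fragmentation_spectrum(
      mz = mz,
      precursor_mz = pepmass,
      intensity = if (have_intensity) intensity else NULL,
      spectrum_id = id,
      adduct = adduct,
      metadata = meta[setdiff(names(meta), c("PEPMASS", "TITLE", "ADDUCT"))]
    )
  }
  spectra
}

#' Write spectra to a Mascot generic format (MGF) file
#'
#' Writes one `BEGIN IONS`/`END IONS` block per spectrum. m/z values are
#' written with six decimal places, so a write/read round trip preserves
#' spectrum count exactly and m/z and precursor m/z to within 1e-6 Th.
#'
#' @param spectra a list of [fragmentation_spectrum()] objects (may be empty).
#' @param sink path to write to, or a connection.
#' @return Invisibly, the character vector of lines written.
#' @export
write_mgf <- function(spectra, sink) {
  stopifnot(is.list(spectra))
  lines <- character()
  for (s in spectra) {
    stopifnot(is_spectrum(s))
    block <- c(
      "BEGIN IONS",
      paste0("TITLE=", s$spectrum_id),
      paste0("PEPMASS=", sprintf("%.6f", s$precursor_mz)),
      if (nzchar(s$adduct)) paste0("ADDUCT=", s$adduct),
      .mgf_meta_lines(s$metadata),
      if (is.null(s$intensity)) sprintf("%.6f", s$mz)
      else sprintf("%.6f %.6g", s$mz, s$intensity),
      "END IONS",
      ""
    )
    lines <- c(lines, block)
  }
  writeLines(lines, sink)
  invisible(lines)
}

# Only scalar metadata survives an MGF round trip; structured entries (e.g.
# the run map attached by the synthetic generator) are silently dropped.
.mgf_meta_lines <- function(metadata) {
  if (!length(metadata)) return(character(0))
  scalar <- vapply(metadata, function(v) is.atomic(v) && length(v) == 1L,
                   NA)
  metadata <- metadata[scalar]
  if (!length(metadata)) return(character(0))
  paste0(names(metadata), "=", vapply(metadata, as.character, ""))
}

# Accept a path, a connection, or a character vector of lines.
.as_lines <- function(source) {
  if (is.character(source) && length(source) == 1L &&
      !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else if (is.character(source)) {
    unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    stop("'source' must be a file path, connection, or character vector",
         call. = FALSE)
  }
}
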