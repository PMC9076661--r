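#' Construct a fragmentation spectrum
#'
#' A fragmentation spectrum is the centroided peak list produced by
#' fragmenting a selected precursor ion: a strictly ascending vector of
#' fragment m/z values (Thomson), optional non-negative intensities, the
#' precursor m/z, and an adduct label such as `"[M+H]+"`. Peaks are
#' canonicalized on construction (sorted ascending, non-positive m/z
#' dropped); intensities are carried through for interoperability but are
#' never consumed by the alignment method itself, which uses m/z values only.
#'
#' @param mz numeric vector of fragment m/z values (Th); must contain at
#'   least one positive value.
#' @param precursor_mz precursor m/z (Th), a single positive number.
#' @param intensity optional numeric vector of non-negative abundances, same
#'   length as `mz`.
#' @param spectrum_id identifier string; defaults to `""`.
#' @param adduct adduct label, e.g. `"[M+H]+"`; defaults to `""`.
#' @param metadata named character list of additional key/value metadata.
#'
#' @return An object of class `fragmentation_spectrum` with fields
#'   `spectrum_id`, `precursor_mz`, `adduct`, `mz`, `intensity` (or `NULL`),
#'   and `metadata`.
#' @examples
#' s <- fragmentation_spectrum(c(201.1, 101.0), precursor_mz = 301.07)
#' s$mz  # sorted ascending
#' @export
fragmentation_spectrum <- function(mz, precursor_mz, intensity = NULL,
                                   spectrum_id = "", adduct = "",
                                   metadata = list()) {
  if (!is.numeric(mz) || length(mz) < 1L) {
    stop("'mz' must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L ||
      !is.finite(precursor_mz) || precursor_mz <= 0) {
    stop("'precursor_mz' must be a single positive number", call. = FALSE)
  }
  if (!is.null(intensity)) {
    if (length(intensity) != length(mz)) {
      stop("'intensity' must have the same length as 'mz'", call. = FALSE)
    }
    if (any(!is.finite(intensity)) || any(intensity < 0)) {
      stop("'intensity' must be finite and non-negative", call. = FALSE)
    }
  }
  keep <- is.finite(mz) & mz > 0
  if (!any(keep)) {
    stop("spectrum has no peaks with positive m/z", call. = FALSE)
  }
  mz <- mz[keep]
  if (!is.null(intensity)) intensity <- intensity[keep]
  ord <- order(mz)
  mz <- mz[ord]
  if (!is.null(intensity)) intensity <- intensity[ord]
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      precursor_mz = as.numeric(precursor_mz),
      adduct = as.character(adduct),
      mz = as.numeric(mz),
      intensity = if (is.null(intensity)) NULL else as.numeric(intensity),
      metadata = metadata
    ),
    class = "fragmentation_spectrum"
  )
}

#' @export
print.fragmentation_spectrum <- function(x, ...) {
  cat(sprintf(
    "fragmentation_spectrum '%s': %d peaks, precursor m/z %.4f%s\n",
    x$spectrum_id, length(x$mz), x$precursor_mz,
    if (nzchar(x$adduct)) paste0(" ", x$adduct) else ""
  ))
  invisible(x)
}

#' @export
length.fragmentation_spectrum <- function(x) length(x$mz)

is_spectrum <- function(x) inherits(x, "fragmentation_spectrum")

#' Canonicalize a peak list
#'
#' Sorts peaks ascending by m/z, removes non-positive m/z values, and merges
#' peaks whose m/z values are closer than `merge_tolerance`. Merged peaks get
#' the intensity-weighted mean m/z and summed intensity; when intensities are
#' absent the unweighted mean m/z is used. The default tolerance of 0 merges
#' nothing, reflecting the use of library spectra as-is; merging is opt-in.
#' Merging is repeated until stable, so the result is idempotent.
#'
#' @param spectrum a [fragmentation_spectrum()].
#' @param merge_tolerance peaks closer than this (Th) are merged; default 0.
#' @return A canonicalized `fragmentation_spectrum`.
#' @examples
#' s <- fragmentation_spectrum(c(100.000, 100.0005, 200.0), 301.0)
#' canonicalize(s, merge_tolerance = 0.002)$mz
#' @export
canonicalize <- function(spectrum, merge_tolerance = 0) {
  stopifnot(is_spectrum(spectrum))
  if (!is.numeric(merge_tolerance) || merge_tolerance < 0) {
    stop("'merge_tolerance' must be a non-negative number", call. = FALSE)
  }
  mz <- spectrum$mz
  intensity <- spectrum$intensity
  keep <- mz > 0
  mz <- mz[keep]
  if (!is.null(intensity)) intensity <- intensity[keep]
  if (length(mz) == 0L) {
    stop("canonicalization removed all peaks (empty spectrum)", call. = FALSE)
  }
  ord <- order(mz)
  mz <- mz[ord]
  if (!is.null(intensity)) intensity <- intensity[ord]
  if (merge_tolerance > 0) {
    repeat {
      d <- diff(mz)
      if (!length(d) || all(d >= merge_tolerance)) break
      # cluster runs of peaks chained closer than the tolerance
      grp <- cumsum(c(1L, as.integer(d >= merge_tolerance)))
      if (is.null(intensity)) {
        mz <- as.numeric(tapply(mz, grp, mean))
      } else {
        wsum <- as.numeric(tapply(intensity, grp, sum))
        wmz <- as.numeric(tapply(mz * intensity, grp, sum))
        # fall back to unweighted mean within zero-intensity clusters
        zero <- wsum == 0
        mz_new <- ifelse(zero, as.numeric(tapply(mz, grp, mean)), wmz / wsum)
        mz <- mz_new
        intensity <- wsum
      }
    }
  }
  out <- spectrum
  out$mz <- mz
  out$intensity <- intensity
  out
}
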