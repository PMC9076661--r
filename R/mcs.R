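#' Jaccard similarity of overlapping bonds
#'
#' Chemical-similarity summary of a maximum common substructure (MCS): given
#' the number of overlapping bonds N between two molecules and their bond
#' counts N_A and N_B, the Jaccard coefficient is
#'
#'   s = N / ((N_A + N_B) - N).
#'
#' Finding N itself requires a substructure search in a cheminformatics
#' toolkit and is outside this package's scope; this helper turns given bond
#' counts into the similarity coefficient.
#'
#' @param N overlapping-bond count, `0 <= N <= min(N_A, N_B)`.
#' @param N_A,N_B bond counts of the two molecules, each >= 1.
#' @return The Jaccard coefficient in \[0, 1\].
#' @examples
#' mcs_jaccard(5, 8, 7)  # 0.5
#' @export
mcs_jaccard <- function(N, N_A, N_B) {
  if (N_A < 1 || N_B < 1) {
    stop("bond counts N_A and N_B must be >= 1", call. = FALSE)
  }
  if (N < 0 || N > min(N_A, N_B)) {
    stop("N must satisfy 0 <= N <= min(N_A, N_B)", call. = FALSE)
  }
  N / ((N_A + N_B) - N)
}

#' Classify an MCS Jaccard coefficient
#'
#' Maps the coefficient to the four-level structural-similarity rubric:
#' below 0.35 `not_similar`, 0.35 up to (but excluding) 0.45 `low`, 0.45
#' through 0.7 (inclusive) `medium`, and above 0.7 `high`.
#'
#' @param s Jaccard coefficient(s) in \[0, 1\].
#' @return A character vector of categories (`not_similar`, `low`, `medium`,
#'   `high`).
#' @examples
#' classify_mcs(c(0.3, 0.4, 0.5, 0.8))
#' @export
classify_mcs <- function(s) {
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("'s' must lie in [0, 1]", call. = FALSE)
  }
  ifelse(s < 0.35, "not_similar",
         ifelse(s < 0.45, "low",
                ifelse(s <= 0.7, "medium", "high")))
}
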