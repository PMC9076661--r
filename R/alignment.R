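#' Zero-gap global alignment of two fragment lists
#'
#' Aligns the rows (fragments of X) and columns (fragments of Y) of the
#' interspectral similarity quadrant with Needleman-Wunsch dynamic
#' programming under a fixed gap penalty of zero:
#'
#'   A(i, j) = max( A(i-1, j-1) + S\[i, j\], A(i-1, j), A(i, j-1) ),
#'
#' with boundary A(i, 0) = A(0, j) = 0. The terminal value A(m, n) is the
#' alignment score (never negative, since gaps are free), and the traceback
#' yields the aligned fragment pairs: a monotone matching, with only diagonal
#' steps that strictly increase A recorded as aligned pairs. Among co-optimal
#' paths, ties are broken diagonal > up > left, which selects the matching
#' with the most aligned pairs; the result is deterministic.
#'
#' @param Sxy m x n numeric matrix (typically
#'   `similarity_quadrant(dec, "xy")`); all entries must be finite.
#' @return An object of class `alignment_result` with fields `score`, `pairs`
#'   (two-column integer matrix of 1-based (i, j) index pairs, both columns
#'   strictly increasing), and `contributing` (the S\[i, j\] values summed by
#'   the score).
#' @examples
#' align_dp(matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2))
#' @export
align_dp <- function(Sxy) {
  Sxy <- .check_align_input(Sxy)
  m <- nrow(Sxy)
  n <- ncol(Sxy)
  A <- matrix(0, m + 1L, n + 1L)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      A[i + 1L, j + 1L] <- max(A[i, j] + Sxy[i, j], A[i, j + 1L], A[i + 1L, j])
    }
  }
  # traceback from (m, n); prefer contributing diagonal, then up, then left
  pairs <- integer(0)
  i <- m
  j <- n
  while (i > 0L && j > 0L) {
    if (Sxy[i, j] > 0 && A[i + 1L, j + 1L] == A[i, j] + Sxy[i, j]) {
      pairs <- c(i, j, pairs)
      i <- i - 1L
      j <- j - 1L
    } else if (A[i + 1L, j + 1L] == A[i, j + 1L]) {
      i <- i - 1L
    } else if (A[i + 1L, j + 1L] == A[i + 1L, j]) {
      j <- j - 1L
    } else {
      # non-contributing diagonal (S <= 0 on an exactly-tying path)
      i <- i - 1L
      j <- j - 1L
    }
  }
  pairs <- matrix(pairs, ncol = 2L, byrow = TRUE,
                  dimnames = list(NULL, c("i", "j")))
  contributing <- Sxy[pairs]
  structure(
    list(score = A[m + 1L, n + 1L], pairs = pairs,
         contributing = as.numeric(contributing)),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment_result: score %.6g, %d aligned ion pair(s)\n",
              x$score, nrow(x$pairs)))
  invisible(x)
}

#' Score-only zero-gap alignment
#'
#' Computes the same terminal score as [align_dp()] without a traceback,
#' using a single loop over the shorter dimension (the matrix is transposed
#' when it has more rows than columns; the score is invariant under
#' transposition). Each iteration is composed of element-wise maxima and a
#' prefix (rolling) maximum, which is what makes the batch version
#' vectorizable across permutations.
#'
#' @param Sxy m x n numeric matrix of finite values.
#' @return The alignment score, a single non-negative number.
#' @export
align_score_fast <- function(Sxy) {
  Sxy <- .check_align_input(Sxy)
  if (nrow(Sxy) > ncol(Sxy)) Sxy <- t(Sxy)
  m <- nrow(Sxy)
  n <- ncol(Sxy)
  a <- numeric(n + 1L)  # A(i-1, 0..n)
  for (i in seq_len(m)) {
    e <- pmax(a[seq_len(n)] + Sxy[i, ], a[1L + seq_len(n)])
    a <- c(0, cummax(e))
  }
  a[[n + 1L]]
}

#' Batched score-only alignment over a stack of matrices
#'
#' Evaluates [align_score_fast()] on every slice of a k x m x n array in a
#' vectorized fashion: the dynamic-programming state is a k x (n+1) matrix
#' and the per-row prefix maximum is computed by logarithmic shift-doubling,
#' so the permutation-test inner loop costs min(m, n) vector operations per
#' stage rather than k separate alignments.
#'
#' @param stack numeric array with dimensions (k, m, n); k may be 0.
#' @return Numeric vector of k alignment scores.
#' @export
align_score_batch <- function(stack) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  k <- dim(stack)[[1]]
  if (k == 0L) return(numeric(0))
  if (any(!is.finite(stack))) {
    stop("similarity stack contains non-finite entries", call. = FALSE)
  }
  if (dim(stack)[[2]] > dim(stack)[[3]]) stack <- aperm(stack, c(1L, 3L, 2L))
  m <- dim(stack)[[2]]
  n <- dim(stack)[[3]]
  A <- matrix(0, k, n + 1L)
  for (i in seq_len(m)) {
    e <- pmax(A[, seq_len(n), drop = FALSE] + stack[, i, ],
              A[, 1L + seq_len(n), drop = FALSE])
    # rolling (prefix) max along columns by shift-doubling
    d <- 1L
    while (d < n) {
      idx <- (d + 1L):n
      e[, idx] <- pmax(e[, idx, drop = FALSE],
                       e[, idx - d, drop = FALSE])
      d <- 2L * d
    }
    A[, 1L + seq_len(n)] <- e
  }
  A[, n + 1L]
}

.check_align_input <- function(Sxy) {
  if (is.vector(Sxy)) Sxy <- matrix(Sxy, nrow = 1L)
  stopifnot(is.matrix(Sxy), nrow(Sxy) >= 1L, ncol(Sxy) >= 1L)
  if (any(!is.finite(Sxy))) {
    stop("similarity quadrant contains non-finite entries", call. = FALSE)
  }
  Sxy
}

#' Count of matched ions in an alignment
#'
#' The number of aligned fragment pairs with strictly positive similarity
#' contribution, the quantity compared against the matched-ion cutoff when
#' filtering hits.
#'
#' @param aln an `alignment_result`.
#' @return Integer count.
#' @export
n_matched_ions <- function(aln) {
  stopifnot(inherits(aln, "alignment_result"))
  sum(aln$contributing > 0)
}
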