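# Independent brute-force oracles for the matrix pipeline and the alignment.
# These deliberately use different algorithms from the package (explicit
# loops, power iteration, svd, exhaustive enumeration) so that agreement is
# evidence of correctness, not of shared code.

# Nested-loop m/z-difference count matrix: for row i in the top block, count
# matches over the whole top m x (m+n) block of D; bottom rows likewise.
oracle_count_matrix <- function(concat_mz, m, n, tol) {
  K <- m + n
  D <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      D[i, j] <- concat_mz[i] - concat_mz[j]
    }
  }
  C <- matrix(0L, K, K)
  for (i in seq_len(K)) {
    rows <- if (i <= m) seq_len(m) else m + seq_len(n)
    block <- D[rows, , drop = FALSE]
    for (j in seq_len(K)) {
      C[i, j] <- sum(abs(block - D[i, j]) <= tol)
    }
  }
  list(D = D, C = C)
}

# Stationary distribution by long power iteration from uniform.
oracle_stationary <- function(T_, iters = 200000L, tol = 1e-15) {
  p <- rep(1 / nrow(T_), nrow(T_))
  for (it in seq_len(iters)) {
    p2 <- drop(p %*% T_)
    p2 <- p2 / sum(p2)
    if (max(abs(p2 - p)) < tol) return(p2)
    p <- p2
  }
  p
}

# Moore-Penrose pseudoinverse via base svd (different route from the
# package's symmetric eigendecomposition).
oracle_pinv <- function(M) {
  s <- svd(M)
  cut <- max(dim(M)) * max(s$d) * 1e-12
  d_inv <- ifelse(s$d > cut, 1 / s$d, 0)
  s$v %*% (d_inv * t(s$u))
}

# Exhaustive zero-gap alignment score: maximum over ALL monotone matchings
# (every equal-size subset of rows and columns, paired in sorted order) of
# the sum of selected entries, floored at 0.
oracle_align_exhaustive <- function(S) {
  m <- nrow(S)
  n <- ncol(S)
  best <- 0
  for (k in seq_len(min(m, n))) {
    rows <- utils::combn(m, k, simplify = FALSE)
    cols <- utils::combn(n, k, simplify = FALSE)
    for (r in rows) {
      for (cc in cols) {
        best <- max(best, sum(S[cbind(r, cc)]))
      }
    }
  }
  best
}

# All order-preserving permutation plans for block sizes (m, n): every
# choice of which m concatenated values form X' (sorted), rest Y' (sorted).
all_permutation_plans <- function(concat_mz, m, n) {
  subsets <- utils::combn(m + n, m, simplify = FALSE)
  lapply(subsets, function(chosen) {
    rest <- setdiff(seq_len(m + n), chosen)
    c(chosen[order(concat_mz[chosen])], rest[order(concat_mz[rest])])
  })
}

# A reproducible random spectrum pair with small fragment counts.
random_small_pair <- function(m, n, mz_range = c(50, 500)) {
  x <- fragmentation_spectrum(sort(stats::runif(m, mz_range[1], mz_range[2])),
                              precursor_mz = mz_range[2] + 1,
                              spectrum_id = "x")
  y <- fragmentation_spectrum(sort(stats::runif(n, mz_range[1], mz_range[2])),
                              precursor_mz = mz_range[2] + 1,
                              spectrum_id = "y")
  list(x = x, y = y)
}
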