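#' Pair a spectrum X with a spectrum Y
#'
#' Bundles two spectra with the concatenation of their m/z lists (X first,
#' then Y), the layout on which the whole similarity construction operates:
#' every matrix downstream is (m+n) x (m+n) with the first m rows/columns
#' indexing X fragments and the last n indexing Y fragments.
#'
#' @param x,y [fragmentation_spectrum()] objects of length m and n.
#' @return An object of class `spectrum_pair` with fields `x`, `y`, `m`, `n`,
#'   and `concat_mz`.
#' @export
spectrum_pair <- function(x, y) {
  stopifnot(is_spectrum(x), is_spectrum(y))
  structure(
    list(x = x, y = y, m = length(x$mz), n = length(y$mz),
         concat_mz = c(x$mz, y$mz)),
    class = "spectrum_pair"
  )
}

#' All pairwise m/z differences of a spectrum pair
#'
#' Forms the (m+n) x (m+n) outer difference matrix D of the concatenated m/z
#' list, D\[i, j\] = mz\[i\] - mz\[j\] (row minus column). The top-right m x n
#' quadrant therefore holds "X minus Y" interspectral differences; D is
#' antisymmetric with a zero diagonal.
#'
#' @param pair a [spectrum_pair()].
#' @return A list of class `difference_matrix` with fields `D`, `m`, `n`.
#' @export
pairwise_difference_matrix <- function(pair) {
  stopifnot(inherits(pair, "spectrum_pair"))
  D <- outer(pair$concat_mz, pair$concat_mz, "-")
  structure(list(D = D, m = pair$m, n = pair$n), class = "difference_matrix")
}

#' Count m/z-difference frequencies blockwise
#'
#' For each entry of the top m rows of D, counts how many entries of the top
#' m x (m+n) block fall within `tolerance` (closed inequality, signed
#' differences) of it; entries of the bottom n rows are counted against the
#' bottom n x (m+n) block. Every difference matches at least itself, so all
#' counts are >= 1. The count of an interspectral difference is high when the
#' same m/z difference cross-links many fragment pairs -- the signature of a
#' shared structural modification.
#'
#' @param dm a `difference_matrix` from [pairwise_difference_matrix()].
#' @param tolerance m/z window (Th) within which two differences are counted
#'   as the same; must be >= 0. Default 0.01.
#' @return A list of class `count_matrix` with fields `C` (integer matrix),
#'   `m`, `n`, `tolerance`.
#' @export
mz_difference_counts <- function(dm, tolerance = 0.01) {
  stopifnot(inherits(dm, "difference_matrix"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0) {
    stop("'tolerance' must be a single non-negative number", call. = FALSE)
  }
  D <- dm$D
  m <- dm$m
  n <- dm$n
  C <- matrix(0L, m + n, m + n)
  C[seq_len(m), ] <- .count_block(D[seq_len(m), , drop = FALSE], tolerance)
  C[m + seq_len(n), ] <- .count_block(D[m + seq_len(n), , drop = FALSE],
                                      tolerance)
  structure(list(C = C, m = m, n = n, tolerance = tolerance),
            class = "count_matrix")
}

# Counts, for each entry q of `block`, #{v in block : |v - q| <= tol}.
# Sorted lookup keeps this O(K log K) in the number of block entries.
.count_block <- function(block, tol) {
  vals <- sort(as.vector(block))
  q <- as.vector(block)
  cnt <- findInterval(q + tol, vals) -
    findInterval(q - tol, vals, left.open = TRUE)
  matrix(as.integer(cnt), nrow(block), ncol(block))
}

#' Row-normalize a count matrix into a Markov transition matrix
#'
#' Divides each row of C by its sum, yielding the m/z transition matrix T in
#' which T\[i, j\] is the probability of the i-th fragment "transitioning" to
#' the j-th under a random walk weighted by m/z-difference frequency.
#'
#' @param cm a `count_matrix` from [mz_difference_counts()], or a plain
#'   matrix of positive counts.
#' @return A row-stochastic numeric matrix.
#' @export
transition_matrix <- function(cm) {
  C <- if (inherits(cm, "count_matrix")) cm$C else cm
  rs <- rowSums(C)
  if (any(rs <= 0)) {
    stop("internal consistency error: count matrix has a non-positive row sum",
         call. = FALSE)
  }
  C / rs
}

#' Stationary distribution of a transition matrix
#'
#' Computes the probability vector p with pT = p (the principal left
#' eigenvector of T, normalized to sum to one). The eigendecomposition of
#' t(T) is used; if its residual exceeds the tolerance, power iteration
#' refines the solution, and as a last resort a vanishing uniform
#' teleportation (1 - a) T + a/(m+n) with a = 1e-8 regularizes a reducible or
#' periodic chain (logged via a warning). Count matrices produced by
#' [mz_difference_counts()] are strictly positive, so the chain is always
#' irreducible and aperiodic in normal use.
#'
#' @param T_ a row-stochastic square matrix.
#' @param tol convergence tolerance on `max(abs(p %*% T - p))`; default 1e-10.
#' @return A numeric vector p with all entries >= 0, summing to 1.
#' @export
stationary_distribution <- function(T_, tol = 1e-10) {
  stopifnot(is.matrix(T_), nrow(T_) == ncol(T_))
  k <- nrow(T_)
  if (k == 1L) return(1)
  p <- .stationary_eigen(T_)
  if (.stationary_residual(p, T_) <= tol) return(p)
  p <- .stationary_power(T_, p)
  if (.stationary_residual(p, T_) <= tol) return(p)
  warning("stationary distribution did not converge; applying uniform teleportation",
          call. = FALSE)
  alpha <- 1e-8
  T_reg <- (1 - alpha) * T_ + alpha / k
  p <- .stationary_power(T_reg, rep(1 / k, k))
  res <- .stationary_residual(p, T_reg)
  if (res > 1e-8) {
    stop(sprintf("stationary distribution failed to converge (residual %.3g)",
                 res), call. = FALSE)
  }
  p
}

.stationary_residual <- function(p, T_) {
  max(abs(drop(p %*% T_) - p))
}

.stationary_eigen <- function(T_) {
  e <- eigen(t(T_))
  i <- which.max(Re(e$values) - abs(Im(e$values)))
  p <- Re(e$vectors[, i])
  if (sum(p) < 0) p <- -p
  p[p < 0] <- 0
  p / sum(p)
}

.stationary_power <- function(T_, p0, max_iter = 100000L, tol = 1e-14) {
  p <- p0 / sum(p0)
  for (it in seq_len(max_iter)) {
    p_new <- drop(p %*% T_)
    p_new <- p_new / sum(p_new)
    if (max(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  p
}

#' Directed graph Laplacian of the m/z random walk
#'
#' L = P^(1/2) (I - T) P^(-1/2), where P is the diagonal matrix of the
#' stationary distribution p. This symmetrizing normalization makes
#' (L + t(L))/2 positive semi-definite, so its pseudoinverse is a valid
#' commute-time kernel.
#'
#' @param T_ row-stochastic transition matrix.
#' @param p stationary distribution of `T_`; all entries must exceed `eps`.
#' @param eps degeneracy guard on stationary probabilities; default 1e-12.
#' @return The Laplacian matrix L.
#' @export
directed_graph_laplacian <- function(T_, p, eps = 1e-12) {
  stopifnot(is.matrix(T_), length(p) == nrow(T_))
  bad <- which(p <= eps)
  if (length(bad)) {
    stop(sprintf(
      "degenerate stationary distribution: fragment index %d has probability <= %g",
      bad[[1]], eps
    ), call. = FALSE)
  }
  sp <- sqrt(p)
  IT <- diag(nrow(T_)) - T_
  sp * IT * rep(1 / sp, each = nrow(T_))
}

#' Pair-specific fragment-ion similarity matrix
#'
#' S is the Moore-Penrose pseudoinverse of the symmetrized Laplacian
#' (L + t(L))/2, i.e. the variance-covariance matrix of the Euclidean
#' commute-time embedding of the fragments: S\[i, i\] + S\[j, j\] - 2 S\[i, j\] is
#' the squared commute-time distance between fragments i and j. The four
#' quadrants S^XX (m x m), S^XY (m x n), S^YX, S^YY split intraspectral from
#' interspectral similarities; the alignment consumes S^XY.
#'
#' The pseudoinverse is computed by symmetric eigendecomposition; eigenvalues
#' of magnitude below `(m+n) * max(abs(eigenvalue)) * 1e-12` are treated as
#' zero.
#'
#' @param L Laplacian matrix from [directed_graph_laplacian()].
#' @param m,n block sizes of the X and Y spectra.
#' @return An object of class `similarity_decomposition` with fields `L`,
#'   `S`, `m`, `n`.
#' @export
similarity_matrix <- function(L, m, n) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L), m + n == nrow(L))
  M <- (L + t(L)) / 2
  S <- .pinv_sym(M)
  if (any(!is.finite(S))) {
    stop("pseudoinverse of the symmetrized Laplacian produced non-finite entries",
         call. = FALSE)
  }
  structure(list(L = L, S = S, m = m, n = n),
            class = "similarity_decomposition")
}

# Moore-Penrose pseudoinverse of a symmetric matrix via eigendecomposition.
.pinv_sym <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  cut <- nrow(M) * max(abs(e$values)) * 1e-12
  inv <- ifelse(abs(e$values) > cut, 1 / e$values, 0)
  e$vectors %*% (inv * t(e$vectors))
}

#' Extract a quadrant of a similarity decomposition
#'
#' @param dec a `similarity_decomposition`.
#' @param which one of `"xx"`, `"xy"`, `"yx"`, `"yy"`.
#' @return The requested block of S as a matrix.
#' @export
similarity_quadrant <- function(dec, which = c("xy", "xx", "yx", "yy")) {
  stopifnot(inherits(dec, "similarity_decomposition"))
  which <- match.arg(which)
  m <- dec$m
  n <- dec$n
  ix <- seq_len(m)
  iy <- m + seq_len(n)
  switch(which,
    xx = dec$S[ix, ix, drop = FALSE],
    xy = dec$S[ix, iy, drop = FALSE],
    yx = dec$S[iy, ix, drop = FALSE],
    yy = dec$S[iy, iy, drop = FALSE]
  )
}

#' Run the full similarity-matrix construction for a spectrum pair
#'
#' Chains difference matrix -> difference-frequency counts -> transition
#' matrix -> stationary distribution -> directed graph Laplacian ->
#' pseudoinverse, returning the decomposition with all intermediate stages
#' attached (useful for inspection and debugging dumps).
#'
#' @param x,y [fragmentation_spectrum()] objects.
#' @param tolerance m/z-difference counting window (Th); default 0.01.
#' @return A `similarity_decomposition` with extra fields `D`, `C`, `T`, `p`,
#'   and `concat_mz`.
#' @examples
#' a <- fragmentation_spectrum(c(100, 150, 230), 231)
#' b <- fragmentation_spectrum(c(114, 164, 244), 245)
#' dec <- pair_similarity(a, b)
#' similarity_quadrant(dec, "xy")
#' @export
pair_similarity <- function(x, y, tolerance = 0.01) {
  pair <- spectrum_pair(x, y)
  dm <- pairwise_difference_matrix(pair)
  cm <- mz_difference_counts(dm, tolerance)
  T_ <- transition_matrix(cm)
  p <- stationary_distribution(T_)
  L <- directed_graph_laplacian(T_, p)
  dec <- similarity_matrix(L, pair$m, pair$n)
  dec$D <- dm$D
  dec$C <- cm$C
  dec$T <- T_
  dec$p <- p
  dec$concat_mz <- pair$concat_mz
  dec
}

#' Dump the similarity-construction matrices as delimited text
#'
#' Writes D, C, T, and S (tab-separated, with a header row of the
#' concatenated fragment m/z values) into a directory, one file per matrix.
#' Intended for debugging and inspection.
#'
#' @param dec a decomposition from [pair_similarity()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
dump_similarity_matrices <- function(dec, dir) {
  stopifnot(inherits(dec, "similarity_decomposition"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- sprintf("%.6f", dec$concat_mz)
  paths <- character()
  for (name in c("D", "C", "T", "S")) {
    M <- dec[[name]]
    if (is.null(M)) next
    path <- file.path(dir, paste0(tolower(name), ".tsv"))
    utils::write.table(
      stats::setNames(as.data.frame(M), header), path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, path)
  }
  invisible(paths)
}
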