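#' Sample an order-preserving permutation of a concatenated m/z list
#'
#' The null hypothesis of the permutation test is that m/z values are
#' exchangeable between the two spectra as long as both hypothetical spectra
#' X' and Y' remain m/z ordered. A valid reassignment is therefore a choice
#' of which m of the m+n concatenated values belong to X' (sorted ascending;
#' the remaining n, sorted, form Y'), and there are choose(m+n, m) of them.
#' This function samples one uniformly, using R's global random number
#' stream, and returns the induced index permutation `perm`: position i of
#' the permuted concatenation holds original index `perm[i]`.
#'
#' @param concat_mz concatenated m/z vector (X then Y, each block ascending).
#' @param m,n block sizes; `m + n` must equal `length(concat_mz)`.
#' @return An object of class `permutation_plan` with fields `perm`, `m`, `n`.
#' @examples
#' set.seed(1)
#' sample_order_preserving_permutation(c(100, 150, 120), m = 2, n = 1)
#' @export
sample_order_preserving_permutation <- function(concat_mz, m, n) {
  stopifnot(is.numeric(concat_mz), m >= 1L, n >= 1L,
            m + n == length(concat_mz))
  chosen <- sort(sample.int(m + n, m))
  rest <- setdiff(seq_len(m + n), chosen)
  xidx <- chosen[order(concat_mz[chosen])]
  yidx <- rest[order(concat_mz[rest])]
  structure(list(perm = c(xidx, yidx), m = m, n = n),
            class = "permutation_plan")
}

#' Alignment score after symmetric permutation of the similarity matrix
#'
#' Applies the plan's index permutation symmetrically to the rows and columns
#' of the full (m+n) x (m+n) similarity matrix S, extracts the new top-right
#' m x n interspectral quadrant (X' vs Y'), and returns its zero-gap
#' alignment score. With the identity plan this is exactly the observed
#' alignment score.
#'
#' @param S full similarity matrix, or a `similarity_decomposition`.
#' @param plan a `permutation_plan`.
#' @return The permuted alignment score.
#' @export
permuted_score <- function(S, plan) {
  if (inherits(S, "similarity_decomposition")) S <- S$S
  stopifnot(inherits(plan, "permutation_plan"),
            is.matrix(S), nrow(S) == ncol(S))
  if (nrow(S) != plan$m + plan$n) {
    stop("permutation plan size does not match the similarity matrix",
         call. = FALSE)
  }
  quad <- S[plan$perm[seq_len(plan$m)],
            plan$perm[plan$m + seq_len(plan$n)], drop = FALSE]
  align_score_fast(quad)
}

# Builds the k x m x n stack of permuted interspectral quadrants for a batch
# of plans, indexing S directly instead of materializing full permutations.
.permuted_quadrant_stack <- function(S, plans, m, n) {
  k <- length(plans)
  stack <- array(0, dim = c(k, m, n))
  for (s in seq_len(k)) {
    perm <- plans[[s]]$perm
    stack[s, , ] <- S[perm[seq_len(m)], perm[m + seq_len(n)]]
  }
  stack
}

#' Monte Carlo permutation p-value of an alignment score
#'
#' Estimates the probability that a random order-preserving reassignment of
#' m/z values between the two spectra attains an alignment score exceeding
#' the observed one. Permutations are evaluated in stages (default 10, 100,
#' 1000 total iterations); after each stage the running p-value is
#'
#'   p = max( count / k, 1 / k ),
#'
#' where k is the iterations so far and `count` is the number of permuted
#' scores greater than or equal to the observed score (ties within `tie_tol`
#' count as exceedances: the conservative convention that keeps the Monte
#' Carlo p-value valid, and the reason a spectrum pair whose alignment score
#' cannot be beaten *or tied* by any permutation -- and only such a pair --
#' can reach the floor 1/k). After the second and later stages, estimation
#' stops early unless the p-value improved at least twofold over the previous
#' stage or is still at its resolution floor 1/k.
#'
#' @param S full similarity matrix or a `similarity_decomposition` from
#'   [pair_similarity()] (which carries `m`, `n`, and `concat_mz`).
#' @param observed the observed alignment score.
#' @param m,n block sizes (taken from the decomposition when `S` is one).
#' @param concat_mz concatenated m/z vector, X block then Y block; needed to
#'   order sampled value subsets (taken from the decomposition when `S` is
#'   one).
#' @param schedule strictly increasing cumulative iteration counts;
#'   default `c(10, 100, 1000)`.
#' @param seed integer seed for the permutation stream (required: the test is
#'   only reproducible under an explicit seed).
#' @param tie_tol numerical tie tolerance on scores; default 1e-9.
#' @return An object of class `pvalue_result` with fields `pvalue`,
#'   `iterations`, `null_scores`, and `stopped_early`.
#' @export
monte_carlo_pvalue <- function(S, observed, m = NULL, n = NULL,
                               concat_mz = NULL,
                               schedule = c(10L, 100L, 1000L),
                               seed = NULL, tie_tol = 1e-9) {
  if (inherits(S, "similarity_decomposition")) {
    m <- S$m
    n <- S$n
    concat_mz <- S$concat_mz
    S <- S$S
  }
  stopifnot(is.matrix(S), !is.null(m), !is.null(n), m + n == nrow(S))
  if (is.null(concat_mz) || length(concat_mz) != m + n) {
    stop("'concat_mz' of length m + n is required to sample permutations",
         call. = FALSE)
  }
  if (!is.finite(observed)) {
    stop("'observed' alignment score must be finite", call. = FALSE)
  }
  if (length(schedule) < 1L || any(schedule <= 0) ||
      any(diff(schedule) <= 0)) {
    stop("'schedule' must be strictly increasing positive iteration counts",
         call. = FALSE)
  }
  if (is.null(seed)) {
    stop("'seed' is required for a reproducible permutation test",
         call. = FALSE)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))

  null_scores <- numeric(0)
  count <- 0L
  p_prev <- NULL
  pvalue <- 1
  stopped_early <- FALSE
  done <- 0L
  for (stage in seq_along(schedule)) {
    k_target <- schedule[[stage]]
    n_new <- k_target - done
    plans <- replicate(
      n_new,
      sample_order_preserving_permutation(concat_mz, m, n),
      simplify = FALSE
    )
    stack <- .permuted_quadrant_stack(S, plans, m, n)
    scores <- align_score_batch(stack)
    null_scores <- c(null_scores, scores)
    count <- count + sum(scores >= observed - tie_tol)
    done <- k_target
    pvalue <- max(count / done, 1 / done)
    if (stage < length(schedule)) {
      if (!is.null(p_prev) &&
          !(pvalue <= p_prev / 2 || pvalue == 1 / done)) {
        stopped_early <- TRUE
        break
      }
      p_prev <- pvalue
    }
  }
  structure(
    list(pvalue = pvalue, iterations = done, null_scores = null_scores,
         stopped_early = stopped_early),
    class = "pvalue_result"
  )
}

#' @export
print.pvalue_result <- function(x, ...) {
  cat(sprintf("pvalue_result: p = %.4g after %d permutations%s\n",
              x$pvalue, x$iterations,
              if (x$stopped_early) " (stopped early)" else ""))
  invisible(x)
}

#' Stage p-value from a null-score count
#'
#' The running Monte Carlo p-value given `count` exceedances out of `k`
#' permutations: `max(count / k, 1 / k)`, floored at the test's resolution.
#'
#' @param count number of permuted scores at or above the observed score.
#' @param k permutations evaluated.
#' @return The p-value.
#' @export
pvalue_from_counts <- function(count, k) {
  stopifnot(k >= 1L, count >= 0L, count <= k)
  max(count / k, 1 / k)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
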