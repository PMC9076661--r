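#' Parameter set for pair scoring and hit filtering
#'
#' Collects the tunable parameters of the method: the m/z-difference counting
#' tolerance, the Monte Carlo iteration schedule, the hit-filtering cutoffs
#' (score >= 0.7, p <= 0.05, matched ions >= 10 by default), and the global
#' seed from which per-pair permutation seeds are derived.
#'
#' @param tolerance m/z-difference counting window, Th; default 0.01.
#' @param schedule cumulative Monte Carlo iteration stages;
#'   default `c(10, 100, 1000)`.
#' @param score_min minimum alignment score for a hit; default 0.7.
#' @param p_max maximum p-value for a hit; default 0.05.
#' @param min_matched_ions minimum aligned-ion count for a hit; default 10.
#' @param seed global integer seed; default 0.
#' @return An object of class `simile_params`.
#' @export
simile_params <- function(tolerance = 0.01, schedule = c(10L, 100L, 1000L),
                          score_min = 0.7, p_max = 0.05,
                          min_matched_ions = 10L, seed = 0L) {
  stopifnot(tolerance >= 0, score_min >= 0, p_max > 0, p_max <= 1,
            min_matched_ions >= 0, length(schedule) >= 1L,
            all(schedule > 0), !is.unsorted(schedule, strictly = TRUE))
  structure(
    list(tolerance = tolerance, schedule = as.integer(schedule),
         score_min = score_min, p_max = p_max,
         min_matched_ions = as.integer(min_matched_ions),
         seed = as.integer(seed)),
    class = "simile_params"
  )
}

#' Score one spectrum pair end to end
#'
#' Runs the full chain for a pair of spectra: similarity-matrix construction,
#' zero-gap alignment of the interspectral quadrant, and the Monte Carlo
#' permutation p-value. The pair is internally oriented by spectrum id so
#' that `compare_pair(a, b)` and `compare_pair(b, a)` are identical,
#' including the p-value; results are deterministic for a fixed seed.
#'
#' @param a,b [fragmentation_spectrum()] objects, each with >= 2 fragments.
#' @param params a [simile_params()].
#' @param seed optional integer overriding the per-pair seed derived from
#'   `params$seed` and the two spectrum ids.
#' @return A one-row `data.frame` of class `pair_score` with columns `id_a`,
#'   `id_b`, `score`, `pvalue`, `n_matched`, `n_iterations`.
#' @examples
#' a <- fragmentation_spectrum(c(100, 150, 230, 280), 281, spectrum_id = "a")
#' compare_pair(a, a, simile_params(schedule = c(10, 100)))
#' @export
compare_pair <- function(a, b, params = simile_params(), seed = NULL) {
  stopifnot(is_spectrum(a), is_spectrum(b),
            inherits(params, "simile_params"))
  for (s in list(a, b)) {
    if (length(s$mz) < 2L) {
      stop(sprintf(
        "spectrum '%s' is degenerate: at least 2 fragments are required",
        s$spectrum_id
      ), call. = FALSE)
    }
  }
  ids <- c(a$spectrum_id, b$spectrum_id)
  if (ids[[2]] < ids[[1]]) {  # canonical orientation for exact symmetry
    tmp <- a; a <- b; b <- tmp
    ids <- rev(ids)
  }
  if (is.null(seed)) seed <- .pair_seed(params$seed, ids[[1]], ids[[2]])
  dec <- pair_similarity(a, b, tolerance = params$tolerance)
  aln <- align_dp(similarity_quadrant(dec, "xy"))
  pv <- monte_carlo_pvalue(dec, aln$score, schedule = params$schedule,
                           seed = seed)
  out <- data.frame(
    id_a = ids[[1]], id_b = ids[[2]],
    score = aln$score, pvalue = pv$pvalue,
    n_matched = n_matched_ions(aln), n_iterations = pv$iterations,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pair_score", class(out))
  out
}

# Deterministic per-pair seed: a polynomial rolling hash of the ordered id
# pair mixed with the global seed, reduced below 2^31 so results do not
# depend on the order pairs are visited in.
.pair_seed <- function(global_seed, id_a, id_b) {
  key <- paste(id_a, id_b, sep = "\r")
  h <- as.double(global_seed %% 2147483647L)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' All-vs-all pair scoring
#'
#' Scores every unordered pair among the input spectra, returning one row per
#' pair (n(n-1)/2 rows). Per-pair seeds are derived from the sorted id pair
#' and the global seed, so the table does not depend on the input order.
#'
#' @param spectra list of spectra with unique, non-empty ids.
#' @param params a [simile_params()].
#' @param progress print a progress message every `progress` pairs; 0 (the
#'   default) is silent.
#' @return A `data.frame` edge table (class `edge_table`) sorted by
#'   (`id_a`, `id_b`).
#' @export
all_vs_all <- function(spectra, params = simile_params(), progress = 0L) {
  stopifnot(is.list(spectra))
  if (length(spectra) < 2L) {
    stop("all-vs-all comparison requires at least 2 spectra", call. = FALSE)
  }
  ids <- vapply(spectra, function(s) s$spectrum_id, "")
  if (anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("spectra must carry unique, non-empty ids", call. = FALSE)
  }
  ord <- order(ids)
  spectra <- spectra[ord]
  n <- length(spectra)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      rows[[k]] <- compare_pair(spectra[[i]], spectra[[j]], params)
      if (progress > 0L && k %% progress == 0L) {
        message(sprintf("scored %d pairs", k))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Filter an edge table with the hit cutoffs
#'
#' Keeps rows with `score >= score_min`, `pvalue <= p_max`, and
#' `n_matched >= min_matched_ions` (all boundaries inclusive). Idempotent;
#' the output is always a subset of the input.
#'
#' @param table an edge table from [all_vs_all()] or [read_score_table()].
#' @param params a [simile_params()] supplying the cutoffs.
#' @return The filtered edge table.
#' @export
filter_hits <- function(table, params = simile_params()) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) return(table)
  keep <- table$score >= params$score_min &
    table$pvalue <= params$p_max &
    table$n_matched >= params$min_matched_ions
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a pair-score table
#'
#' Tab-separated with header `id_a id_b score pvalue n_matched n_iterations`,
#' the interchange format between scoring, filtering, and networking.
#'
#' @param table an edge table.
#' @param path file path.
#' @return `write_score_table` returns the path invisibly;
#'   `read_score_table` returns the edge table.
#' @export
write_score_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(id_a = "character",
                                          id_b = "character"))
  need <- c("id_a", "id_b", "score", "pvalue", "n_matched")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    stop(sprintf("score table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  class(out) <- c("edge_table", "data.frame")
  out
}
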