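#' Block molecules: synthetic ground truth for spectral alignment
#'
#' A block molecule is a linear chain of mass blocks, optionally carrying
#' modifier mass deltas on individual blocks. Fragmenting it along the
#' backbone (one fragment per non-empty contiguous block run) yields a
#' spectrum whose interspectral m/z-difference structure against a modified
#' copy is known exactly: a modifier on block b shifts precisely the
#' fragments whose run contains b. This gives related/unrelated spectrum
#' pairs with known fragment correspondences for testing every stage of the
#' method without any external data.
#'
#' @param block_masses positive block masses, Da; at least 2 blocks.
#' @param modifiers named numeric vector of mass deltas, names are block
#'   indices (e.g. `c("2" = 14.0157)`); may be negative.
#' @param adduct_mass ionization mass shift, Da; default +1.007276 (proton,
#'   positive mode).
#' @return An object of class `block_molecule`.
#' @examples
#' m <- block_molecule(c(100, 120, 140))
#' enumerate_fragments(m)$mz
#' @export
block_molecule <- function(block_masses, modifiers = numeric(0),
                           adduct_mass = 1.007276) {
  stopifnot(is.numeric(block_masses), length(block_masses) >= 2L,
            all(block_masses > 0))
  if (length(modifiers)) {
    idx <- suppressWarnings(as.integer(names(modifiers)))
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(block_masses))) {
      stop("modifier names must be valid block indices", call. = FALSE)
    }
  }
  structure(
    list(block_masses = as.numeric(block_masses),
         modifiers = modifiers, adduct_mass = adduct_mass),
    class = "block_molecule"
  )
}

#' Enumerate backbone fragments of a block molecule
#'
#' Produces one fragment per non-empty contiguous block run (k blocks give
#' k(k+1)/2 runs): fragment m/z = sum of the run's block masses + the
#' modifier deltas of blocks in the run + the adduct mass. Exact duplicate
#' masses are merged, so the spectrum may have fewer peaks than runs. The
#' precursor is the full-chain fragment.
#'
#' @param mol a [block_molecule()].
#' @param spectrum_id identifier for the resulting spectrum.
#' @return A [fragmentation_spectrum()]; the run for each peak is recorded in
#'   `metadata$runs` (a two-column matrix of run start/end block indices, one
#'   row per *run*, with `metadata$run_mz` the corresponding m/z values).
#' @export
enumerate_fragments <- function(mol, spectrum_id = "") {
  stopifnot(inherits(mol, "block_molecule"))
  masses <- mol$block_masses
  if (length(mol$modifiers)) {
    idx <- as.integer(names(mol$modifiers))
    masses[idx] <- masses[idx] + as.numeric(mol$modifiers)
  }
  k <- length(masses)
  runs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  runs <- runs[order(runs[, 1], runs[, 2]), , drop = FALSE]
  colnames(runs) <- c("start", "end")
  csum <- c(0, cumsum(masses))
  run_mass <- csum[runs[, "end"] + 1L] - csum[runs[, "start"]]
  run_mz <- run_mass + mol$adduct_mass
  if (any(run_mz <= 0)) {
    stop("fragment generation produced a non-positive m/z; check modifiers",
         call. = FALSE)
  }
  mz <- sort(unique(run_mz))
  fragmentation_spectrum(
    mz = mz,
    precursor_mz = sum(masses) + mol$adduct_mass,
    spectrum_id = spectrum_id,
    adduct = if (mol$adduct_mass >= 0) "[M+H]+" else "[M-H]-",
    metadata = list(runs = runs, run_mz = run_mz)
  )
}

#' Generate a related spectrum pair from one block skeleton
#'
#' Spectrum A fragments the base molecule; spectrum B fragments the same
#' skeleton with `modifiers` applied (added to any modifiers already on the
#' base). The pair is related by construction and `shared_fragment_map`
#' records the run-to-run correspondence between the two spectra.
#'
#' @param base a [block_molecule()].
#' @param modifiers named numeric vector of modifier deltas, names = block
#'   indices.
#' @param id_a,id_b spectrum ids; defaults `"A"` and `"B"`.
#' @return A list of class `ground_truth_pair` with fields `spectrum_a`,
#'   `spectrum_b`, `related = TRUE`, `modifiers`, and `shared_fragment_map`
#'   (a data.frame of run start/end and the corresponding m/z in each
#'   spectrum).
#' @export
make_related_pair <- function(base, modifiers, id_a = "A", id_b = "B") {
  stopifnot(inherits(base, "block_molecule"))
  mod_all <- base$modifiers
  for (nm in names(modifiers)) {
    mod_all[nm] <- if (!is.null(mod_all[nm]) && !is.na(mod_all[nm])) {
      mod_all[[nm]] + modifiers[[nm]]
    } else {
      modifiers[[nm]]
    }
  }
  modified <- block_molecule(base$block_masses, mod_all, base$adduct_mass)
  sa <- enumerate_fragments(base, id_a)
  sb <- enumerate_fragments(modified, id_b)
  map <- data.frame(
    start = sa$metadata$runs[, "start"],
    end = sa$metadata$runs[, "end"],
    mz_a = sa$metadata$run_mz,
    mz_b = sb$metadata$run_mz
  )
  structure(
    list(spectrum_a = sa, spectrum_b = sb, related = TRUE,
         modifiers = modifiers, shared_fragment_map = map),
    class = "ground_truth_pair"
  )
}

#' Random null spectrum
#'
#' Draws `n_fragments` distinct m/z values uniformly in `mz_range` (sorted
#' ascending) using R's global random number stream. A minimum spacing --
#' by default twice the counting tolerance of 0.01 Th -- is enforced by
#' redrawing, so null spectra carry no accidental repeated-difference
#' structure at the tolerance scale.
#'
#' @param n_fragments number of peaks, >= 1.
#' @param mz_range length-2 numeric range, Th; default `c(50, 500)`.
#' @param min_spacing minimum distance between adjacent peaks; default 0.02.
#' @param spectrum_id identifier.
#' @return A [fragmentation_spectrum()] with precursor just above the largest
#'   fragment.
#' @export
random_spectrum <- function(n_fragments, mz_range = c(50, 500),
                            min_spacing = 0.02, spectrum_id = "") {
  stopifnot(n_fragments >= 1L, length(mz_range) == 2L,
            mz_range[[2]] > mz_range[[1]])
  if ((n_fragments - 1L) * min_spacing >= diff(mz_range)) {
    stop("m/z range too small for the requested peak count and spacing",
         call. = FALSE)
  }
  for (try in seq_len(1000L)) {
    mz <- sort(stats::runif(n_fragments, mz_range[[1]], mz_range[[2]]))
    if (n_fragments == 1L || min(diff(mz)) >= min_spacing) {
      return(fragmentation_spectrum(
        mz = mz,
        precursor_mz = max(mz) + 1.007276,
        spectrum_id = spectrum_id
      ))
    }
  }
  stop("failed to draw a spectrum with the requested minimum spacing",
       call. = FALSE)
}

# Common small-molecule modifier masses (Da): CH2, O, H2, C2H2O, H2O loss,
# CO, glycosyl-like C6H10O5.
.modifier_masses <- c(14.01565, 15.99491, 2.01565, 42.01057, -18.01056,
                      27.99491, 162.05282)

#' Random block molecule
#'
#' Blocks are drawn uniformly from `mass_range`; with the defaults (five
#' blocks of 60-180 Da) a molecule fragments into 15 backbone fragments,
#' comparable to a typical centroided small-molecule library spectrum.
#'
#' @param n_blocks number of blocks; default 5.
#' @param mass_range block-mass range, Da; default `c(60, 180)`.
#' @param adduct_mass see [block_molecule()].
#' @return A [block_molecule()].
#' @export
random_block_molecule <- function(n_blocks = 5L, mass_range = c(60, 180),
                                  adduct_mass = 1.007276) {
  block_molecule(stats::runif(n_blocks, mass_range[[1]], mass_range[[2]]),
                 adduct_mass = adduct_mass)
}

#' Generate a ground-truth set of related and unrelated pairs
#'
#' Related pairs share a random block skeleton and differ by one or two
#' modifiers (drawn from common structural mass shifts such as CH2, O, or a
#' glycosyl unit) placed on distinct random blocks. Unrelated pairs are two
#' independent uniform-random spectra with the same fragment count as the
#' block molecules. This is the study condition for null calibration and for
#' related/unrelated discrimination.
#'
#' @param n_related,n_unrelated pair counts; defaults 50 each.
#' @param seed integer seed; required for reproducibility.
#' @param n_blocks blocks per molecule; default 5.
#' @param mass_range block-mass range; default `c(60, 180)`.
#' @param n_modifiers_range modifiers per related pair, sampled uniformly
#'   from this inclusive range; default `c(1, 2)`.
#' @return A list of `ground_truth_pair` objects (unrelated pairs carry
#'   `related = FALSE` and no fragment map), each with unique spectrum ids.
#' @export
synth_pair_set <- function(n_related = 50L, n_unrelated = 50L, seed = 0L,
                           n_blocks = 5L, mass_range = c(60, 180),
                           n_modifiers_range = c(1L, 2L)) {
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n_frag <- n_blocks * (n_blocks + 1L) / 2L
  pairs <- vector("list", n_related + n_unrelated)
  for (i in seq_len(n_related)) {
    base <- random_block_molecule(n_blocks, mass_range)
    n_mod <- sample(seq(n_modifiers_range[[1]], n_modifiers_range[[2]]), 1L)
    blocks <- sample.int(n_blocks, n_mod)
    deltas <- sample(.modifier_masses, n_mod, replace = TRUE)
    names(deltas) <- as.character(blocks)
    pairs[[i]] <- make_related_pair(
      base, deltas,
      id_a = sprintf("rel%03d_a", i), id_b = sprintf("rel%03d_b", i)
    )
  }
  for (i in seq_len(n_unrelated)) {
    sa <- random_spectrum(n_frag, spectrum_id = sprintf("nul%03d_a", i))
    sb <- random_spectrum(n_frag, spectrum_id = sprintf("nul%03d_b", i))
    pairs[[n_related + i]] <- structure(
      list(spectrum_a = sa, spectrum_b = sb, related = FALSE,
           modifiers = NULL, shared_fragment_map = NULL),
      class = "ground_truth_pair"
    )
  }
  pairs
}

#' Write a synthetic pair set as MGF plus a ground-truth table
#'
#' Emits `spectra.mgf` (all spectra) and `ground_truth.tsv` (pair ids,
#' related flag, modifier masses) into a directory, the on-disk form used by
#' the command-line `synth` subcommand.
#'
#' @param pairs output of [synth_pair_set()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the two paths written.
#' @export
write_synthetic_set <- function(pairs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spectra <- unlist(lapply(pairs, function(p) list(p$spectrum_a, p$spectrum_b)),
                    recursive = FALSE)
  mgf_path <- file.path(dir, "spectra.mgf")
  write_mgf(spectra, mgf_path)
  truth <- data.frame(
    id_a = vapply(pairs, function(p) p$spectrum_a$spectrum_id, ""),
    id_b = vapply(pairs, function(p) p$spectrum_b$spectrum_id, ""),
    related = vapply(pairs, function(p) p$related, NA),
    modifier_masses = vapply(pairs, function(p) {
      if (is.null(p$modifiers)) "" else paste(sprintf("%.5f", p$modifiers),
                                              collapse = ",")
    }, "")
  )
  truth_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mgf_path, truth_path))
}
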