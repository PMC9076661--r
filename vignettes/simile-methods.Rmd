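---
title: "Aligning fragmentation spectra with significance: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning fragmentation spectra with significance: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simileR)
```

## The model

The package scores the similarity of two fragmentation spectra X (m
fragments) and Y (n fragments) by aligning *substitutable* fragment ions
rather than identical m/z values. The premise: a structural modification to
a molecule adds or removes fragmentation reactions, and fragments whose
fragmentation paths survive the modification appear in both spectra shifted
by characteristic m/z differences. Fragments cross-linked by *recurrent* m/z
differences are therefore likely substitutable, while a single coincidental
difference is weak evidence.

This is operationalized as a random walk on the m+n concatenated fragments.
The signed outer-difference matrix `D` is reduced blockwise to a count
matrix `C` (each difference is replaced by the number of differences in its
spectrum's block within a tolerance window of it — every difference matches
at least itself, so `C >= 1` and the walk is irreducible and aperiodic).
Row-normalizing gives a transition matrix `T`; its stationary distribution
`p` (the principal left eigenvector, `pT = p`) weights the directed graph
Laplacian `L = P^{1/2}(I - T)P^{-1/2}`. The similarity matrix

S = pinv( (L + Lᵀ) / 2 )

is the variance–covariance matrix of the Euclidean commute-time embedding:
`S[i,i] + S[j,j] - 2 S[i,j]` is the squared expected round-trip time of the
walk between fragments i and j, so `S` is a valid kernel in which strongly
cross-linked fragments have high covariance. Because the permutation test
exchanges fragments *between* spectra, intraspectral and interspectral
similarities must live in the same space — hence one (m+n)×(m+n) matrix
with quadrants S^XX, S^XY, S^YX, S^YY, not a rectangular score matrix.

The interspectral quadrant S^XY is aligned by Needleman–Wunsch with a gap
penalty of **zero**:

A(i,j) = max( A(i−1,j−1) + S_ij, A(i−1,j), A(i,j−1) ),  A(i,0) = A(0,j) = 0.

Gaps are free because modified molecules legitimately gain or lose
fragments; the score is driven entirely by the aligned (diagonal) steps. The
terminal value is the alignment score — never negative, and equal to the
maximum over all monotone matchings of the summed similarities, floored at
zero. Alignment (rather than maximum-weight bipartite matching) is a
deliberate constraint: commute-time similarity is blind to the magnitude of
mass differences, and the m/z-order restriction stochastically penalizes
matchings that would pair fragments across implausibly large mass gaps.

## Significance

The null hypothesis is that m/z values are exchangeable between the spectra
so long as both hypothetical spectra X′ and Y′ remain m/z-ordered. A null
sample is a uniform draw of which m of the m+n values form X′ (there are
choose(m+n, m) such assignments); the induced index permutation is applied
to rows and columns of `S` symmetrically and the new top-right quadrant is
re-aligned. The p-value after k permutations is

p = max( #\{null score ≥ observed score\} / k, 1/k ),

estimated in stages of 10, 100, and 1000 cumulative iterations; after the
second stage, estimation stops early unless p improved at least twofold over
the previous stage or is still at its resolution floor 1/k. Scores within
1e-9 of the observed score are treated as ties and counted as exceedances —
the conservative convention that keeps the Monte Carlo estimate a valid
p-value.

### Degenerate inputs and tie handling

Two corner cases shaped this choice, and both are worth understanding
before interpreting p-values on synthetic data:

* **Unstructured pairs.** For spectra with no repeated m/z differences at
  the tolerance scale (e.g. uniform random peak lists), `C` is the identity
  structure plus ones, and `S` has *all-negative off-diagonal* entries: the
  observed score and every permuted score are exactly 0. The statistic is
  constant under the null, so no permutation evidence exists either way.
  With ties counted, such pairs get p = 1 (the test is conservative where
  it is uninformative) and stop at 100 iterations. Had ties been excluded,
  every structureless pair would report the floor p = 1/k — maximal
  significance from zero signal.
* **Self- and near-self pairs.** When the two spectra share exact m/z
  values, every choice between duplicate copies yields a permutation
  mathematically equivalent to the identity (2^d of them for d duplicated
  values — about 2% of all plans for an 8-fragment self-comparison). Their
  permuted scores tie the observed score, so the p-value of a spectrum
  aligned against itself converges to that equivalence mass (~0.02), not to
  the 1/1000 floor. This is a property of the null (the observed
  configuration genuinely is not unique under order-preserving exchange),
  not an estimation artifact; p-values for *distinct* related molecules,
  which share few or no exact m/z values, are unaffected and routinely
  reach the floor.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `tolerance` | 0.01 | Th | window within which two m/z differences count as the same; 0.01 suits high-resolution library spectra, 0.5 reproduces low-resolution cosine conventions |
| `schedule` | 10, 100, 1000 | iterations | staged Monte Carlo budget; the floor p is 1/max(schedule) |
| `score_min` | 0.7 | — | hit-filter score cutoff (inclusive) |
| `p_max` | 0.05 | — | hit-filter p cutoff (inclusive) |
| `min_matched_ions` | 10 | ions | hit-filter cutoff on aligned pairs with positive contribution (inclusive) |
| network `score_min` | 1.0 | — | stricter edge cutoff for molecular networks |
| network `top_k` | 10 | edges | mutual top-k: an edge survives only if it ranks in the top k at *both* endpoints |
| network `max_component` | 100 | nodes | oversized components repeatedly lose their weakest edge |
| `seed` | 0 | — | global seed; per-pair seeds are a stable hash of the sorted id pair, so all-vs-all tables are independent of input order |

Intensities are parsed and carried through the readers/writer for
interoperability but never consumed: the method operates on m/z values
alone, and library spectra are used as-is (peak merging via
`canonicalize()` is opt-in, default tolerance 0).

## Numerical choices

* Stationary distribution: eigendecomposition of `t(T)`, power-iteration
  refinement if the residual exceeds 1e-10, and only on failure a uniform
  teleportation of 1e-8 (warned); counts ≥ 1 make this fallback unreachable
  in normal use.
* Pseudoinverse: symmetric eigendecomposition; eigenvalues below
  `(m+n) · max|λ| · 1e-12` are treated as zero.
* Difference counting uses closed inequalities on *signed* differences, and
  the diagonal zeros of `D` participate like any other entry.
* Traceback ties prefer diagonal over up over left, yielding the
  co-optimal matching with the most aligned pairs, deterministically; only
  diagonal steps with strictly positive contribution are reported as
  matched ions.
* The score-only path iterates min(m, n) times using element-wise maxima
  and prefix maxima; the batched version evaluates whole permutation stacks
  with log-shift rolling maxima. Both agree with the traceback DP to 1e-9.
* Network determinism: score ties in top-k ranking and in component pruning
  are broken by lexicographic edge id.

## The synthetic generator

`block_molecule()` / `synth_pair_set()` emulate linear backbones that
fragment at block boundaries: one fragment per contiguous block run, so a
five-block molecule yields 15 fragments, comparable to a centroided
small-molecule library spectrum. Defaults: block masses uniform in 60–180 Da
(amino-acid/sugar-scale substructures), proton adduct (+1.007276 Da), and
per related pair one or two modifiers drawn from common structural shifts
(CH2 +14.016, O +15.995, H2 +2.016, C2H2O +42.011, H2O −18.011, CO +27.995,
C6H10O5 +162.053 Da) on distinct random blocks. A modifier shifts exactly
the fragments whose run contains the modified block — the multi-site,
delocalized-difference regime the aligner targets. Unrelated pairs are
uniform random spectra with matched fragment counts and a minimum spacing of
twice the counting tolerance.

What the generator does **not** emulate: intensity structure, noise and
contaminant peaks, rearrangement chemistry, isotopes, multiple adducts, or
mass-dependent instrument error. Passing tests on this ground truth
therefore demonstrate the *mechanics* of the method — that recurrent
difference structure is detected, aligned, and separated from unstructured
nulls — not its sensitivity/specificity on real libraries.

## Problem sizes used by the test suite

Oracle equivalence is checked on 200 random pairs with 2–6 fragments per
spectrum (every stage against nested-loop brute force, 1e-8), alignment on
500 random matrices up to 5×5 against exhaustive enumeration of monotone
matchings plus 200 5×7 fast/batch comparisons (1e-9), permutation uniformity
on 3000 draws over the 3 enumerable plans at m=2, n=1 (χ², α = 0.001), null
behavior on 1000 uniform-random pairs, and end-to-end discrimination on 50
related plus 50 unrelated block-molecule pairs under fixed seeds.

## Known limitations

* Only protonated/deprotonated adducts are contemplated; no multi-adduct or
  multi-charge handling.
* Raw alignment scores are not normalized; cutoffs (0.7 for hits, 1.0 for
  networks) are conventions for this score scale, and an optional
  self-alignment normalization is not applied by default.
* The p-value floor is 1/max(schedule); deeper significance requires a
  longer schedule at linear cost.
* Very large, well-aligning spectra make the permutation stage expensive
  (O(k·m·n) per pair), as the early-stopping schedule then runs to
  completion.
* The maximum-common-substructure helper computes only the Jaccard
  coefficient and rubric from given bond counts; finding the substructure
  overlap itself requires an external cheminformatics toolkit.
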