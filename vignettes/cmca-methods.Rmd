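---
title: "Conservation–mutation correlation analysis: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation–mutation correlation analysis: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmca)
```

## The model

An aligned protein family of N sequences and L0 columns is viewed over an
alphabet of M = 21 residue types: the 20 amino acids (indices 1–20) and
the alignment gap, treated as a special type with index 0. Three objects
carry the analysis:

1. **Binary tensor** `X[i, k, l]`: 1 when sequence *i* carries type *k* at
   column *l*. Exactly one type per (sequence, column) cell.
2. **Frequency matrix** `F[k, l]`: integer counts of each type per column;
   every column sums to N.
3. **Mutation matrix** `T[k, l]`: the mutative factor of each type at each
   column (below).

Columns dominated by gaps are removed before any correlation is computed:
the natural-residue fraction `q[l]` (counts of the 20 amino acids divided
by N) must reach the gap threshold (default 0.20), i.e. a column with more
than 80 % gaps is deleted. The comparison is deliberately *strict* — a
column at exactly 20 % natural residues is kept — because the deletion
rule is phrased as "fewer than 20 %". The surviving columns keep their
original 1-based numbering in a position map, and a reference sequence can
be mapped so results are also reported in the residue numbering of a
well-characterized family member (gapped reference columns are marked
absent, rendered `-`).

### The mutative factor

The per-type mutability score at a column with `n` observed residue types
(gap included) in a family of N sequences is

    t(f; N, n) = (n − 1) / (|f − N/n| + 1).

This closed form is fixed by four properties we require of a mutability
measure:

* an invariant column (n = 1) must score 0 for every type — the `n − 1`
  numerator;
* the score must be finite everywhere, including at the average frequency
  f = N/n — the `+ 1` in the denominator;
* for fixed `n` the score must be maximal exactly at f = N/n: a type
  sitting at the column's average frequency is the one drifting freely,
  whereas types far more frequent (conserved) or far less frequent
  (absent/forbidden) than average are evolutionarily pinned;
* the peak value is n − 1, so more diversified columns can score higher:
  with N = 100 and n = 20 the maximum is 19, attained at f = 5.

`N/n` is kept as an exact real; `f` is an integer count. The acceptance
suite verifies all four properties exhaustively over integer frequencies
for N in {10, 100, 240} and every n in 1..21, plus strict monotone decay
of t with |f − N/n|.

### Correlation matrices

Both flavors correlate 21-dimensional *column profiles* with the Pearson
coefficient: conservation uses the raw frequency profiles `F[., l]`,
mutation uses the mutative-factor profiles `T[., l]`. Internally the
population covariance (divisor M) over the type axis is formed and
normalized; the divisor cancels in the correlation, which the test suite
checks explicitly by comparing against an independent sample-covariance
(divisor M − 1) computation, and against a brute-force per-pair Pearson
loop at 1e−10 tolerance.

Numerical conventions:

* **Gap row.** After gap reduction, kept columns can still contain gaps;
  these are a legitimate 21st residue type and participate in profiles by
  default. `include_gap_row = FALSE` switches to the 20-amino-acid
  convention, since which of the two conventions is preferable can depend
  on how gappy the kept columns are; both are tested.
* **Zero-variance profiles.** An invariant column has an all-zero
  mutation profile, so its mutation correlations are undefined (0/0).
  Such positions are reported in `undefined`, their off-diagonal entries
  set to 0 (no evidence of coupling) and their diagonal kept at 1 by
  convention, avoiding NaN propagation downstream.
* **Symmetry** is enforced exactly by averaging the matrix with its
  transpose (guards against last-bit asymmetry from floating-point
  summation order).

## Coupling extraction

* **Pairs**: lower-triangle entries with `r > 0.80`, strictly — the
  convention is "higher than 0.80", so a pair at exactly 0.80 is excluded.
  The display floor works the other way: cells `≥ 0.5` survive masking
  because the convention filters cells "less than 0.5".
* **Regions**: the contiguous blobs one sees in a contour map of the
  masked matrix. No canonical clustering rule exists for these, so the
  package uses single-linkage clustering of pair cells under Chebyshev
  distance with radius 5 (configurable): two hits whose row and column
  indices both differ by at most 5 join the same region, and linkage
  chains extend regions. Region labels (R1, R2, …) follow the position of
  each region's smallest member cell. Region output is exploratory — a
  different radius yields a different partition — which is why the radius
  is an exposed parameter rather than a fixed constant.
* **Groups**: connected components of the graph whose vertices are
  positions and whose edges are extracted pairs. Components are computed
  with igraph and cross-checked in the tests against a brute-force
  transitive-closure oracle. `min_group_size` defaults to 2 (report every
  coupled component); 3 reproduces the common "networks only" view.

## The synthetic generator

`generate_family()` plants three kinds of structure, each emulating one
feature the pipeline must detect:

* **Background columns** draw a random dominant residue with probability
  `background` (default 0.85 in the bundled small fixtures, 0.8 for
  generic use) and otherwise a uniformly chosen alternative — conserved
  columns with noise.
* **Gap columns** replace an *exact* count `round(fraction × N)` of
  residues with gaps, so gap-filter boundary tests are deterministic
  rather than binomially noisy.
* **Coupled sets** share one latent state per sequence, drawn uniformly
  from `states_per_set` states; a state writes the *same* residue at
  every member column. Member columns therefore co-vary perfectly and
  have identical profiles, which makes their mutation correlation exactly
  1. This is a deliberate design point: the correlation stage only ever
  sees per-column profiles over the 21 types, so two columns correlate at
  1 only when their profiles are affinely identical over the *same*
  symbols. Mapping states to different residues at different member
  columns — superficially a more "biological" co-variation — produces
  symbol-permuted profiles whose Pearson correlation is generally far
  from 1 (with equal state multiplicities on disjoint symbols it is
  negative), and would be invisible to this class of method. Different
  coupled sets use disjoint residue alphabets so cross-set correlations
  stay structurally low.

`pdz_like_fixture()` scales this to the dimensions of a structure-aligned
PDZ collection: 240 sequences, 129 columns, exactly 27 columns at 15 %
natural residues (deleted by the 20 % rule, leaving 102), and three
planted sets of sizes 5, 3 and 3 under a fixed seed. Its background
columns are fully invariant (`background = 1.0`). That choice is what
makes the fixture's expected outcome *exact*: invariant columns are
mutationally silent (undefined, correlation 0), so the planted couplings
are the only signal, every planted pair scores 1 and every other pair
stays below 0.5. It also mirrors the strong conservation of real PDZ
positions. With noisy background columns no such guarantee is possible
even in principle: a Pearson coefficient over 21-point profiles has a
null standard deviation near 0.22, so the maximum over the thousands of
background pairs of a 100-column family essentially always exceeds 0.5.
This is worth remembering when reading results on real alignments — a
handful of moderate background correlations is expected noise, which is
exactly why the pair threshold sits at 0.80, far in the null tail, and
why passing tests on the fixture demonstrate correctness of the
machinery, not that every above-threshold pair in a real family is a
functional coupling.

Generation is fully reproducible from `seed` (the generator saves and
restores the global RNG state), and a ground-truth record (planted sets,
state alphabets, exact expected q per column) is returned with every
family.

## Problem sizes and runtime

The pipeline is O(N·L) for counting plus O(M·L²) for the correlation
stage; the 240 × 129 fixture runs end-to-end in well under a second. The
test suite uses families of 10–240 sequences and 2–129 columns, 100
seeded replicates for the planted-pair ranking property, and 100 random
profiles for the Pearson oracle; the whole suite completes in a few
seconds.

## Known limitations

* The method is profile-based: it detects positions with *similar
  type-usage patterns*, not general statistical dependence between
  columns across sequences (no mutual information, no sequence-level
  contingency). Couplings expressed through different residue alphabets
  at the two positions are invisible.
* No phylogenetic correction or sequence weighting: a clade of near
  duplicates inflates frequencies and hence correlations.
* No significance assessment of extracted pairs; thresholds are
  conventions, not tests.
* Region clustering is a visualization aid with an invented, tunable
  rule; region labels are not comparable across parameter settings.
* Ambiguous residue codes (X, B, Z, U, O, J, `*`) are collapsed to gap on
  input — acceptable at typical rarity, lossy if a family is rich in
  nonstandard residues.
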