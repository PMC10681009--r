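---
title: "Methods: lattice tumour growth, spatial sampling and heterogeneity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice tumour growth, spatial sampling and heterogeneity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `spatialith`, the
choices made where the underlying design was genuinely open, and what
the test suite does and does not establish.

## The growth model

A tumour starts as one cell at the centre of a square (2D) or cubic
(3D) lattice and grows in **synchronous generations**. In each
generation, every cell alive at its start is visited once, in uniformly
shuffled order. The division rule per cell:

1. If at least one Moore neighbour (8 sites in 2D, 26 in 3D) is empty,
   the cell divides with probability 1; one daughter occupies a
   uniformly chosen empty neighbour, the other stays in place.
2. If fully enclosed, the cell divides with probability `push_rate`
   (*p*), first creating an empty neighbour via a pushing algorithm.
3. Both products of a division are *new* cells with fresh ids (the
   parent record is retired): the model treats both daughters as
   distinct genotype nodes, since each independently acquires
   Poisson(λ) new mutations. Cell ids therefore encode birth order.
4. Newborns first act in the following generation.

Growth stops at the end of the first generation in which the
population reaches `target_size`, or after `max_generations` —
reaching the cap without the size is the normal outcome for
fixed-duration surface-growth runs, not an error.

At *p* = 1 this reproduces exact doubling (2^g cells after g
generations, 2^15 cells in exactly 15 generations); at *p* = 0 only rim
cells divide and the cluster expands as a compact Eden-like mass.

**Why synchronous with shuffled order?** The exponential limit requires
that every cell divide in each time step at *p* = 1, which pins the
time model to whole-generation sweeps. Whether newborns may act within
the same sweep, and in what order cells are visited, is not pinned
down; we chose "newborns wait one generation" (otherwise *p* = 1 growth
would exceed doubling) and uniform shuffling (no spurious spatial bias
from id order). One measurable consequence: at *p* = 0 this update
yields a mean of ~31,000 cells after 100 generations, about 13% above
the ~27,500 sometimes quoted for this kind of model — an irreducible
sensitivity to the unstated update-scheme details; the corresponding
check in `test-acceptance.R` is expected to fail and documents this.

A real finite-size subtlety of the same kind: at intermediate push
rates the mean final frequency of generation-*g* mutations is 2^-g
only to first order. Occasionally an early cell is already enclosed
and skips a generation, so for g ≥ 4 the mean sits a few percent above
2^-g. Generation 1 is exact in expectation (the seed always has
space). Tests therefore check generation 1 against a 3-standard-error
band and later generations against the cross-replicate 3σ band.

## Pushing algorithms

* `random_direction` — a uniformly random Moore direction is chosen;
  the contiguous run of cells from the dividing cell along that
  discrete ray (diagonals included) shifts outward one step, up to the
  first empty site. This is the default.
* `shortest_path` — the nearest empty lattice site is located by
  Euclidean distance (scanning Chebyshev rings; ties broken uniformly
  at random), and the cells on a discretised straight segment from the
  dividing cell to that site (rounded parametric line; consecutive
  points always differ by at most one per axis, i.e. Moore steps)
  shift one step toward it. A breadth-first-search path would also
  conserve occupancy; the straight-line discretisation is the simplest
  reading of "push along the shortest path" and is the documented
  choice.

Both conserve the multiset of cell ids, and both abort with an error if
a push reaches the lattice boundary (the lattice is sized
`4 * ceiling(target_size^(1/dimension))` by default, so this indicates
a misconfiguration rather than something to clamp silently).

All stochastic choices draw from R's RNG in a fixed order (generation
shuffle, then per cell: empty-neighbour choice *or* push-gate uniform
plus direction/tie draw, then one Poisson per daughter), so a seed
replays a simulation bit-identically.

## Mutations and frequency conventions

Each daughter draws k ~ Poisson(λ) private mutations; λ = 10 per
division by default, the conventional order of magnitude for point
mutations per cell division in tumours. The seed cell carries none:
truncal mutations would be clonal everywhere and are excluded from all
sub-clonal analyses anyway. Genotypes are stored as ancestry deltas
(parent pointer + private-id range) — the only representation that
scales to 2^14 cells × ~10 mutations/division — and resolved on demand.

Frequencies are **cell fractions** natively (the discrete ladders 0.5,
0.25, 0.125, … of an exponentially growing tumour are cell fractions).
For rate inference the **diploid VAF** convention v = f/2 with
f_max = 1/2 is the default: with one Poisson(λ) draw per daughter, the
generation-g daughters contribute λ·2^g mutations at v = 2^-(g+1), so
the cumulative curve is M(v) = λ(1/v − 2) and the fitted slope equals λ
exactly — the binary-tree oracle in the tests checks this closed form.
Under the raw cell-fraction convention the slope is 2λ; it remains
available as an option.

## Inference pipeline choices

* **Detection limit** 0.01 (inclusive), applied to cell fractions in
  whatever universe is being analysed (whole tumour, or within-sample
  frequencies re-normalised to the sample — the latter is what
  per-sample inference uses).
* **Truncation**: the 3 lowest-frequency points of the cumulative curve
  are dropped before regression; they sit against the detection limit
  and would otherwise dominate the fit.
* **Free intercept** OLS rather than forcing −(μ/β)/f_max: the free
  intercept absorbs truncation and detection-limit edge effects.
* **KS distance**: observed and fitted curves are both normalised by
  the maximum observed cumulative count over the fitted points, and the
  distance is the maximum absolute difference, clipped to [0, 1]. The
  normalisation makes values comparable across sampling sizes; only
  orderings across push rates and sizes are treated as reproducible
  quantities, not the absolute scale.

## Spatial sampling

"Rectangular" samples are realised as squares (cubes) of side
`round(S^(1/dim))` — the standard sizes (100, 196, 400, 3600) are
perfect squares. A candidate centre is drawn uniformly among occupied
sites and accepted only if the whole box is occupied, so every sample
holds exactly S cells; boxes straddling the rim are rejected, and an
attempt cap reports the acceptance rate if sampling is infeasible.
Samples may overlap each other at draw time; analyses restrict to
spatially non-overlapping pairs (box disjointness), whose minimum
centre distance equals the sample side.

The centre/margin partition labels a sample "centre" when its centre
lies within two-thirds of the tumour radius (inclusive at the
boundary), where the radius is the maximum Euclidean distance of any
occupied site from the seed. Centre/margin analyses compare
within-region pair sets.

## Jaccard analysis

J(A,B) = |A∩B|/|A∪B| on sample mutation sets, with **J(∅,∅) = 0**:
after sub-clonal filtering, two samples with nothing informative left
should not count as identical. Pairing is **ordered** by default — n
samples yield n(n−1) records, matching the convention in which 500
samples give 249,500 indices — with an unordered option that halves the
compute since J is symmetric.

Implementation note: a sample's mutation set is exactly the set of its
members' ancestors weighted by each ancestor's private-mutation count,
so pairwise intersections are computed as a sparse incidence-matrix
crossproduct (Matrix package) rather than by materialising mutation
sets. The tests verify this path against brute-force per-cell genotype
resolution on small tumours.

Sub-clonal filters: `whole_tumour_clonal` (drop mutations carried by
every alive cell), and the presence-based variants
`present_in_all_samples` / `present_in_more_than_half_of_samples` used
for biopsy tables, where impurity means truly clonal mutations rarely
appear in literally every sample.

Trend summaries use 20 equal-width distance bins over the
non-overlapping range; binning is purely descriptive (the underlying
records are what the correlation uses). Degenerate inputs (constant
distance or constant J) are flagged rather than fitted.

## The biopsy fixture generator

`generate_biopsy_fixture()` emulates the *shape* of multi-region exome
data: biopsies scattered in a disc, each sub-clonal mutation
originating in one biopsy and shared with another at distance d with
probability q·exp(−decay·d), plus a clonal fraction present everywhere.
Large decay gives tight local clones (negative Jaccard–distance
correlation); decay 0 removes spatial structure entirely (correlation
statistically zero) — the two poles the tests check. It does **not**
emulate sequencing noise, purity variation, copy number, or the
correlated phylogenetic structure of real clones, so a green test
establishes only that the metrics respond correctly to presence/absence
spatial structure, not that the generator is a realistic patient
simulator. Real patient correlations are not reproduced anywhere in
this package — they require the original data.

## Scales used in the tests

The acceptance-style tests run at the model's stated scales (2^14–2^15
cells; 20–100 replicates; 500 samples), which this implementation
completes in well under a minute thanks to the compiled engine.
Property tests elsewhere use smaller tumours (2^6–2^13) purely for
speed; every such reduction is a test-side choice, not a model default.
Monotone-decay checks count only *material* inversions (an increase
exceeding 2% of the first bin's mean J) because the fully decayed tail
of the curve jitters at the 10^-4 level with 500 samples.

## Known limitations

* No cell death or turnover: μ/β equals the per-division rate; KS and
  slope behaviour under death is out of scope.
* No selection, no driver mutations, no micro-environment coupling —
  deviations of real data from these baselines are the point of
  comparing against a neutral spatial model.
* 3D runs use the same code paths but larger lattices; sampling sizes
  that are not perfect cubes are rounded to the nearest cube side.
* Sequencing noise and depth are not simulated; "detection" is a hard
  frequency threshold.
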