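---
title: "Selecting representative conformers of transition-metal complexes"
author: "confsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting representative conformers of transition-metal complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsel)
```

## The problem

High-throughput screening of homogeneous catalysts — for instance Rh
complexes bearing bisphosphine ligands — needs conformer ensembles of each
complex. Tight-binding conformer searches (CREST with GFN2-xTB//GFN-FF) are
cheap and exhaustive, but two of their properties make naive use wasteful:

* **They overestimate flexibility.** Many low-level conformers, even ones
  separated by tens of kJ/mol at the tight-binding level, relax onto the
  *same* stationary point when reoptimised with DFT. An ensemble of dozens
  of low-level conformers typically collapses to a handful of DFT minima.
* **Their energies misrank.** The low-level relative energy of a conformer
  is a poor predictor of its DFT relative energy, so keeping "the lowest
  few" low-level conformers risks discarding the true DFT minimum.

`confsel` implements the selection strategies used to bridge the two
ensembles — energy pruning, greedy RMSD pruning, steric-descriptor extremes,
PCA projection, and DBSCAN clustering on (relative energy, RMSD) — together
with the confusion-matrix framework that scores any predicted subset against
a DFT ground truth, and a synthetic generator that reproduces the
basin-collapse structure so the whole pipeline is testable without any
quantum chemistry.

## Ground truth: DFT minima within chemical accuracy

Converged DFT conformers are grouped into *minima* by `group_dft_minima()`:
records are sorted by energy and a record joins the current group when it
lies within a 5 kJ/mol window — chemical accuracy — of the group's *anchor*
(its lowest member); otherwise it starts a new group. Anchoring (rather than
transitive chaining) was chosen because a window "around a minimum" should
not let a chain of closely spaced conformers merge minima tens of kJ/mol
apart; the window is a parameter, and an externally curated truth table can
be supplied instead. Records that failed to converge or retain imaginary
frequencies are excluded from the evaluable universe altogether.

Given a truth assignment, each minimum needs exactly one *significant*
conformer to represent it; all others are *redundant*. `confusion()` scores
a selection: a covered minimum contributes one TP (its surplus selected
members are FP, its eliminated members TN); an uncovered minimum contributes
one FN (its remaining members TN). Hence TP + FN equals the number of
minima, TP + FP the selection size, and TN + FP the redundant total — the
identities the tests assert on random instances. The two quantities that
matter operationally are FN (minima lost) and TN (computation saved).

## Selection strategies

All strategies partition the ensemble into `selected` and `eliminated`
conformer ids and always retain the lowest-energy conformer.

**Energy pruning** keeps conformers whose low-level relative energy is at
most 12.55 kJ/mol (3.0 kcal/mol); the boundary value is kept. **RMSD
pruning** walks conformers in ascending energy and keeps one only if its
heavy-atom Kabsch RMSD to *every* already-kept conformer exceeds 0.35 Å.
The pairwise-greedy form was chosen over comparing only to the reference
conformer because the latter would keep near-duplicates of non-reference
conformers; the greedy form is also what ensemble-pruning tools implement.
**Combined pruning** applies energy first, then RMSD on the survivors — the
order matters for which near-duplicates survive and is therefore fixed and
documented rather than implicit.

**Descriptor extremes** keeps, within a candidate set, the conformers with
minimal and maximal percent buried volume and minimal and maximal cone angle
(at most four; ties go to the lowest conformer index), on the premise that
steric extremes are the most likely to converge to distinct DFT minima.

**PCA projection** (`pca_project()`) standardizes each descriptor column to
zero mean and unit variance, drops constant columns, and returns the first
two component scores with a deterministic sign convention (each component's
dominant loading is positive). It is exploratory: no selection is built on
it, because the descriptor variance visible to the low-level method does not
separate conformers by their DFT fate.

**DBSCAN selection** (`dbscan_select()`) clusters the two-dimensional
feature space (relative energy, RMSD-to-reference) with Euclidean DBSCAN at
radius ε and `min_samples = 2`, keeps the lowest-energy member of each
cluster, and keeps *every* noise point — sparse regions of the feature space
are exactly where overlooked minima hide. Boundary comparisons are
inclusive (distance ≤ ε) for determinism, and border points reachable from
several clusters are claimed by the earliest-seeded cluster, matching the
classic seed-order expansion so results are reproducible across
implementations.

### Feature scaling: one ensemble versus many

Within one ensemble the two features are standardized over that ensemble.
For a *sweep across many ensembles* (`epsilon_sweep()`,
`method_report(methods = "dbscan")`) the default is pooled scaling: one
mean and standard deviation per feature computed over all conformers of all
ensembles. A shared ε presupposes a shared feature scale; with per-ensemble
scaling the same ε means different things in a 5-conformer and a
50-conformer ensemble — small ensembles inflate their internal distances to
unit variance and fragment at any ε at which large ensembles are still
separable, truncating the usable ε window. `scale = "ensemble"` restores
per-ensemble scaling for comparison.

## Geometric machinery

**Superposition.** `kabsch_superpose()` minimises RMSD over proper
rotations only (SVD with the usual determinant sign correction). Allowing
reflections would silently superpose mirror images and leak chirality
changes into the RMSD — the one signal the preprocessing must preserve.
RMSD uses heavy atoms (everything except hydrogen, the metal included). No
atom reordering or graph matching is attempted: conformer generators
preserve atom order, and silent reordering would change results invisibly.

**Chirality filtering.** A stereocentre is any atom with exactly four bonded
neighbours; its handedness is the sign of the determinant of the edge
vectors to its first three neighbours in index order. A conformer is removed
(`remove_flipped()`) when any centre's sign differs from the reference
geometry and both determinant magnitudes exceed a planarity tolerance of
1e-3 Å³, which suppresses sign noise at near-planar centres. This
determinant convention is a deliberate stand-in for full CIP ranking, which
is out of scope; it is exact for the tetrahedral centres it tests.

**Buried volume.** `buried_volume()` integrates, on a uniform cubic grid
(0.10 Å spacing), the fraction of a 4.0 Å sphere centred on the metal that
falls inside any scaled van der Waals sphere of the chosen atoms — Bondi
radii × 1.17, hydrogens excluded by default, following the conventions of
the descriptor tooling in common use. Grid integration was preferred over
Monte-Carlo for determinism; the test suite keeps a 10⁶-sample Monte-Carlo
integrator as an independent oracle (agreement within 0.5 percentage
points), and halving the grid spacing moves values by less than 0.3 points.

**Exact cone angle.** `exact_cone_angle()` finds the smallest cone with
apex at the metal containing every atom's tangent cone (half-angle
asin(r/d)). The minimal cone is determined by one, two, or three boundary
atoms; one- and two-atom candidates are closed-form, three-atom candidates
are found by root-finding (tolerance 1e-10) on the unit-axis condition, and
equal-aperture ties break to the lexicographically smallest axis for
determinism. Radii are unscaled Bondi values, the Tolman-style convention.
The test oracle is a 10⁵-direction Fibonacci-sphere search with local
refinement (agreement within 0.1°).

**Ligand subset.** Descriptors are computed over the connected component(s)
of the connectivity graph containing the designated donor atoms after
deleting the metal — i.e. the bisphosphine ligand without whatever sits
trans to it. A whole-complex option exists since published workflows are
not always explicit about the trans moiety.

## The synthetic generator as a study design

`generate_ensemble()` and `generate_benchmark()` emulate the regime
described above, with known bookkeeping. Conditions (the defaults of
`basin_spec()`) are chosen once to represent that regime:

* a rigid scaffold (Rh centre, two P donors at 2.3 Å with an 87° bite
  angle, a grown C/H frame with at least one genuine stereocentre);
* 1–4 geometric basins per ensemble (weighted 0.4/0.3/0.2/0.1 in the
  24-ensemble benchmark, matching campaigns where about half the complexes
  have a single DFT minimum), 4–14 conformers per basin;
* basin templates displaced by smooth orientation-preserving linear
  distortions to pairwise heavy-atom RMSD ≥ 1.0 Å (rejection-sampled), so
  no stereocentre ever flips by accident; conformers jittered to a
  realized RMSD within 2% of the 0.15 Å within-basin target (iterative
  rescaling rather than an analytic shrinkage correction);
* high-level (DFT-like) basin anchors spaced 8 kJ/mol apart — clear of the
  5 kJ/mol grouping window — with ≤ 1 kJ/mol intra-basin spread;
* low-level (xTB-like) energies add a per-basin offset (sd 10 kJ/mol,
  redrawn until offset anchors are ≥ 8 kJ/mol apart so basins stay
  energetically resolvable while misranked) and per-conformer noise
  (sd 1.5 kJ/mol, truncated at 2σ);
* optionally, a fraction of conformers reflected through the origin to
  exercise the chirality filter.

What the generator does *not* emulate: physically realistic force-field
geometries, torsional sampling, rotamer substructure, non-converged DFT
records, and basins that overlap in the (energy, RMSD) feature plane. A
passing benchmark therefore demonstrates that the machinery is correct and
that the methods behave as designed *when basins are separable*; it does not
certify performance on real ensembles, where basin overlap is exactly the
failure mode that makes ε system-dependent.

All generation is driven by a single integer seed; the 24-ensemble
benchmark regenerates byte-identically from the same seed. Benchmark sizes
(24 ensembles, ~400–600 conformers) were chosen as the package's standard
problem size for its own evaluation scripts.

## Numerical choices and degenerate inputs

* Energies are kJ/mol internally; XYZ comment lines default to Hartree
  (1 Eh = 2625.4996394799 kJ/mol) since that is what conformer-search tools
  write; fixtures use kJ/mol to keep tests conversion-free.
* The comment-line energy is the first token that parses as a number, so
  dialects that append labels still read.
* Boundary-inclusive comparisons throughout (≤ threshold kept, ≤ ε is a
  neighbour).
* A single-conformer ensemble clusters to one noise point, which is
  selected. Zero-variance features standardize to all zeros rather than
  NaN. An all-hydrogen structure has no heavy-atom RMSD and is an error.
* Superpositions over fewer than three atoms are computed but flagged
  rank-deficient.
* Grouping by Gibbs energy instead of electronic energy is a flag
  (`use_gibbs`); electronic energy is the default as the more robust
  quantity when thermochemical corrections are noisy.

## Known limitations

* The confusion framework assumes the truth assignment covers every
  evaluable conformer; curating that truth for real data may need manual
  adjustment, which is out of scope here (an override table can be read
  instead).
* The chirality test covers 4-coordinate centres only; exotic coordination
  geometries would need a different handedness criterion.
* ε remains system-dependent on real data. The sweep machinery quantifies
  the trade-off; it does not remove it.

## A worked run

```{r example, eval = FALSE}
bench <- generate_benchmark(24, seed = 1)
ens <- lapply(bench, `[[`, "ensemble")
truths <- lapply(bench, `[[`, "truth")

method_report(ens, truths)

sw <- epsilon_sweep(ens, truths, grid = seq(0.02, 1.5, by = 0.02))
plot(sw)
```

The same computation, from the shell:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
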