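# confsel

Conformer ensemble pruning, clustering and selection for transition-metal
complexes.

## The problem

Screening homogeneous catalysts (e.g. Rh–bisphosphine complexes) requires
conformer ensembles. Cheap tight-binding conformer searches (CREST with
GFN2-xTB//GFN-FF) produce large ensembles whose flexibility is
overestimated: after DFT reoptimisation, dozens of low-level conformers
collapse onto a handful of distinct minima, and the low-level relative
energies ΔE_xTB correlate poorly with ΔE_DFT. Selecting which low-level
conformers to refine at the DFT level is therefore a real decision problem:
keep too many and the DFT budget is wasted on redundant structures; keep the
"lowest few" by ΔE_xTB and the true DFT minimum is often lost.

`confsel` implements and evaluates the standard selection strategies:

* **energy pruning** — drop conformers with ΔE_xTB > 12.55 kJ/mol
  (3.0 kcal/mol);
* **RMSD pruning** — greedy elimination of geometric near-duplicates:
  walking conformers in ascending energy, keep one only if its heavy-atom
  Kabsch RMSD to every kept conformer exceeds 0.35 Å;
* **combined pruning** — energy first, then RMSD on the survivors;
* **descriptor extremes** — keep the conformers with minimal/maximal
  percent buried volume (%V_bur, 4.0 Å sphere at the metal) and
  minimal/maximal exact ligand cone angle;
* **PCA projection** — two-component chemical-space maps of standardized
  descriptors (exploratory);
* **DBSCAN selection** — density-based clustering in the standardized
  (ΔE_xTB, RMSD) plane with `min_samples = 2`; one representative
  (lowest-energy member) per cluster, all noise points retained.

Any selection is scored against a DFT ground truth in which converged
conformers are grouped into minima within a 5 kJ/mol chemical-accuracy
window: per minimum, one conformer is *significant* and the rest are
*redundant*, giving TP/FP/TN/FN counts where FN counts lost minima and TN
counts correctly discarded redundancy. An ε-sweep (`epsilon_sweep()`) maps
the accuracy–cost trade-off of the clustering radius.

A seeded synthetic generator (`generate_ensemble()`,
`generate_benchmark()`) produces basin-structured ensembles with known
ground truth — tight geometric basins ≥ 1 Å apart, high-level basin
energies ≥ 8 kJ/mol apart, low-level energies decorrelated by per-basin
offsets — so the entire pipeline is testable without running any quantum
chemistry.

## Worked example

```r
library(confsel)

# a synthetic ensemble: 3 basins, known truth
x <- generate_ensemble(basin_spec(n_basins = 3, seed = 7))
x$ensemble
#> conformer_ensemble: 24 conformers, 16 atoms (13 heavy)
#>   reference (lowest energy): conformer 9 (id 9)
#>   rel. energy span: 30.76 kJ/mol; max RMSD to reference: 1.416 A
#>   metal: Rh (atom 1)
#>   connectivity: present

sel <- dbscan_select(x$ensemble, cluster_config(epsilon = 0.3))
sel
#> selection_result [dbscan]: 4 of 24 conformers selected
#>   parameters: epsilon=0.3, min_samples=2, standardize=TRUE
#>   clusters: 3, noise points: 1

confusion(sel, x$truth)
#> confusion_counts: TP 3  FP 1  TN 20  FN 0  (24 conformers, 3 minima)
```

Four conformers cover all three minima (FN = 0) while 20 of the 21
redundant conformers are eliminated (TN = 20); one cluster contributed a
surplus representative (FP = 1).

Comparing pruning methods over a 24-ensemble benchmark:

```r
bench <- generate_benchmark(24, seed = 1)
rep <- method_report(lapply(bench, `[[`, "ensemble"),
                     lapply(bench, `[[`, "truth"))
rep$counts
#>     method tp  fp  tn fn n_minima n_conformers
#> 1   energy 32 223 158 18       50          431
#> 2     rmsd 50   0 381  0       50          431
#> 3 combined 32   0 381 18       50          431
```

Energy pruning misses 18 of 50 minima while removing only 158 of 381
redundant conformers; geometric (RMSD) pruning removes all 381 and misses
none — the qualitative ranking that motivates structure-based selection.

Real data enter through `read_multi_xyz()` (CREST-dialect multi-structure
XYZ, energies on the comment line), `read_molfile_connectivity()` (MDL
V2000), and `read_dft_table()` (a distilled CSV of per-conformer DFT
outcomes). A thin command-line wrapper with `simulate`, `prune`,
`select-extremes`, `descriptors`, `pca`, `cluster`, `sweep`, `evaluate` and
`pipeline` subcommands is installed at
`system.file("cli", "confsel.R", package = "confsel")`.

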