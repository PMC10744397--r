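# amdmem

Analysis toolkit for **accelerated molecular dynamics (aMD)** studies of
membrane-active peptides — the post-processing side of a
peptide-at-a-bilayer simulation campaign: boost-energy bookkeeping,
canonical-ensemble reweighting, dihedral PCA with conformational-cluster
extraction, reweighted free-energy surfaces, lipid order parameters, and
peptide-headgroup contact analysis. Synthetic-data generators with known
ground truth make every stage testable without a production trajectory.

## Who it is for

aMD flattens energy barriers by adding a boost

    ΔV(V) = (E − V)² / (α + E − V)   for V < E,   ΔV = 0 otherwise

to the potential, so a peptide explores binding, reorientation and
insertion at a bilayer far faster than plain MD. The sampled ensemble is
then biased, and every observable binned over a reaction coordinate must
be reweighted by the Boltzmann factor of the per-frame boost,
exp(ΔV/k_BT), to recover the canonical free-energy landscape:

    PMF_b = −k_B T · ln( p_b / max_b p_b ),    p_b ∝ Σ_{i∈b} w_i

with `w_i = exp(ΔV_i/k_BT)` (exponential) or its truncated Maclaurin
series `Σ_{j≤k} (ΔV_i/k_BT)^j / j!`, which trades a controlled bias for
much lower statistical noise at large boosts (default order k = 10).
If you run aMD with Amber-style boost logs and need reweighted PMFs,
dihedral-PCA cluster populations, |S_CD| profiles, peptide-membrane
distances or headgroup contact fractions in R, this package is the
analysis layer.

## What is in the box

- `boost_energy()`, `total_boost()`, `params_from_classical_averages()` —
  the aMD boost closed form, the three `iamd` boost criteria, and the
  standard dual-boost parameter recipe from classical-run averages.
- `parse_amd_log()` / `write_amd_log()` — a lossless boost-log dialect
  (with a column map for Amber-style 8-column logs); `read_topology()`,
  `read_frames()`, `write_frames()` — PDB (via bio3d) and a plain-text
  frame table.
- `frame_weights()`, `weighted_histogram()`, `pmf_from_histogram()`,
  `pmf_2d()` — exponential / Maclaurin reweighting into 1D and 2D
  free-energy surfaces with exact anchoring and masked empty bins.
- `compute_phi_psi()`, `dpca_fit()`, `cluster_top_pcs()` — circular-safe
  dihedral PCA (sin/cos features) and density-grid extraction of the
  most populated conformational clusters with representative frames.
- `chain_vectors()`, `scd_profile()`, `com_z_distance()`,
  `insertion_pmf()`, `headgroup_contact_fractions()` — membrane-facing
  observables.
- `sample_boosted()`, `gen_torsion_clusters()`, `gen_oriented_vectors()`,
  `gen_toy_membrane_system()` — seeded synthetic-data generators with
  ground truth.
- `run_pipeline()` — config-driven end-to-end run with TSV outputs and a
  YAML manifest; `inst/scripts/amdmem.R` is a thin shell wrapper.

## Worked example

Boost a 3 kcal/mol double well, sample it, and recover the canonical
landscape by Maclaurin reweighting:

```r
library(amdmem)
th  <- thermo_params(300)                       # kT = 0.59616 kcal/mol
pot <- toy_potential("double_well_1d", barrier = 3)
amd <- amd_params(1, E_total = 4, alpha_total = 2)
s   <- sample_boosted(pot, sampler_spec(20000, seed = 1, kT = th$kT, amd = amd))
w   <- frame_weights(s$boost, th, "maclaurin", k = 10)
w
#> frame_weights: 20000 frames, method maclaurin:10, kT = 0.59616 kcal/mol
#>   weight range: [1, 87.0645]
fes <- pmf_from_histogram(
  weighted_histogram(s$positions, w, seq(-1.75, 1.75, length.out = 41)),
  th, coord = "x")
fes
#> fes: 1D free-energy surface over x
#>   bins: 40; occupied: 36; kT = 0.59616 kcal/mol
#>   PMF minimum at x = -1.006
```

The boosted chain hops the barrier freely (mean recorded boost 1.76
kcal/mol, max 2.67), yet after reweighting the PMF minimum lands on a
well bottom (x = ±1) and the well-to-barrier height approaches the true
3 kcal/mol. Planted conformational clusters are recovered the same way:

```r
g  <- gen_torsion_clusters(5000, 18, c(0.7, 0.3),
                           list(c(-60, -45), c(60, 75)), c(20, 20), seed = 2)
cluster_top_pcs(dpca_fit(g$series))
#> cluster_set: 2 cluster(s), 0 noise frame(s)
#>   populations: 3479, 1521
```

— two clusters, populations within sampling noise of the planted
0.7/0.3 split.

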