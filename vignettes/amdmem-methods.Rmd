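---
title: "Methods: aMD reweighting and membrane-interaction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aMD reweighting and membrane-interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdmem)
```

## The problem

Membrane-active peptides such as peptaibols bind, reorient and sometimes
insert into lipid bilayers on timescales that plain molecular dynamics
struggles to reach. Accelerated MD (aMD) addresses this by adding a
non-negative boost

$$
\Delta V(V) = \frac{(E - V)^2}{\alpha + E - V} \quad (V < E), \qquad
\Delta V = 0 \quad (V \ge E),
$$

to the potential wherever it falls below a threshold $E$, flattening
barriers so the system diffuses across its landscape faster. The price is
that the sampled ensemble is no longer canonical: every observable binned
over a reaction coordinate must be reweighted by the Boltzmann factor of
the boost, $e^{\Delta V / k_B T}$, to recover the unbiased free-energy
landscape. `amdmem` implements this bookkeeping plus the downstream
analyses a peptide-membrane study needs: dihedral PCA with
most-populated-cluster extraction, reweighted potentials of mean force
(PMFs), acyl-chain order parameters, peptide-to-membrane distance series,
and residue-headgroup contact fractions. Everything is validated
end-to-end on synthetic data with known ground truth.

## Boost model and parameter recipe

Three boost criteria are supported, following the Amber `iamd`
convention: mode 1 boosts the whole potential, mode 2 only the torsional
term, mode 3 both (dual boost). `params_from_classical_averages()`
encodes the standard recipe that seeds $(E, \alpha)$ from a short
conventional run: $E_{dih} = \langle V_{dih}\rangle + 3.5\,n_{res}$,
$\alpha_{dih} = 3.5\,n_{res}/5$, $E_{tot} = \langle V\rangle +
0.175\,n_{atoms}$, $\alpha_{tot} = 0.175\,n_{atoms}$ (kcal/mol). All four
constants are arguments, because published variants differ. The boost
obeys the identities the reweighting relies on: $\Delta V \ge 0$ with
equality iff $V \ge E$, $\Delta V \le E - V$ below threshold,
monotonically non-increasing in $V$, and $V + \Delta V$ non-decreasing
(the boosted surface never inverts the ordering of states). The test
suite asserts all four on a dense $(V, E, \alpha)$ grid.

$k_B$ is fixed at 0.0019872041 kcal mol$^{-1}$ K$^{-1}$; at the study
temperature of 300 K, $k_B T = 0.59616$ kcal/mol.

## Reweighting: exponential and Maclaurin

`frame_weights()` computes $w_i = e^{\Delta V_i / k_B T}$ (exponential)
or its truncated Maclaurin series $w_i = \sum_{j=0}^{k} (\Delta V_i /
k_B T)^j / j!$. The exponential estimator is unbiased but noisy when
large boosts put enormous weight on a few frames; the truncated series
damps that noise at the cost of a controlled bias. The default order is
$k = 10$, the common practice for this estimator; on boosts up to
$3\,k_B T$ it agrees with the exponential to better than 0.05% relative,
and the truncation error decreases monotonically in $k$ (both are
asserted in the tests). Order 0 reduces to unit weights, i.e. no
reweighting. Whether the total boost ($\Delta V_P + \Delta V_D$) or the
dihedral boost alone enters the factor is a switch (`boost_which`),
defaulting to the total.

PMFs are built from weighted histograms: $p_b$ is the weight sum in bin
$b$ over the total, and $\mathrm{PMF}_b = -k_B T \ln(p_b / \max_b p_b)$,
anchored so the most probable bin sits at exactly zero — the convention
used by free-energy surface color maps. Empty bins are masked (`NA`),
never imputed; the plotting method caps them at the largest finite value
plus one $k_B T$ for display only. Default bin width for distance
coordinates is 1 Å; 2D surfaces default to 50 × 50 bins spanning the
observed range.

## Synthetic ground truth

The generators exist so that every pipeline stage can be tested against
a known answer, and they are first-class, seeded, pure functions of
their arguments:

- `sample_boosted()` draws Metropolis samples from the *boosted* surface
  $V^*(x) = V(x) + \Delta V(V(x))$ of a closed-form toy potential
  (harmonic or double well) and records each sample's boost, exactly the
  contract of an aMD trajectory plus its boost log. Metropolis (rather
  than discretised dynamics) is used deliberately: the reweighting
  contract only requires correct stationary statistics, and a sampler
  with no integrator error keeps discretisation bias out of the recovery
  checks. The proposal width is auto-tuned to 30-50% acceptance during
  burn-in. Samples are serially correlated, as MD frames are; tests that
  need near-independent draws (e.g. the Kolmogorov-Smirnov check against
  the analytic Boltzmann CDF) use the `thinning` argument.
- `gen_torsion_clusters()` plants conformational clusters: each frame's
  $\phi/\psi$ vector is drawn from per-angle von Mises distributions
  around its cluster's means (Best-Fisher rejection sampling), with
  ground-truth labels returned.
- `gen_oriented_vectors()` produces unit vectors with a delta, isotropic
  or von Mises-Fisher polar-angle law about the bilayer normal.
- `gen_toy_membrane_system()` builds a mirror-symmetric two-leaflet
  pseudo-membrane (headgroup bead plus chain beads per lipid, PE:PG 3:1)
  and an optional pseudo-peptide placed so that the frame-0
  peptide-membrane distance equals the requested offset exactly.

What these emulate is the *structure* of the real inputs — boosted
ensembles with per-frame boosts, clustered torsion series, tilted C-H
bonds, a peptide approaching a bilayer. What they deliberately do not
emulate: force-field realism, solvent, lipid internal structure,
collective membrane modes, or the 2.2 µs timescale of a production aMD
run. Passing tests therefore demonstrate that the *estimators* are
correct, not that any particular membrane result is reproduced.

## Recovery conditions used in the checks

The headline recovery check samples $n = 200{,}000$ Metropolis points
from a 1D double well with a 3 kcal/mol barrier at $k_B T = 0.59616$
kcal/mol, boosted with $E = \min V + 4$ kcal/mol and $\alpha = 2$
kcal/mol, then reweights exponentially into 40 bins spanning
$[-1.75, 1.75]$ (chosen to cover everywhere the boosted density is
non-negligible; the potential is ~12.7 kcal/mol above its minimum at the
edges). The recovered PMF must match the analytic profile
$F(x) = V(x) - \min V$ within 0.2 kcal/mol on every bin holding at least
200 raw counts. Because the double well is symmetric, its analytic
minimum is a degenerate pair of bins whose tie is broken only by
floating-point noise; the location check therefore requires the
recovered argmin to fall in the analytic minimum *set* (bins within
$10^{-9}$ of the minimum). Two further scaled checks: the insertion-PMF
geometry test plants a harmonic distance potential with its minimum at
28 Å and requires the reweighted argmin within one 1 Å bin of it, and
the cluster-recovery test plants two von Mises clusters (weights
0.7/0.3, $\kappa = 20$, 120° mean separation, 18 residues, 5,000
frames) and requires exact cluster-count recovery with at least 99%
label agreement. These problem sizes run in seconds and give the
estimators enough statistics that failures indicate defects, not noise.

## Dihedral PCA and clustering

Backbone torsions are computed from the standard four-atom construction
($\phi_i$: C$_{i-1}$-N$_i$-CA$_i$-C$_i$; $\psi_i$:
N$_i$-CA$_i$-C$_i$-N$_{i+1}$), IUPAC sign convention, and verified in the
tests against an independent torsion implementation (bio3d). Terminal
residues lacking a neighbour — including a C-terminal amino alcohol
without a carbonyl — contribute only their defined angle; absent angles
are flagged, never zero-filled, and their columns are excluded from the
PCA.

Each angle $\chi$ is embedded as $(\cos\chi, \sin\chi)$ before the
covariance is taken. Raw-angle PCA breaks at the ±180° seam — two frames
at +179° and −179° are 2° apart, not 358° — and the doubled feature
space removes that artefact at the cost of at most doubling the
dimension. The eigendecomposition is exact (symmetric `eigen`), and the
model records eigenvalues, orthonormal eigenvectors and per-frame
projections.

Cluster extraction follows the "most populated clusters" idiom:
histogram the top-3 PC projections on a grid, call cells dense when they
hold at least 0.2% of frames, take connected components of dense cells
(full diagonal neighbourhood) as basins, rank by population, and report
each basin's representative frame (the member nearest its members'
centroid). Two resolution choices were genuinely open and were fixed by
measurement on planted ground truth: a 32-bins-per-axis grid
over-resolves realistic basins — a basin thin along PC1 but diffuse along
the low-variance PCs fragments into many components and sheds noise
frames — so the default is 12 bins per axis; and frames in non-dense
cells attach to the nearest basin within 3 cells (Chebyshev) rather than
1, with frames farther than that labelled noise. At these defaults the
two-cluster recovery above is exact (2 clusters, 100% agreement across
ten seeds). Both knobs are exported arguments.

## Membrane observables

- **Order parameters.** $|S_{CD}| = |0.5\,\langle 3\cos^2\theta - 1
  \rangle|$ per chain carbon, $\theta$ the angle between each C-H bond
  vector and the bilayer normal, averaged over lipids, frames and
  hydrogens *before* taking the absolute value. Carbon indices count
  from the carbonyl carbon = 1 (which bears no hydrogen). C-H vectors
  come from explicit hydrogens (all-atom convention); there is no
  united-atom hydrogen reconstruction. The atom-naming map defaults to
  the CHARMM-style `C2x`/`C3x` with `HxR/S`, `HxX/Y` convention and is
  fully replaceable.
- **Distance coordinate.** Per frame, the absolute difference between
  mass-weighted z centres-of-mass of the peptide and membrane
  selections, with peptide atoms wrapped to the periodic image nearest
  the membrane COM along z when a box is present. The membrane "centre"
  is the COM of all lipid atoms (a phosphate-plane midpoint would be an
  alternative definition; selections are explicit arguments, so either
  is expressible).
- **Contacts.** A residue is "in contact" in a frame when any of its
  side-chain heavy atoms lies within the cutoff (default 4.5 Å,
  heavy-atom) of any flagged headgroup heavy atom, minimum-image along
  periodic axes. Side chain means non-backbone heavy atoms; for cap and
  amino-alcohol residues (ACE, NME, PHL) all heavy atoms count, since
  terminal groups are exactly the ones contact analyses of
  terminal-adjacent residues care about. Fractions are monotone
  non-decreasing in the cutoff, which the tests assert.

## Numerical and degenerate-input policy

Histogram bins are half-open $[e_b, e_{b+1})$ with values at or beyond
the last edge excluded and counted. PMF anchoring is exact (the modal
bin is 0 by construction, not by subtraction of a float minimum). Empty
histograms, empty selections, fewer than 2 frames for PCA, unknown iamd
modes, negative boosts, non-monotone steps or edges are all hard errors;
unknown residue names degrade to an `"unknown"` class with a warning.
Zero-variance projections are clustered on a widened degenerate axis
rather than failing. Zero-boost series reweight to unit weights and
reproduce plain histograms bitwise.

## File formats

The boost log is a self-describing dialect: `#` comments (one of which
records `iamd=`), then whitespace columns `step V_P V_D dV_P dV_D` in
kcal/mol, written at full precision so write-then-parse is numerically
the identity. An Amber-style wider log can be ingested by naming which
columns carry which fields. Trajectories travel as multi-model PDB (via
bio3d) or as a plain whitespace frame table (`FRAME` separator lines,
one `x y z` line per atom) that round-trips bit-identically; the frame
table is the canonical fixture format because it needs no binary
dependency. Results are TSV with one `#` header line naming columns,
units and the run seed. `run_pipeline()` chains the stages over these
files and writes a YAML manifest with the resolved config, input MD5
hashes, per-stage status and collected warnings.

## Known limitations

- The package analyses trajectories; it does not run MD, and binary
  trajectory formats (DCD/XTC/NetCDF) are out of scope for the core.
- Only backbone $\phi/\psi$ torsions enter the PCA (no side chains or
  $\omega$).
- Gaussian-accelerated MD and cumulant-expansion reweighting are not
  implemented.
- Published plateau order parameters or insertion free energies from
  microsecond production runs are context for the method, not
  quantities the synthetic pipeline can reproduce; the checks here are
  property-based by design.

## A minimal worked example

```{r example}
th <- thermo_params(300)
pot <- toy_potential("double_well_1d", barrier = 3)
amd <- amd_params(1, E_total = 4, alpha_total = 2)
s <- sample_boosted(pot, sampler_spec(20000, seed = 1, kT = th$kT, amd = amd))
w <- frame_weights(s$boost, th, "maclaurin", k = 10)
fes <- pmf_from_histogram(
  weighted_histogram(s$positions, w, seq(-1.75, 1.75, length.out = 41)),
  th, coord = "x")
fes
```
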