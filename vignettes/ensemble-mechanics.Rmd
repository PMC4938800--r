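---
title: "Conformational ensemble mechanics: models, parameters and design choices"
author: "ensmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensemble mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensmech)
```

## The scientific problem

Large protein assemblies such as the bacterial flagellar rotor switch between
discrete functional states by propagating small conformational changes over
long distances. A single crystal structure shows one frozen conformer;
understanding the mechanics — which loops act as hinges, how interfacial
fluctuations are amplified into a distal output helix, and whether the
observed state heterogeneity reflects discrete traps or intrinsic
flexibility — requires an *ensemble* of thermally accessible conformers and
statistics over it.

`ensmech` implements that workflow end to end:

1. **Ensemble generation** from one structure by iterative satisfaction of
   geometric distance constraints (a reduced-representation distance-geometry
   engine in the tCONCOORD tradition).
2. **Essential dynamics**: PCA of Calpha fluctuations; eigenvalue spectra,
   anisotropy curves, conformer spread, RMSF, single-PC pseudo-trajectories.
3. **Structural-alphabet encoding** of overlapping 4-residue fragments and
   **normalized mutual-information (nMI) networks** linking local fragment
   states to collective motions (nMI_PC profiles), with eigenvector
   centrality and peak ("node") calling.
4. **Hinge mechanics** from named vector pairs: difference-angle
   distributions, bending/rotation widths, serial-hinge amplification,
   single vs symmetric-double Gaussian model selection, and torsional
   stiffness.
5. **Deletion mimics**: removing a residue stretch, ligating the flanks in
   the constraint set and comparing native vs edited ensembles.
6. **Coevolution**: pairing two protein families by organism and genomic
   proximity, mean-field direct coupling analysis (DCA) and APC-corrected
   mutual information, and classification of top couplings against
   structure contacts and the dynamic network.

Every stage is exercised on synthetic fixtures with known ground truth, so
the whole pipeline is testable without downloading structures or alignments.

## The constraint engine

`extract_constraints()` converts a structure into distance bounds:

| class | pairs | bounds | default |
|---|---|---|---|
| covalent | sequential Calpha–Calpha | 3.80 ± 0.05 Å | lower bound 2.90 Å before proline |
| hbond | backbone N–O within cutoff | observed ± 0.15 Å | cutoff 3.5 Å |
| salt_bridge | charged centroid pairs | observed ± 0.25 Å | cutoff 4.5 Å |
| contact | Calpha pairs within cutoff | observed ± 1.0 Å | cutoff 8 Å |
| ligation | deletion flanks | 3.80 ± 0.05 Å | — |

A hydrogen bond whose midpoint is surrounded by polar side-chain atoms
and/or solvent-exposed is *labile*: `score_lability()` counts polar
side-chain heavy atoms in a 4.5 Å shell plus an exposure proxy (1 when
fewer than 10 heavy atoms occupy the shell), and bonds scoring ≥ 3 are
demoted to loose contact bounds. This is what lets the ensemble cross
hydrogen-bond-locked barriers.

`generate_conformer()` starts each atom at the reference plus a uniform
displacement inside a bounding box (half-width 1.5 Å by default), then
repeatedly sweeps the constraints in a freshly shuffled order, moving each
violating pair symmetrically onto the nearest bound, until the largest
violation is below 0.05 Å or 500 sweeps have elapsed; non-convergence is
reported rather than raised, and `generate_ensemble()` retains only
converged conformers, reporting the acceptance rate. Real structures are
first reduced to backbone N, CA, C, O plus one side-chain centroid
pseudo-atom per residue (`reduce_structure()`); the full-atom engine of the
original method, with its solvation-aware rebuilding, is deliberately not
reproduced, so results on real structures are approximate in scale.

Two numerical properties matter for interpretation:

* **Exploration is start-limited.** The projection method converges to a
  feasible point near its random start, so the amplitude of collective
  motion in the ensemble grows with the bounding-box half-width, not with
  the slack left in the bounds. Demonstrations of inter-domain hinge
  flexibility therefore use a wider box (4 Å) together with tightened
  intra-domain bounds; at the default 1.5 Å the ensemble reports local
  compliance.
* **Chirality is not constrained.** Distance bounds are mirror-blind; with
  very large boxes partially reflected solutions can converge. The default
  box is far below that regime.

Determinism: each conformer runs on a private xorshift64* stream derived
from the master seed, so ensembles are bit-identical across runs and
platforms regardless of R's RNG state.

## Synthetic fixtures and what they do (not) emulate

`make_hinge_ensemble()` builds an ideal helical Calpha trace (2.3 Å radius,
1.5 Å rise, 100°/residue) split into segments, and applies per-conformer
bend and twist rotations at each segment boundary, drawn from a Gaussian
well (sd in degrees) or a symmetric two-state model (±Δ with within-state
sd), with optional isotropic coordinate jitter for elastic noise. The
default segment length of 19 residues is chosen for exact identifiability:
at 100°/residue the first-to-last Calpha line of a 19-residue segment is
exactly parallel to the helix axis, and the plane normal through residues
(i−9, i, i+9) is exactly perpendicular to it. Bend angles are applied about
the ring-normal direction and twists about the axis, so the signed
difference angle measured between the corresponding vector pairs *is* the
generator's draw, to machine precision — which is why the recovery
tolerances in the tests can be tight (±5 %).

The fixtures emulate the statistical structure the analysis assumes —
harmonic or bimodal hinge wells, serial amplification, rigid secondary
structure — but not protein chemistry: no side chains, no packing, no
solvent, no realistic B-factor gradients. Passing tests therefore
demonstrate that the *statistics are computed correctly and recover known
truth*, not that the reduced engine reproduces any particular protein's
dynamics.

`sample_potts_msa()` Gibbs-samples sequences from a pairwise Potts model
with like-state couplings on declared position pairs, splits columns into
two pseudo-proteins and attaches synthetic organism ids and gene distances
(|N(18, 24)|, truncated at 99) so the organism/locus pairing stage is
exercised. Each sequence is an independent chain (200 sweeps from a random
start); couplings above J ≈ 5 trigger a slow-mixing warning.

## Essential dynamics conventions

PCA runs on Calpha coordinates only, mass-unweighted, with *population*
covariance (divide by N) — the same population convention is used for all
profile normalizations and angle widths. Eigenvector signs follow a fixed
convention (largest-magnitude component positive) purely for
reproducibility; signs are physically arbitrary. Conformer spread is
`sqrt(sum(lambda[pcs]))/10` in nm — the combined SD of the selected,
statistically independent PCs about the mean structure — with uncertainty
from bootstrap over conformers, refitted in the essential subspace.
Single-PC attribution of an angle width uses `pc_trajectory()` with a
Gaussian-quantile amplitude grid (`gaussian_amplitude_grid()`), so the sd
measured uniformly over the trajectory equals the sd the PC contributes in
the ensemble; with a uniform grid it would overweight the tails. Variances
attributed to individual PCs add to the full-ensemble variance within ~10 %
on the fixtures.

## Fragment encoding and nMI networks

Fragments are 4 consecutive Calpha, indexed by their first residue; chain
changes and numbering gaps (deletion sites) terminate windows rather than
bridging them. A fragment encodes to the library letter with minimal
Kabsch-superposed RMSD (ties to the lowest index). The shipped 25-letter
library (`inst/extdata/alphabet_synthetic_25.tsv`) is **synthetic**,
generated procedurally from ideal helix/strand/polyproline seeds plus
kinked variants on a 15° grid: the empirical fragment alphabet derived from
high-resolution crystal structures is an external dataset whose canonical
coordinates are not redistributable here. Any user library in the same TSV
format is accepted, and all correctness tests run on a small synthetic
library built in code, so nothing depends on the shipped file's contents.

`nmi_pair()` computes `(I − ε)/H_joint`, clamped to [0, 1], with the
finite-size bias `ε = (B_i − 1)(B_j − 1)/(2N ln 2)` bits; both the
correction and the normalization can be switched off (the oracle tests run
with ε off). PC projections are discretized into **equal-occupancy** bins
(default 10) before nMI against fragment columns — equal-width binning is
pathological for heavy-tailed projections. Significance uses column-wise
conformer shuffling (95th percentile of the null). Node calling takes local
maxima with topographic prominence ≥ 0.2 × the profile maximum; the
prominence rule is this package's own choice, as no published node-calling
rule exists for these profiles.

## Hinge mechanics

Vector definitions are configuration data (name, kind, chain, anchor
residue ids), not code. Difference angles are unsigned by default; a signed
series needs a sign-reference vector (the sign is that of
`(v1 × v2) · ref`), and the fixtures' rotation pairs are measured signed,
which the bimodal (±Δ) histograms require. Histogram fits use
Freedman–Diaconis bins and nonlinear least squares on bin centers for the
single form `a·exp(−0.5((x−x0)/b)²)` and the symmetric double form
`a[exp(−0.5((x−x0)/b)²) + exp(−0.5((x+x0)/b)²)]`; the model with the higher
R² is preferred, and fit failures are reported per model, not fatal.

Torsional stiffness uses `κ = k_B·T/σ_rad²` with k_B·T = 4.114 pN·nm at the
default 300 K (the commonly quoted room-temperature value). Published
stiffness figures for the flagellar switch interface (≈740 pN·nm one-state,
≈1,500 pN·nm two-state) are larger than this formula gives from the
corresponding printed Gaussian widths (≈450 and ≈1,825 pN·nm respectively);
the original work does not state its formula or temperature, so `ensmech`
reports the transparent harmonic estimate and leaves the systematic factor
to the user rather than forcing agreement.

`coupling_relation()` classifies an (x, y) angle–angle relation by adjusted
R² among linear, parabolic (elastic well) and saturating end-state
(plateau/linear/plateau) forms — the three regimes relevant for
interface-to-output coupling.

## Coevolution

`pair_sequences()` pairs the two families within each organism by smallest
gene distance (greedy by default; exhaustive minimum-weight matching for
≤10 paralogs), discarding pairs at ≥100 genes. Redundancy filtering is
greedy keep-first at 80 % identity over mutually non-gap columns, and its
output is a fixed point of the filter. `mfdca()` is a standard mean-field
DCA: sequence reweighting at 0.8 identity, pseudocount 0.5 (as a fraction),
gap as an extra state *only when gaps occur*, couplings from the inverse
connected-correlation matrix, and direct information from each pair's
two-site model (marginal matching by iterative proportional fitting,
tolerance 1e−12). A sparse-inverse-covariance method is deliberately not
re-implemented; APC-corrected MI (`apc_mi()`) is the second, cheaper
scorer, and the two agree on the top planted pair across replicate
fixtures. `top_fraction()` reports the top 1.5 % of pairs by default plus
the empirical upper-tail fractions at 2σ and 3σ of the score distribution,
because whether published tail percentages were one- or two-tailed is not
decidable from the text.

## Problem sizes

The shipped tests and the acceptance script use the sizes at which the
statistics they check are stable: 4,096 conformers for parameter recovery
(the analytic fixtures generate these in seconds), 1,024 per cell of the
3×3 hinge-calling grid, 2,048 for amplification, 200–512 for
constraint-engine ensembles, and 20 replicate alignments of 2,000 sequences
for coevolution recovery. The engine's flag for 65,536-conformer runs
exists (`generate_ensemble(n = 65536)`) for full-scale studies.

## Known limitations

* The reduced-representation engine approximates, and does not reproduce,
  full-atom constraint generation: no explicit solvent, no rotamer
  rebuilding, no statistical bonding tables; acceptance on real structures
  is directional/approximate by design.
* Ensembles are unordered samples: no time correlations, no kinetics.
* The shipped fragment library is synthetic; letter identities are not
  comparable with empirical structural-alphabet letters, only the
  information-theoretic statistics built on them are.
* The engine's conformational exploration scales with the starting-box
  width, so absolute fluctuation amplitudes are tied to that parameter;
  comparisons between ensembles generated with identical configurations
  remain meaningful.
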