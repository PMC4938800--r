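# ensmech — conformational ensemble mechanics of protein switch complexes

`ensmech` is an R package for asking *mechanical* questions of a single
protein structure: which loops act as hinges, how interfacial fluctuations
are amplified into distal output elements, whether an angle fluctuates in a
harmonic well or between two states, and whether residue coevolution tracks
the dynamic couplings. It was built for multi-domain switch assemblies of
the bacterial flagellar rotor type (FliM/FliG-like middle/C-terminal domain
complexes), but every stage is generic.

The pipeline:

1. **Conformer ensembles from one structure** — a reduced-representation
   distance-geometry engine: distance bounds are extracted from the
   structure (covalent Cα–Cα virtual bonds 3.80 ± 0.05 Å, tight backbone
   N–O hydrogen bonds unless labile, salt bridges, loose Cα contacts
   within 8 Å), and each conformer is rebuilt from a randomized start by
   iteratively projecting violating pairs onto their bounds (≤500 sweeps,
   tolerance 0.05 Å).
2. **Essential dynamics** — PCA of Cα fluctuations: eigenvalue spectra
   λ₁ ≥ λ₂ ≥ …, cumulative anisotropy, conformer spread
   σ = √(Σₖ λₖ) (nm), RMSF, per-residue B = (8π²/3)⟨|Δr|²⟩, and single-PC
   pseudo-trajectories.
3. **Fragment encoding + nMI networks** — each overlapping 4-residue Cα
   fragment becomes a structural-alphabet letter; normalized mutual
   information nMI = (I − ε)/H_joint between fragment columns, and between
   columns and equal-occupancy-binned PC projections (**nMI_PC**), whose
   peaks mark hinges; eigenvector centrality and prominence-based node
   calling summarize the network.
4. **Hinge mechanics** — difference-angle distributions between named
   line / plane-normal vector pairs; widths σ (population SD), serial-hinge
   amplification σ_distal/σ_proximal, single vs symmetric-double Gaussian
   fits `a·exp(−½((x−x₀)/b)²)` (+ mirrored term), torsional stiffness
   κ = k_BT/σ_rad², and linear / end-state / parabolic coupling relations.
5. **Deletion mimics** — remove a residue stretch, keep the numbering,
   ligate the flanks in the constraint set, regenerate and compare.
6. **Coevolution** — organism + gene-proximity pairing of two families,
   80 % redundancy filtering, mean-field DCA (direct information) and
   APC-corrected MI, top-fraction networks, and overlap of inter-protein
   couplings with structure contacts and dynamic-network nodes.

Synthetic fixtures with known ground truth (segmented-helix hinge polymers;
Potts-sampled paired alignments) make the whole pipeline testable offline.

## Worked example

```r
library(ensmech)

# two 19-residue helical segments, one hinge with Gaussian bend sd 10 deg
ens  <- make_hinge_ensemble(segments = c(19, 19), bend_sd = 10,
                            n = 4096, seed = 42)
defs <- hinge_vector_defs(c(19, 19))
bend <- angle_series(ens, c("AX1", "AX2"), defs, signed = TRUE,
                     sign_ref = "RN1")
angle_sigma(bend)
#> 10.04

m <- fit_pca(ens)
cumulative_anisotropy(m)[3]          # variance captured by PC1-3
#> 1.000
conformer_spread(m)$sigma_nm         # sqrt(lambda1+lambda2+lambda3), nm
#> 0.470

ft <- encode_ensemble(ens)           # structural-alphabet strings
pr <- nmi_pc_profile(ft, m, k = 1, n_bins = 10)
ft$positions$resno[which.max(pr)]    # hinge straddles residues 19|20
#> 18

fit <- fit_angle_models(bend)
c(fit$single$b, fit$single$r2)       # Gaussian well width, fit quality
#> 9.94  0.992
torsional_stiffness(fit$single$b)$kappa_pn_nm
#> 137
```

Reading the numbers: the signed difference angle across the hinge recovers
the generator's 10° width; essentially all ensemble variance lives in the
first PCs (one engineered hinge); the nMI_PC1 profile peaks at fragment 18,
i.e. the window spanning the hinge boundary; the histogram is a clean
single-Gaussian well of width ≈10°, corresponding to a torsional stiffness
of ≈137 pN·nm at 300 K.

## Analysis drivers

`analysis/01…05_*.R` are narrative Rscripts that run the stages on the
synthetic study systems and write tables under `results/`: hinge-width
recovery and stiffness (01), constraint-engine convergence, B-factor/SASA
profiles and two-domain hinge flexibility (02), fragment networks and node
calling (03), deletion-mimic comparison (04), and the coevolution workflow
(05). Run them from the repository root, e.g.
`Rscript analysis/01_hinge_fixture_mechanics.R`.

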