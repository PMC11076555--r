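# pdzcoupling

Tools for discovering and characterizing **internal PDZ-binding peptide
motifs** and the dynamics of peptide–PDZ domain complexes.

PDZ domains usually grip the free C-terminus of a partner protein, but some —
notably the PDZ domain of Dishevelled2 (Dvl2), the adapter that activates the
RhoA exchange factor WGEF in Wnt planar-cell-polarity signalling — also
recognize *internal* peptide stretches, in which an aspartate side chain
mimics the C-terminal carboxylate. Characterizing such a motif combines
several computational steps that this package implements as one tested
toolkit:

- **Motif scanning** with degenerate residue-class templates
  (`X-Y-G-W-Φa-D/G`, `X-W-Φa-D-G-P`, `W-Φs-D-X-P`, where `X` is any residue,
  `Φa` aliphatic \{A,V,L,I,M\} and `Φs` short hydrophilic \{S,T\}), scored per
  position with conservative-substitution credit, plus mapping of hits onto
  the PDZ **P-position nomenclature** (the carboxylate-mimicking Asp is P0,
  positions run …P−2, P−1, P0, P1, P2…).
- **Trajectory statistics**: per-residue RMSF
  (`RMSF_i = sqrt(mean_t |r_i(t) − r̄_i|²)` after superposition),
  side-chain **interaction propensity** (fraction of frames with a
  side-chain heavy atom within 4 Å of a domain residue), and β-strand
  propensity from backbone φ/ψ dihedrals.
- **Dynamical coupling**: the cross-correlation matrix
  `dC_ij = ⟨Δr_i·Δr_j⟩` over Cα displacement vectors (raw or normalized),
  replicate merging, and decomposition into **dynamical sectors** — clusters
  of co-moving residues — via eigenvalue retention against a shuffle null,
  independent-component rotation and coupling-based grouping.
- **Rigid-body superposition** (Kabsch, reflections excluded), pairwise RMSD
  matrices and residue-wise deviations between conformers.
- **Binding and kinetics fits**: 1:1 dissociation constants from titration
  series using the exact quadratic mass balance
  `fb = ([R]+[L]+K_d − sqrt(([R]+[L]+K_d)² − 4[R][L])) / (2[R])`,
  and single-exponential nucleotide-exchange decays
  `y(t) = y∞ + (y₀−y∞)e^(−kt)` with relative GEF activities.
- A **synthetic-data module** that generates every input with known ground
  truth: planted-covariance Cα trajectories, scripted-contact complexes,
  serial-dilution titrations, exchange traces and ortholog sequence sets.

## Worked example

Scan a fragment of human WGEF (full-length numbering via the offset), map the
hit onto P positions, and fit a dissociation constant from a synthetic
16-point 1:2 microscale-thermophoresis dilution series:

```r
library(pdzcoupling)

seq <- protein_sequence("hWGEF", paste0("MSPTRE", "GSTFSLWQDIP", "KARGEL"),
                        numbering_offset = 343L)
scan_motifs(seq)
#>   sequence_id   template start end matched score mismatches
#> 1       hWGEF W-Φs-D-X-P   355 359   WQDIP   0.8          1

map <- assign_pdz_positions("GSTFSLWQDIP")
t(setNames(map$p, map$residue))
#>       G  S  T  F  S  L  W  Q D I P
#> [1,] -8 -7 -6 -5 -4 -3 -2 -1 0 1 2
```

The single hit is the `WQDIP` core of the internal motif, with the anchor
aspartate at P0, tryptophan at P−2 and proline at P2 — the positions that
dominate internal-peptide binding to Dvl2's PDZ domain.

```r
ts <- gen_titration(45e-6, dilution_series(3.4e-3, 2, 16),
                    receptor = 50e-9, noise_frac = 0.02, seed = 17)
fit_kd(ts)
#> <fit_result> converged
#>   kd        4.23589e-05 (se 8.52e-07)
#>   unbound   -0.00139262 (se 0.00282)
#>   bound     0.98891 (se 0.00366)
```

A K_d of 45 µM planted under the experimental design (16 half-log-2
dilutions from 3.4 mM, 50 nM labelled receptor, 2 % noise) is recovered as
42.4 ± 0.9 µM. Planted dynamical sectors are recovered the same way:

```r
cov <- planted_sector_covariance(50, list(list(members = 1:10, rho = 0.8),
                                          list(members = 11:20, rho = 0.8)))
tr <- gen_trajectory(cov, 2000, seed = 3)
spectral_sectors(dccm(tr, fit = FALSE), seed = 3)
#> <sector_decomposition> 2 retained mode(s), 2 sector(s)
#>   sector_1: 10 residues
#>   sector_2: 10 residues
```

Both planted 10-residue blocks come back as separate sectors (Jaccard 1.0),
and a white-noise trajectory yields zero sectors.

A thin command-line wrapper over the same functions ships in
`inst/cli/pdzcoupling.R` (subcommands `scan-motif`, `dccm`, `sectors`,
`propensity`, `rmsf`, `fit-kd`, `simulate`, …); see
`Rscript inst/cli/pdzcoupling.R --help` after installation.

## Package layout

- `R/sequence-motif.R` — templates, scanner, P-position mapping, conservation
- `R/structure-io.R` — PDB / plain-text trajectory I/O, atom selections
- `R/superposition.R` — Kabsch superposition, pairwise RMSD
- `R/trajectory-analysis.R` — RMSF, contact propensity, SS propensity,
  residue deviations
- `R/dynamic-coupling.R` — DCCM, replicate merging, sector decomposition
- `R/binding-fits.R` — K_d and exchange-rate fits
- `R/synthetic-data.R` — ground-truth generators
- `vignettes/pdzcoupling-methods.Rmd` — models, parameter choices and
  limitations
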