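---
title: "Models and methods behind pdzcoupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pdzcoupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzcoupling)
```

This vignette is the package's own account of the models it implements, the
tunable parameters that matter, the numerical choices made where the design
was genuinely open, and the limits of what its synthetic-data validation can
show.

## The scientific setting

PDZ domains are ~90-residue peptide-binding modules that normally clamp the
free C-terminal carboxylate of a partner protein between their carboxylate
binding loop and the groove formed by strand β2 and helix α2. A smaller set
of interactions instead uses an *internal* peptide stretch, in which an
aspartate side chain stands in for the missing carboxylate. The PDZ domain
of Dishevelled2 (Dvl2), the signalling hub of Wnt pathways, is a prominent
internal-motif binder: it engages an internal motif of the RhoA exchange
factor WGEF to release the GEF from autoinhibition. Characterizing such an
interaction computationally involves (i) finding the candidate motif in
sequence, (ii) quantifying the peptide–domain contact statistics and
flexibility of the complex over trajectories, (iii) asking which domain
residues move as coupled groups ("sectors"), and (iv) fitting the binding
and activity measurements that anchor the model experimentally. The package
covers these four layers plus generators that produce each input with known
ground truth.

## Motif scanning

Templates are dash-delimited degenerate patterns over residue classes: `X`
(any residue), `Φa` (aliphatic, \{A,V,L,I,M\}), `Φs` (short-side-chain
hydrophilic, exactly \{S,T\}), literal residues, and alternations such as
`D/G`. The three bundled internal-peptide templates are `X-Y-G-W-Φa-D/G`,
`X-W-Φa-D-G-P` and `W-Φs-D-X-P`.

Known internal PDZ-binding motifs are not exact matches to these templates —
the WGEF motif places a glutamine at the `Φs` slot of `W-Φs-D-X-P` — so the
scanner scores windows instead of requiring membership at every position:
1 for class membership, `s_cons` (default 0.5) for a *conservative
substitution* (the residue shares one of the fixed substitution groups
\{D,E\}, \{N,Q\}, \{S,T\}, \{K,R\}, \{F,Y,W\}, \{A,V,L,I,M\} with a class
member), and 0 otherwise; the window score is the per-position mean. A
window is reported when its score reaches `min_score` (default 0.8) *and*
its count of zero-scoring positions stays within `max_strict_mismatches`
(default 1). Under these defaults the `WQDIP` core of the WGEF motif scores
0.8 with one strict mismatch (the Q) and is the only hit in its sequence
context, while exact template matches score 1. Both thresholds and the
substitution credit are arguments, because no mismatch tolerance is
canonical for this family of searches; the defaults are the package's
calibration to the known positive. Scanning is performed on whatever
sequence is supplied — full-length or domain-masked — since restricting the
search region is a modelling decision best left to the caller. An `X` in the
*target* sequence matches nothing (score 0): unknown residues should never
create hits.

Ties between equally scoring windows are broken by start position and then
by template order as supplied. Hit coordinates are 1-based inclusive in
full-length numbering via the sequence's `numbering_offset`.

P-position mapping implements the internal-motif anchor rule: the aspartate
whose side chain mimics the carboxylate is P0, residues toward the
C-terminus are P1, P2, …, and toward the N-terminus P−1, P−2, …. A peptide
with several aspartates is ambiguous; the mapping refuses to guess and
requires an explicit anchor index.

## Structures, trajectories, selections

Coordinates are Å throughout and residue numbering is 1-based author
numbering. The PDB reader handles multi-model files (one model per `MODEL`
record), resolves alternate locations by highest occupancy with ties going
to altloc `A`, and rejects insertion codes — a deliberate simplification
that keeps residue identity a plain integer. Malformed fixed-width records
report their line number. The package also defines `xyzt`, a plain-text
frame stack (`"natoms nframes"` header, then per frame one
`name resid resname chain x y z` line per atom) convenient for generated
trajectories; both formats must keep an identical atom order across frames.

Selections are deterministic predicates over chain, residue range, atom
names, and a side-chain flag. Side chains are heavy atoms excluding the
backbone set \{N, CA, C, O, OXT\}; glycine, which has no side-chain heavy
atom, is represented by its CA (configurable, including dropping glycines).
Hydrogens are excluded from all distance computations by default — contact
statistics on MD-derived structures are conventionally reported on heavy
atoms, and the choice is exposed should a hydrogen-aware variant be needed.

## Superposition and deviations

`kabsch()` computes the least-squares rigid superposition by singular value
decomposition of the weighted cross-covariance, with the determinant
correction that excludes reflections; inputs with fewer than three pairs or
(nearly) collinear geometry are rejected since the rotation is then not
unique. The test suite checks it against an independently implemented
quaternion (Horn) method.

Trajectory superposition fits every frame onto a reference and is used by
RMSF and the coupling matrix. The reference is built iteratively: frames are
first aligned to frame 1, then refit onto the running mean structure until
the mean stops moving (tolerance 1e-9 Å, at most 20 passes). A fixed
two-pass scheme was considered and rejected: when frames carry large
rigid-body motion the mean of unaligned frames is a degenerate reference and
two passes leave alignment residuals far above numerical noise, breaking the
expected invariance of fitted RMSF under per-frame rigid jitter. Iterating
to convergence restores that invariance to ~1e-6 Å.

`residue_deviation()` superposes two conformers globally on paired CA atoms
and reports per-residue CA displacements — the residue-wise counterpart of a
global RMSD between, say, apo and peptide-bound domain structures. Residues
may be excluded from the fit (while still being reported) to measure a local
displacement against an alignment of the unchanged remainder.

## Trajectory statistics

**RMSF.** `RMSF_i = sqrt(mean_t |r_i(t) − r̄_i|²)`, after the superposition
above when `fit = TRUE`. For isotropic Gaussian displacements with per-axis
standard deviation σ the expected value is σ√3, which the suite verifies at
σ = 0.5 Å over 5000 frames. Note that superposition absorbs the six
rigid-body degrees of freedom, deterministically shrinking RMSF by a factor
of about `sqrt(1 − 6/(3n))`; closed-form comparisons therefore run with
`fit = FALSE` on trajectories that contain no rigid motion.

**Interaction propensity.** Cell (i, j) is the fraction of frames in which
the minimum distance between the side-chain heavy atoms of peptide residue i
and *any* heavy atom of domain residue j is strictly below the cutoff
(default 4 Å). The asymmetric atom scope — side chain on the peptide side,
whole residue on the domain side — reflects that the statistic asks where
the peptide's side chains sit relative to domain residues; both scopes are
configurable. Distances exactly at the cutoff are non-contacts; this
convention only matters for constructed fixtures placed on the boundary.

**β-strand propensity.** Backbone φ/ψ are computed per frame from the N,
CA, C atoms of each residue and its chain neighbours, and a residue counts
as strand when φ ∈ [−180°, −45°] and ψ ∈ [45°, 180°] ∪ [−180°, −120°].
These dihedral boxes are this package's operational definition — generous
enough to cover ideal parallel and antiparallel strands while excluding
helical conformations — chosen because no single secondary-structure
algorithm is canonical for per-frame propensities and a dihedral rule keeps
the statistic self-contained (a DSSP-style assignment could be swapped in
without changing the interface). Terminal residues lack one of the two
dihedrals and are reported as missing (`NA`), never as zero.

## Dynamical coupling and sectors

The coupling matrix is the displacement covariance over (by default) Cα
atoms: `raw_ij = mean_t( Δr_i(t)·Δr_j(t) )` with `Δr = r − r̄`, a full 3-D
dot product — the standard reading of the cross-correlation
`⟨r_i r_j⟩ − ⟨r_i⟩⟨r_j⟩` for vector-valued positions. The normalized mode
divides by `sqrt(raw_ii · raw_jj)` (defined as 0 where either variance
vanishes) and is the default output, matching the convention of the
trajectory-analysis tools this field uses; the raw covariance is exposed for
when absolute amplitudes matter. Replicate runs are merged by frame
concatenation before analysis, which the suite verifies equals the pooled
covariance about the pooled mean.

Sector decomposition proceeds in four steps, each with an explicit rule:

1. **Mode retention.** Eigenvalues are compared against a null ensemble in
   which each residue's displacement series is permuted independently over
   frames — per-residue variances survive, all coupling dies. Modes whose
   eigenvalues exceed the *largest* eigenvalue seen in `n_null` (default
   100) null replicates are retained. When only the matrix is available
   (not the trajectory), the null is simulated from independent Gaussian
   series with matched per-residue variance and frame count, which has the
   same distribution for frame-exchangeable displacements; the trajectory
   can be supplied for a true permutation null. A fixed component count can
   be requested instead, mirroring workflows that report a set number of
   independent components.
2. **ICA rotation.** Retained eigenvectors are rotated by symmetric FastICA
   (tanh contrast, deterministic seeded start, implemented in-package),
   ordered by explained coupling variance, signs flipped so the largest
   loading is positive. For two planted blocks of equal strength, ICA
   legitimately converges to the symmetric/antisymmetric mixture basis —
   the contrast direction is more non-Gaussian than either block alone —
   which is why membership is read out per *sign*, not per component alone
   (step 3). Sector membership is identical across reseeded restarts on the
   planted fixtures.
3. **Membership.** Loadings are scaled by the square root of the coupling
   variance their component explains, putting them in units of the coupling
   they carry, and a residue joins the component (and sign) of its largest
   absolute scaled loading when that loading reaches the `loading_quantile`
   (default 0.9) of the *null ensemble's* scaled eigenvector entries. The
   threshold is referenced to the null rather than to the observed loading
   distribution deliberately: a quantile of the observed loadings depends on
   the (unknown) fraction of member residues and cannot separate members
   from background for any fixed default, whereas "larger than chance
   produces" is calibrated for free by the same null used for retention.
4. **Grouping.** Like-sign members of a component form a candidate group;
   opposite signs move in antiphase and are never pooled directly. Groups
   whose signed mean inter-group coupling exceeds the median off-diagonal
   |c_ij| are merged, and merged unions are reported as sectors, numbered
   by decreasing size. The signed criterion matters: rigid-body
   superposition of a trajectory with two independent coherent blocks
   induces genuine anticorrelation between them (the fitted rotation
   recoils), and an unsigned criterion would fuse what are dynamically
   opposing groups.

On the planted benchmark (two disjoint 10-residue blocks at intra-block
correlation 0.8 among 50 residues, 2000 frames) the decomposition returns
exactly the two blocks (Jaccard 1.0); on white noise it returns zero
sectors. Superposition is switched off for these fixtures since the
generator adds no rigid motion; with fitting on, the recoil coupling
described above additionally surfaces as a genuine sector of the fitted
coordinates.

## Binding and kinetics fits

**Dissociation constants.** Titration responses are modelled as affine in
the exact 1:1 bound fraction:
`response = U + (B − U)·fb([L]; K_d, [R])`, where `fb` solves the quadratic
mass balance and reduces to the hyperbola `[L]/(K_d + [L])` as `[R] → 0`.
Receptor depletion *lowers* the bound fraction relative to the hyperbola
(less free ligand than the total), with equality in the limit — at the 50 nM
receptor concentrations typical of the thermophoresis design the correction
is negligible, but the exact form costs nothing. The quadratic is evaluated
through its numerically stable root `2LR/(b + sqrt(b² − 4LR))`; the textbook
`(b − sqrt(·))/2` form loses all significant digits precisely in the
`[R] ≪ K_d` regime the assay lives in. Thermophoresis signal physics is not
modelled — responses are treated as affine in bound fraction, which is what
makes the fit identifiable from a concentration–response table alone.
`K_d` is fitted on the log scale (positivity for free) by Levenberg–
Marquardt least squares from five log-spaced starts spanning the
concentration range; `U` and `B` are linear plateaus. Fits whose optimum
falls outside `[min conc/100, max conc × 100]` are flagged poorly
determined, and series spanning under two orders of magnitude in ligand are
rejected outright. A grid-search oracle (1000 log-spaced `K_d` values,
linear parameters profiled out) confirms the optimizer lands within one
grid step.

**Exchange kinetics.** Fluorescence decays are fitted as
`y(t) = y∞ + (y₀ − y∞)e^(−kt)`, with starting values from a log-linearized
fit, the rate refined from five log-spaced multistarts, and standard errors
from the Jacobian. Non-convergence (including flat traces, where `k` is
unidentifiable) yields a *flagged* result rather than an exception, so batch
fitting survives degenerate wells. Relative GEF activity is the plain rate
ratio `k_variant / k_reference` with errors propagated in quadrature.

## Synthetic data: what it emulates and what it does not

The generators produce inputs whose ground truth is known exactly and
attached to each object (and exportable as a JSON sidecar):

- `planted_sector_covariance()` / `gen_trajectory()` build residue
  covariances with planted correlated blocks and draw i.i.d. frames per
  axis from the corresponding multivariate normal, so the normalized
  coupling matrix converges to the planted correlation (three independent
  per-axis draws make that target exact rather than axis-coupled).
- `gen_complex_trajectory()` scripts sub-cutoff contact events: each
  scheduled peptide–domain pair sits at 0.8 × cutoff in exactly
  `round(fraction × F)` frames (seeded shuffle) and at 2 × cutoff
  otherwise, on a 20 Å grid that keeps every unscheduled pair far outside
  the cutoff — so the propensity matrix is known exactly, not
  approximately.
- `gen_titration()` / `gen_exchange_trace()` apply multiplicative Gaussian
  noise to the exact fit models under the published experimental design
  (16-point 1:2 dilutions from 3.4 mM, 50 nM receptor; five-lifetime decay
  traces).
- `gen_ortholog_set()` embeds a motif in random flanks, conserving motif
  columns at a higher per-column rate (default 0.9) than the flank
  background (default 0.5), emulating an alignment of orthologs around a
  conserved binding motif. Defaults follow the study conditions: five
  orthologs, as in the sequence comparison that established the motif's
  conservation.

The deliberate omissions define what passing tests do and do not show.
Frames are i.i.d. — there is no temporal autocorrelation, no solvent, no
force field — so the trajectory statistics are validated as *estimators of
stationary quantities*, not as reproductions of molecular-dynamics physics;
correlation-time effects on convergence rates are out of scope. Scripted
complexes validate contact counting, not binding geometry. Titrations assume
the response is affine in bound fraction, which real thermophoresis data
only approximates.

## Problem sizes and determinism

The validation suite runs at sizes chosen to make sampling error a small
fraction of the tested tolerances while keeping the full suite under a
minute: 5000 frames for closed-form RMSF and correlation-convergence checks
(sampling error ~1/√F ≈ 1.4 %), 2000 frames and 100 null replicates for
sector recovery, 200 Monte-Carlo replicates for fit-bias checks, and 100
seeded ortholog sets for scanner localization. All generators are
bit-reproducible given their seed, and every stochastic analysis step
(null ensembles, ICA starts) is seed-controlled; reruns are byte-identical.

## Known limitations

- No insertion codes, no mmCIF, no compressed binary trajectory formats;
  adapters can wrap external readers but are not part of the contract.
- The scanner's thresholds are calibrated to a single known positive; on
  genome-scale searches the defaults will admit hits whose biological
  relevance must be judged separately (conservation profiling helps).
- The β-propensity dihedral boxes are a package definition, not a DSSP
  reimplementation; absolute propensities from different assignment rules
  differ at region boundaries.
- Sector decomposition inherits the usual indeterminacies of ICA; the
  sign-split readout and null-referenced threshold make membership stable
  on well-separated structure, but weakly coupled groups near the retention
  threshold can move between runs with different null seeds.
- The exchange model is a single exponential; multi-phase exchange or
  photobleaching backgrounds require a different model.
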