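Package: pdzcoupling
Title: Internal PDZ-Binding Motif Discovery and Dynamical Coupling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing internal PDZ-binding peptide motifs and
    the dynamics of peptide-PDZ domain complexes. Scans protein sequences with
    degenerate residue-class templates and maps hits onto PDZ P-position
    nomenclature; reads and writes multi-model PDB and plain-text trajectory
    formats; computes per-residue trajectory statistics (RMSF, side-chain
    contact propensity at a distance cutoff, beta-strand propensity from
    backbone dihedrals); builds dynamical cross-correlation matrices and
    decomposes them into independent components and dynamical sectors;
    performs Kabsch superposition and residue-wise deviation analysis; and
    fits single-exponential nucleotide-exchange traces and 1:1 binding
    isotherms from titration series. A synthetic-data module generates every
    input with known ground truth (planted-covariance trajectories, scripted
    contact schedules, titrations, exchange traces, ortholog sequence sets)
    for validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    minpack.lm,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
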