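# Synthetic-data generators with known ground truth.
#
# Every input the analysis pipeline consumes can be generated here with its
# ground truth attached: planted-covariance CA trajectories (stand-ins for MD
# runs), scripted-contact peptide-domain complexes, pseudo-structures,
# ortholog sequence sets, titration series and exchange traces. Displacements
# are drawn i.i.d. across frames — the DCCM and sector analysis depend only
# on the stationary covariance, so temporal correlation is deliberately not
# modelled. All generators are bit-reproducible given their seed.

#' Planted-sector residue covariance matrix
#'
#' Builds an n x n covariance with `Sigma_ii = variance_i`,
#' `Sigma_ij = rho_b sqrt(Sigma_ii Sigma_jj)` inside block b and 0 elsewhere.
#' If eigenvalue clipping is needed to restore positive semi-definiteness it
#' is applied and reported via a message.
#'
#' @param n_residues Number of residues.
#' @param blocks List of blocks, each `list(members = <indices>, rho = <r>)`;
#'   members must be disjoint across blocks.
#' @param variance Per-residue variance (Angstrom^2), scalar or length-n.
#' @return Symmetric PSD covariance matrix.
#' @export
planted_sector_covariance <- function(n_residues, blocks = list(),
                                      variance = 1) {
  v <- rep_len(variance, n_residues)
  all_members <- unlist(lapply(blocks, `[[`, "members"))
  if (anyDuplicated(all_members))
    stopf("covariance blocks overlap at residue %d",
          all_members[duplicated(all_members)][1])
  if (length(all_members) && (min(all_members) < 1 ||
                              max(all_members) > n_residues))
    stopf("block member outside 1..n_residues")
  S <- diag(v, n_residues)
  for (b in blocks) {
    m <- b$members
    for (i in m) for (j in m) if (i != j)
      S[i, j] <- b$rho * sqrt(v[i] * v[j])
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    message("planted covariance repaired by eigenvalue clipping (min eigenvalue ",
            format(min(ev$values)), ")")
    S <- ev$vectors %*% diag(pmax(ev$values, 0)) %*% t(ev$vectors)
    S <- (S + t(S)) / 2
  }
  S
}

#' Generate a CA trajectory from a residue covariance
#'
#' For each Cartesian axis independently, `n_frames` zero-mean multivariate
#' normal displacement vectors with the given covariance are drawn and added
#' to the base coordinates; consequently `E[dr_i . dr_j] = 3 cov_ij` and the
#' normalized DCCM converges to `corr(cov)`. Three independent per-axis draws
#' (rather than one shared draw) make that target exact.
#'
#' @param cov PSD residue covariance (Angstrom^2).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param base Optional `structure_model` with one CA per residue; a gentle
#'   CA-trace curve is built when omitted.
#' @return A `trajectory` with ground truth in `attr(, "ground_truth")`.
#' @export
gen_trajectory <- function(cov, n_frames, seed = 1L, base = NULL) {
  n <- nrow(cov)
  if (is.null(base))
    base <- build_chain_structure(strrep("A", n))
  ca <- select_atoms(base, ca_selection())
  if (length(ca) != n)
    stopf("base structure has %d CA atoms for a %d-residue covariance",
          length(ca), n)
  ev <- eigen(cov, symmetric = TRUE)
  if (min(ev$values) < -1e-10) stopf("covariance is not PSD")
  base_xyz <- coords_matrix(base)[ca, , drop = FALSE]
  frames <- array(NA_real_, c(n_frames, n, 3))
  with_local_seed(seed, {
    for (ax in 1:3) {
      D <- MASS::mvrnorm(n_frames, mu = rep(0, n), Sigma = cov)
      if (n_frames == 1L) D <- matrix(D, 1)
      frames[, , ax] <- sweep(D, 2, base_xyz[, ax], "+")
    }
  })
  topo <- base
  topo$atoms <- topo$atoms[ca, , drop = FALSE]
  rownames(topo$atoms) <- NULL
  tr <- trajectory(topo, frames)
  attr(tr, "ground_truth") <- list(covariance = cov, n_frames = n_frames,
                                   seed = seed)
  tr
}

#' Build a pseudo-structure for a peptide sequence
#'
#' Places CA atoms at 3.8 Angstrom spacing along a gentle (helix-free) arc;
#' `"pseudo-sidechain"` mode adds one CB atom 1.5 Angstrom off-axis per
#' non-glycine residue.
#'
#' @param sequence One-letter residue string.
#' @param mode `"ca-trace"` or `"pseudo-sidechain"`.
#' @param chain Chain identifier.
#' @return A `structure_model`.
#' @export
build_chain_structure <- function(sequence,
                                  mode = c("ca-trace", "pseudo-sidechain"),
                                  chain = "A") {
  mode <- match.arg(mode)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), names(AA1TO3))
  if (length(bad)) stopf("invalid residue letter(s): %s",
                         paste(bad, collapse = ", "))
  n <- length(chars)
  radius <- 60
  dtheta <- 2 * asin(3.8 / (2 * radius))
  theta <- (seq_len(n) - 1L) * dtheta
  ca <- cbind(radius * cos(theta), radius * sin(theta), 0)
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- AA1TO3[[chars[i]]]
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resid = i, resname = res3, chain = chain,
      x = ca[i, 1], y = ca[i, 2], z = ca[i, 3], stringsAsFactors = FALSE)
    if (mode == "pseudo-sidechain" && chars[i] != "G") {
      cb <- ca[i, ] * (radius + 1.5) / radius  # radially outward, 1.5 A
      rows[[length(rows) + 1L]] <- data.frame(
        name = "CB", resid = i, resname = res3, chain = chain,
        x = cb[1], y = cb[2], z = cb[3], stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows))
}

# Place a new atom D given atoms A-B-C, a B/C-D bond length, C angle B-C-D
# (degrees) and torsion A-B-C-D (degrees): natural extension reference frame.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an idealized backbone from phi/psi dihedrals
#'
#' Places N, CA and C atoms with ideal bond lengths and angles and
#' trans-peptide omega, so trajectories with prescribed backbone dihedrals
#' (ideal strand, helix, or mixtures) can be constructed for
#' secondary-structure propensity analysis.
#'
#' @param sequence One-letter residue string (length n).
#' @param phi,psi Dihedral vectors in degrees, length n (`phi[1]` and
#'   `psi[n]` are unused).
#' @param chain Chain identifier.
#' @return A `structure_model` with N, CA, C per residue.
#' @export
build_backbone_from_dihedrals <- function(sequence, phi, psi, chain = "A") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  stopifnot(length(phi) == n, length(psi) == n)
  # ideal geometry: N-CA 1.458, CA-C 1.525, C-N 1.329 A;
  # angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7 deg; omega 180
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  a <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1L)) {
    N[i + 1L, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    CA[i + 1L, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, 180)
    C[i + 1L, ] <- nerf_place(C[i, ], N[i + 1L, ], CA[i + 1L, ], 1.525, 111.2,
                              phi[i + 1L])
  }
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    res3 <- AA1TO3[[chars[i]]]
    data.frame(name = c("N", "CA", "C"), resid = i, resname = res3,
               chain = chain,
               x = c(N[i, 1], CA[i, 1], C[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3]), stringsAsFactors = FALSE)
  }))
  structure_model(rows)
}

#' Scripted-contact peptide-domain trajectory
#'
#' Builds a two-chain system (domain chain `A`: CA trace on a 20 Angstrom
#' grid; peptide chain `B`: CA plus CB side-chain proxy) in which each
#' scheduled peptide-domain residue pair sits at `0.8 * cutoff` in exactly
#' `round(fraction * n_frames)` frames (chosen by seeded shuffle) and at
#' `2 * cutoff` otherwise, so the interaction-propensity matrix is known by
#' construction. A peptide residue may appear in at most one schedule entry;
#' conflicting placements are an error.
#'
#' @param peptide One-letter peptide string.
#' @param domain_size Number of domain residues.
#' @param contact_schedule Data frame with columns `pep_res`, `dom_res`,
#'   `fraction` (frame fractions in \[0, 1\]).
#' @param cutoff Contact cutoff the schedule is scripted against (Angstrom).
#' @param n_frames Number of frames.
#' @param seed RNG seed for the frame shuffle.
#' @return A `trajectory` (peptide chain `"B"`, domain chain `"A"`) with the
#'   realized schedule in `attr(, "ground_truth")`.
#' @export
gen_complex_trajectory <- function(peptide, domain_size, contact_schedule,
                                   cutoff = 4.0, n_frames = 10L, seed = 1L) {
  chars <- strsplit(toupper(peptide), "")[[1]]
  np <- length(chars)
  sch <- as.data.frame(contact_schedule)
  if (nrow(sch)) {
    stopifnot(all(c("pep_res", "dom_res", "fraction") %in% names(sch)))
    if (any(sch$fraction < 0 | sch$fraction > 1))
      stopf("schedule fractions must lie in [0, 1]")
    if (anyDuplicated(sch$pep_res))
      stopf("infeasible simultaneous contacts: peptide residue %d scheduled twice",
            sch$pep_res[duplicated(sch$pep_res)][1])
    if (any(sch$pep_res < 1 | sch$pep_res > np) ||
        any(sch$dom_res < 1 | sch$dom_res > domain_size))
      stopf("schedule indexes a residue outside the system")
  }
  dom_x <- (seq_len(domain_size) - 1L) * 20
  rows <- list()
  for (j in seq_len(domain_size))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resid = j, resname = "ALA", chain = "A",
      x = dom_x[j], y = 0, z = 0, stringsAsFactors = FALSE)
  pep_rows <- list()
  for (i in seq_len(np)) {
    res3 <- AA1TO3[[chars[i]]]
    pep_rows[[length(pep_rows) + 1L]] <- data.frame(
      name = "CA", resid = i, resname = res3, chain = "B",
      x = (i - 1L) * 20, y = 50, z = 0, stringsAsFactors = FALSE)
    if (chars[i] != "G")
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        name = "CB", resid = i, resname = res3, chain = "B",
        x = (i - 1L) * 20, y = 48.5, z = 0, stringsAsFactors = FALSE)
  }
  topo <- structure_model(rbind(do.call(rbind, rows),
                                do.call(rbind, pep_rows)))
  at <- topo$atoms
  frames <- array(rep(as.matrix(at[, c("x", "y", "z")]),
                      each = n_frames),
                  c(n_frames, nrow(at), 3))
  realized <- sch
  if (nrow(sch)) realized$realized_fraction <- NA_real_
  with_local_seed(seed, {
    for (r in seq_len(nrow(sch))) {
      i <- sch$pep_res[r]; j <- sch$dom_res[r]
      n_contact <- round(sch$fraction[r] * n_frames)
      contact_frames <- if (n_contact > 0) sample.int(n_frames, n_contact)
                        else integer()
      proxy_name <- if (chars[i] == "G") "CA" else "CB"
      iprox <- which(at$chain == "B" & at$resid == i & at$name == proxy_name)
      ica <- which(at$chain == "B" & at$resid == i & at$name == "CA")
      for (f in seq_len(n_frames)) {
        d <- if (f %in% contact_frames) 0.8 * cutoff else 2 * cutoff
        frames[f, iprox, ] <- c(dom_x[j], d, 0)
        if (iprox != ica) frames[f, ica, ] <- c(dom_x[j], d + 1.5, 0)
      }
      realized$realized_fraction[r] <- n_contact / n_frames
    }
  })
  tr <- trajectory(topo, frames)
  attr(tr, "ground_truth") <- list(schedule = realized, cutoff = cutoff,
                                   n_frames = n_frames, seed = seed)
  tr
}

#' Simulate a titration series from a planted dissociation constant
#'
#' Responses follow the exact 1:1 binding model of [fit_kd()] with
#' multiplicative Gaussian noise.
#'
#' @param kd Planted dissociation constant, molar.
#' @param design Ligand concentrations, e.g. [dilution_series()] output.
#' @param receptor Receptor concentration, molar (default 50 nM).
#' @param noise_frac Multiplicative noise fraction (e.g. 0.02 for 2 percent).
#' @param seed RNG seed.
#' @param unbound,bound Response plateaus.
#' @return A `titration_series` with ground truth attached.
#' @export
gen_titration <- function(kd, design = dilution_series(3.4e-3, 2, 16),
                          receptor = 50e-9, noise_frac = 0.02, seed = 1L,
                          unbound = 0, bound = 1) {
  stopifnot(kd > 0, noise_frac >= 0)
  mu <- unbound + (bound - unbound) * fraction_bound(design, kd, receptor)
  y <- with_local_seed(seed, mu * (1 + noise_frac * stats::rnorm(length(mu))))
  out <- titration_series(design, y, receptor)
  attr(out, "ground_truth") <- list(kd = kd, receptor = receptor,
                                    noise_frac = noise_frac, seed = seed,
                                    unbound = unbound, bound = bound)
  out
}

#' Simulate a single-exponential exchange trace
#'
#' @param k Planted exchange rate (1/s).
#' @param y0,yinf Initial and plateau fluorescence.
#' @param n_points Number of time points.
#' @param t_max Final time; defaults to `5 / k` (five decay lifetimes).
#' @param noise_frac Multiplicative Gaussian noise fraction.
#' @param seed RNG seed.
#' @return An `exchange_trace` with ground truth attached.
#' @export
gen_exchange_trace <- function(k, y0 = 1, yinf = 0.2, n_points = 200L,
                               t_max = NULL, noise_frac = 0.01, seed = 1L) {
  stopifnot(k > 0, n_points >= 5L, noise_frac >= 0)
  t_max <- t_max %||% (5 / k)
  tt <- seq(0, t_max, length.out = n_points)
  mu <- yinf + (y0 - yinf) * exp(-k * tt)
  y <- with_local_seed(seed, mu * (1 + noise_frac * stats::rnorm(n_points)))
  out <- exchange_trace(tt, y)
  attr(out, "ground_truth") <- list(k = k, y0 = y0, yinf = yinf,
                                    noise_frac = noise_frac, seed = seed)
  out
}

#' Simulate an ortholog sequence set with an embedded motif
#'
#' A reference sequence of random flanks is drawn once; each ortholog copies
#' flank positions with probability `background_identity` (random residue
#' otherwise) and motif positions with probability `motif_conservation`, so
#' the motif columns are conserved above background, as in an alignment of
#' orthologous GEF sequences around a conserved PDZ-binding motif.
#'
#' @param motif One-letter motif string to embed.
#' @param n_seqs Number of orthologs.
#' @param flank_len Flank length on each side.
#' @param motif_conservation Per-column probability of keeping the motif
#'   residue.
#' @param background_identity Per-column probability of matching the
#'   reference in the flanks.
#' @param seed RNG seed.
#' @return List with `sequences` (list of `protein_sequence`, pre-aligned),
#'   `motif_start`, `motif_end` (1-based columns); ground truth attached.
#' @export
gen_ortholog_set <- function(motif, n_seqs = 5L, flank_len = 30L,
                             motif_conservation = 0.9,
                             background_identity = 0.5, seed = 1L) {
  mchars <- strsplit(toupper(motif), "")[[1]]
  stopifnot(all(mchars %in% AA_ALPHABET),
            motif_conservation >= 0, motif_conservation <= 1,
            background_identity >= 0, background_identity <= 1)
  len <- 2L * flank_len + length(mchars)
  motif_start <- flank_len + 1L
  motif_end <- flank_len + length(mchars)
  seqs <- with_local_seed(seed, {
    ref <- sample(AA_ALPHABET, len, replace = TRUE)
    ref[motif_start:motif_end] <- mchars
    lapply(seq_len(n_seqs), function(s) {
      chars <- vapply(seq_len(len), function(p) {
        keep_p <- if (p >= motif_start && p <= motif_end) motif_conservation
                  else background_identity
        if (stats::runif(1) < keep_p) ref[p] else sample(AA_ALPHABET, 1)
      }, character(1))
      protein_sequence(sprintf("ortholog_%d", s),
                       paste(chars, collapse = ""))
    })
  })
  out <- list(sequences = seqs, motif_start = motif_start,
              motif_end = motif_end)
  attr(out, "ground_truth") <- list(motif = motif, motif_start = motif_start,
                                    motif_end = motif_end,
                                    motif_conservation = motif_conservation,
                                    background_identity = background_identity,
                                    n_seqs = n_seqs, seed = seed)
  out
}

#' Write a generator's ground truth as a JSON sidecar
#'
#' @param x Any generator output carrying a `ground_truth` attribute.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stopf("object carries no ground_truth attribute")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
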