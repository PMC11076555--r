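# Per-residue trajectory statistics: RMSF, side-chain contact propensity at a
# distance cutoff, beta-strand propensity from backbone dihedrals, and
# residue-wise deviation between conformers.

residue_keys <- function(model, atom_idx) {
  unique(paste(model$atoms$chain[atom_idx], model$atoms$resid[atom_idx]))
}

residue_label <- function(model, chain, resid) {
  i <- which(model$atoms$chain == chain & model$atoms$resid == resid)[1]
  sprintf("%s%d%s", model$atoms$resname[i], resid,
          if (nzchar(trimws(chain))) paste0(":", chain) else "")
}

#' Superpose every trajectory frame onto the mean structure
#'
#' Frames are first aligned (Kabsch, on the selected atoms) onto the first
#' frame, then iteratively refit onto the running mean structure until the
#' mean stops moving (or `max_passes` is reached). The iteration removes the
#' dependence on the arbitrary reference frame of the raw coordinates, even
#' when frames carry large rigid-body motions.
#'
#' @param traj A `trajectory`.
#' @param sel Atoms used for fitting; default CA.
#' @param max_passes Maximum mean-structure iterations.
#' @param tol Convergence tolerance on the mean-structure RMSD between
#'   passes (Angstrom).
#' @return A `trajectory` with superposed frames.
#' @export
superpose_trajectory <- function(traj, sel = ca_selection(),
                                 max_passes = 20L, tol = 1e-9) {
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stopf("empty fitting selection")
  frames <- traj$frames
  f_n <- dim(frames)[1]
  refit <- function(frames, ref) {
    for (f in seq_len(f_n)) {
      sr <- kabsch(frames[f, idx, , drop = TRUE], ref)
      frames[f, , ] <- apply_transform(frames[f, , , drop = TRUE], sr)
    }
    frames
  }
  frames <- refit(frames, frames[1, idx, , drop = TRUE])
  ref <- apply(frames[, idx, , drop = FALSE], c(2, 3), mean)
  for (p in seq_len(max_passes)) {
    frames <- refit(frames, ref)
    new_ref <- apply(frames[, idx, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(mean(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) break
  }
  traj$frames <- frames
  traj
}

#' Root-mean-square fluctuation per selected atom
#'
#' RMSF_i = sqrt(mean_t |r_i(t) - rbar_i|^2). With `fit = TRUE` every frame
#' is first superposed onto the mean structure (two-pass iteration, Kabsch on
#' the selection).
#'
#' @param traj A `trajectory` with at least 2 frames.
#' @param sel Atom selection (default CA, one value per residue).
#' @param fit Superpose before measuring fluctuations?
#' @return Data frame of class `residue_profile` with columns `label`,
#'   `chain`, `resid`, `value` (Angstrom).
#' @export
rmsf <- function(traj, sel = ca_selection(), fit = TRUE) {
  if (n_frames(traj) < 2L) stopf("RMSF needs at least 2 frames")
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stopf("empty selection")
  if (fit) traj <- superpose_trajectory(traj, sel)
  X <- traj$frames[, idx, , drop = FALSE]
  mu <- apply(X, c(2, 3), mean)
  dev2 <- sapply(seq_along(idx), function(i)
    mean(rowSums((X[, i, , drop = TRUE] - matrix(mu[i, ], dim(X)[1], 3,
                                                 byrow = TRUE))^2)))
  at <- traj$topology$atoms
  out <- data.frame(
    label = vapply(idx, function(i)
      residue_label(traj$topology, at$chain[i], at$resid[i]), character(1)),
    chain = at$chain[idx], resid = at$resid[idx], value = sqrt(dev2),
    stringsAsFactors = FALSE)
  class(out) <- c("residue_profile", "data.frame")
  out
}

# Atom indices per residue for one side of the contact statistic.
contact_atom_groups <- function(traj, sel, sidechain, who) {
  base <- selection(chain = sel$chain, resid = sel$resid,
                    sidechain = sidechain, heavy_only = TRUE,
                    gly_proxy = sel$gly_proxy %||% "CA")
  idx <- select_atoms(traj, base)
  res_sel <- selection(chain = sel$chain, resid = sel$resid, heavy_only = TRUE)
  all_idx <- select_atoms(traj, res_sel)
  at <- traj$topology$atoms
  keys <- unique(paste(at$chain[all_idx], at$resid[all_idx], sep = "\r"))
  groups <- lapply(keys, function(k) {
    parts <- strsplit(k, "\r")[[1]]
    idx[at$chain[idx] == parts[1] & at$resid[idx] == as.integer(parts[2])]
  })
  empty <- lengths(groups) == 0L
  if (any(empty)) {
    k <- strsplit(keys[which(empty)[1]], "\r")[[1]]
    stopf("%s residue %s:%s has no qualifying heavy atoms", who, k[2], k[1])
  }
  names(groups) <- vapply(keys, function(k) {
    parts <- strsplit(k, "\r")[[1]]
    residue_label(traj$topology, parts[1], as.integer(parts[2]))
  }, character(1))
  groups
}

#' Peptide-domain interaction propensity matrix
#'
#' Cell (i, j) is the fraction of frames in which the minimum distance
#' between the side-chain heavy atoms of peptide residue i and any heavy atom
#' of domain residue j is strictly below `cutoff`. This is the probability of
#' the peptide residue side chain lying within the cutoff of the domain
#' residue; glycine side chains are represented by their CA proxy.
#'
#' @param traj A `trajectory`.
#' @param peptide_sel,domain_sel Disjoint `atom_selection`s delimiting the
#'   two molecules (typically by chain).
#' @param cutoff Distance cutoff in Angstrom (default 4.0). Distances equal
#'   to the cutoff count as non-contacts.
#' @return Matrix of frame fractions in \[0, 1\] with peptide residues as
#'   rows and domain residues as columns; attributes `cutoff`.
#' @export
interaction_propensity <- function(traj, peptide_sel, domain_sel,
                                   cutoff = 4.0) {
  pep <- contact_atom_groups(traj, peptide_sel, sidechain = TRUE, "peptide")
  dom <- contact_atom_groups(traj, domain_sel, sidechain = FALSE, "domain")
  if (length(intersect(unlist(pep), unlist(dom))))
    stopf("peptide and domain selections overlap")
  f_n <- n_frames(traj)
  out <- matrix(0, length(pep), length(dom),
                dimnames = list(names(pep), names(dom)))
  cut2 <- cutoff^2
  for (i in seq_along(pep)) {
    A <- traj$frames[, pep[[i]], , drop = FALSE]
    for (j in seq_along(dom)) {
      B <- traj$frames[, dom[[j]], , drop = FALSE]
      hits <- 0L
      for (f in seq_len(f_n)) {
        a <- matrix(A[f, , ], ncol = 3)
        b <- matrix(B[f, , ], ncol = 3)
        d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
        if (min(d2) < cut2) hits <- hits + 1L
      }
      out[i, j] <- hits / f_n
    }
  }
  attr(out, "cutoff") <- cutoff
  class(out) <- c("propensity_matrix", class(out))
  out
}

# Signed dihedral angle (degrees) defined by four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / nb, sum(n1 * n2)) * 180 / pi
}

in_beta_region <- function(phi, psi) {
  phi >= -180 & phi <= -45 &
    ((psi >= 45 & psi <= 180) | (psi >= -180 & psi <= -120))
}

#' Beta-strand propensity per residue from backbone dihedrals
#'
#' Backbone phi/psi angles are computed per frame from the N, CA and C atoms
#' of each residue and its chain neighbours. A residue is counted as strand
#' in a frame when phi lies in \[-180, -45\] degrees and psi in
#' \[45, 180\] or \[-180, -120\] degrees; the propensity is the strand frame
#' fraction. Terminal residues, which lack one of the two dihedrals, are
#' reported as `NA` rather than 0.
#'
#' @param traj A `trajectory` whose topology carries backbone atoms.
#' @param sel Residue scope (default: all residues).
#' @param class Secondary-structure class; only `"beta"` is defined.
#' @return Data frame of class `residue_profile` (`value` = strand frame
#'   fraction, `NA` for terminal residues).
#' @export
ss_propensity <- function(traj, sel = selection(), class = "beta") {
  class <- match.arg(class, "beta")
  at <- traj$topology$atoms
  scope <- select_atoms(traj, selection(chain = sel$chain, resid = sel$resid,
                                        atom_names = "CA"))
  if (!length(scope)) stopf("empty selection")
  f_n <- n_frames(traj)
  bb_index <- function(chain, resid, name) {
    i <- which(at$chain == chain & at$resid == resid & at$name == name)
    if (length(i) != 1L) NA_integer_ else i
  }
  rows <- lapply(scope, function(ca) {
    ch <- at$chain[ca]; rs <- at$resid[ca]
    iN <- bb_index(ch, rs, "N"); iCA <- ca; iC <- bb_index(ch, rs, "C")
    iCprev <- bb_index(ch, rs - 1L, "C")
    iNnext <- bb_index(ch, rs + 1L, "N")
    has_prev <- any(at$chain == ch & at$resid == rs - 1L)
    has_next <- any(at$chain == ch & at$resid == rs + 1L)
    if (!has_prev || !has_next)
      return(data.frame(chain = ch, resid = rs, value = NA_real_))
    if (is.na(iN) || is.na(iC) || is.na(iCprev) || is.na(iNnext))
      stopf("residue %d:%s lacks a backbone atom needed for phi/psi", rs, ch)
    n_beta <- 0L
    for (f in seq_len(f_n)) {
      co <- traj$frames[f, , ]
      phi <- dihedral_angle(co[iCprev, ], co[iN, ], co[iCA, ], co[iC, ])
      psi <- dihedral_angle(co[iN, ], co[iCA, ], co[iC, ], co[iNnext, ])
      if (in_beta_region(phi, psi)) n_beta <- n_beta + 1L
    }
    data.frame(chain = ch, resid = rs, value = n_beta / f_n)
  })
  out <- do.call(rbind, rows)
  out$label <- vapply(seq_len(nrow(out)), function(i)
    residue_label(traj$topology, out$chain[i], out$resid[i]), character(1))
  out <- out[, c("label", "chain", "resid", "value")]
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' Residue-wise deviation between two conformers
#'
#' After a single global Kabsch superposition on all paired CA atoms, the
#' per-residue CA displacement is reported — the residue-wise counterpart of
#' a global RMSD between, e.g., apo and peptide-bound domain structures.
#'
#' @param a,b `structure_model`s.
#' @param pairing Optional data frame with columns `resid_a`, `resid_b`
#'   (and optionally `chain_a`, `chain_b`); by default residues are paired by
#'   shared chain and residue number.
#' @param exclude_from_fit Residue numbers (in `a`) reported but excluded
#'   from the superposition, e.g. to measure a local displacement against an
#'   alignment of the unchanged remainder.
#' @return Data frame of class `residue_profile` (`value` = CA displacement
#'   in Angstrom after superposition, labels from `a`).
#' @export
residue_deviation <- function(a, b, pairing = NULL,
                              exclude_from_fit = integer()) {
  if (is.null(pairing)) {
    p <- shared_pairs(a, b, ca_selection())
    ia <- p$a; ib <- p$b
  } else {
    ca <- pairing$chain_a %||% rep(a$atoms$chain[1], nrow(pairing))
    cb <- pairing$chain_b %||% rep(b$atoms$chain[1], nrow(pairing))
    ia <- mapply(function(ch, rs)
      which(a$atoms$chain == ch & a$atoms$resid == rs & a$atoms$name == "CA")[1],
      ca, pairing$resid_a)
    ib <- mapply(function(ch, rs)
      which(b$atoms$chain == ch & b$atoms$resid == rs & b$atoms$name == "CA")[1],
      cb, pairing$resid_b)
    keep <- !is.na(ia) & !is.na(ib)
    ia <- ia[keep]; ib <- ib[keep]
  }
  if (!length(ia)) stopf("empty residue pairing")
  Xa <- coords_matrix(a)[ia, , drop = FALSE]
  Xb <- coords_matrix(b)[ib, , drop = FALSE]
  w <- as.numeric(!(a$atoms$resid[ia] %in% exclude_from_fit))
  sr <- kabsch(Xa, Xb, weights = w)
  dev <- sqrt(rowSums((apply_transform(Xa, sr) - Xb)^2))
  out <- data.frame(
    label = vapply(seq_along(ia), function(k)
      residue_label(a, a$atoms$chain[ia[k]], a$atoms$resid[ia[k]]),
      character(1)),
    chain = a$atoms$chain[ia], resid = a$atoms$resid[ia], value = dev,
    stringsAsFactors = FALSE)
  class(out) <- c("residue_profile", "data.frame")
  out
}
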