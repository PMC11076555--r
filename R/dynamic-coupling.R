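# Dynamical cross-correlation and sector decomposition.
#
# The dynamical cross-correlation matrix (DCCM) over CA displacement vectors,
# dC_ij = <r_i . r_j> - <r_i> . <r_j> (3-D dot products of displacements),
# captures which residues move together over a trajectory. Spectral
# decomposition of the (normalized) DCCM, followed by an independent-component
# rotation of the retained eigenmodes, groups residues into dynamical
# "sectors": clusters of mutually coupled amino acids of the kind produced by
# statistical coupling analysis.

#' Dynamical cross-correlation matrix of a trajectory
#'
#' After optional superposition onto the mean structure (two passes, Kabsch
#' on the selection), the raw coupling is
#' `raw_ij = mean_t( dr_i(t) . dr_j(t) )` with `dr = r - rbar` (3-D dot
#' product, units Angstrom^2). The normalized mode divides by
#' `sqrt(raw_ii raw_jj)` and is defined 0 where either variance vanishes;
#' its diagonal is 1 wherever the variance is positive.
#'
#' @param traj A `trajectory` with at least 2 frames.
#' @param sel Atom selection, one atom per residue (default CA).
#' @param mode `"normalized"` (default, dimensionless in \[-1, 1\]) or
#'   `"raw"` (covariance, Angstrom^2).
#' @param fit Superpose frames before computing displacements?
#' @return A symmetric matrix of class `coupling_matrix` with residue labels
#'   as dimnames and attributes `mode`, `n_frames`, `variances` (raw
#'   diagonal).
#' @export
dccm <- function(traj, sel = ca_selection(), mode = c("normalized", "raw"),
                 fit = TRUE) {
  mode <- match.arg(mode)
  if (n_frames(traj) < 2L) stopf("DCCM needs at least 2 frames")
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stopf("empty selection")
  if (fit) traj <- superpose_trajectory(traj, sel)
  X <- traj$frames[, idx, , drop = FALSE]
  f_n <- dim(X)[1]; n <- dim(X)[2]
  C <- matrix(0, n, n)
  for (ax in 1:3) {
    D <- X[, , ax]
    D <- sweep(D, 2, colMeans(D))
    C <- C + crossprod(D) / f_n
  }
  v <- diag(C)
  if (mode == "normalized") {
    denom <- sqrt(outer(v, v))
    Cn <- ifelse(denom > 0, C / denom, 0)
    diag(Cn) <- ifelse(v > 0, 1, 0)
    C <- Cn
  }
  at <- traj$topology$atoms
  labels <- vapply(idx, function(i)
    residue_label(traj$topology, at$chain[i], at$resid[i]), character(1))
  dimnames(C) <- list(labels, labels)
  C <- (C + t(C)) / 2
  attr(C, "mode") <- mode
  attr(C, "n_frames") <- f_n
  attr(C, "variances") <- stats::setNames(v, labels)
  class(C) <- c("coupling_matrix", class(C))
  C
}

#' Concatenate replicate trajectories
#'
#' Frames are concatenated in argument order; topologies must be identical
#' (same atoms in the same order). Replicate runs are typically merged before
#' dynamical coupling analysis so the DCCM pools all frames.
#'
#' @param trajs List of `trajectory` objects.
#' @return A single `trajectory`.
#' @export
merge_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  sig <- topology_signature(trajs[[1]]$topology)
  for (k in seq_along(trajs)) {
    if (!identical(topology_signature(trajs[[k]]$topology), sig))
      stopf("trajectory %d has a different topology", k)
  }
  total <- sum(vapply(trajs, n_frames, integer(1)))
  natoms <- dim(trajs[[1]]$frames)[2]
  frames <- array(NA_real_, c(total, natoms, 3))
  off <- 0L
  for (tr in trajs) {
    f <- n_frames(tr)
    frames[(off + 1L):(off + f), , ] <- tr$frames
    off <- off + f
  }
  trajectory(trajs[[1]]$topology, frames,
             frame_spacing = trajs[[1]]$frame_spacing)
}

# Symmetric FastICA (tanh contrast) on an n x k whitened loading matrix.
# Returns the rotated n x k component matrix with unit-norm columns.
fastica_rotate <- function(Z, seed, max_iter = 500L, tol = 1e-10) {
  n <- nrow(Z); k <- ncol(Z)
  if (k == 1L) return(Z / sqrt(sum(Z^2)))
  # scale columns to unit variance so Z acts as whitened data (n samples)
  Zw <- sweep(Z, 2, sqrt(colMeans(Z^2)), "/")
  W <- with_local_seed(seed, {
    qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-15)), k) %*%
      t(e$vectors)
    solve_sqrt %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- Zw %*% t(W)            # n x k projections
    G <- tanh(WX)
    Gp <- 1 - G^2
    W_new <- t(G) %*% Zw / n - diag(colMeans(Gp), k) %*% W
    W_new <- sym_decorrelate(W_new)
    conv <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (conv < tol) break
  }
  S <- Zw %*% t(W)
  sweep(S, 2, sqrt(colSums(S^2)), "/")
}

# Null coupling matrices with per-residue variance preserved and coupling
# destroyed. With a trajectory: each residue's displacement series is
# independently permuted over frames. Without: independent Gaussian series
# with matched variance and frame count (equivalent in distribution for
# frame-exchangeable displacements).
null_coupling <- function(cm, traj, sel, fit, n_null, seed) {
  mode <- attr(cm, "mode") %||% "normalized"
  f_n <- attr(cm, "n_frames")
  n <- nrow(cm)
  v <- attr(cm, "variances") %||% diag(cm)
  with_local_seed(seed, {
    if (!is.null(traj)) {
      idx <- select_atoms(traj, sel)
      tr <- if (fit) superpose_trajectory(traj, sel) else traj
      X <- tr$frames[, idx, , drop = FALSE]
      lapply(seq_len(n_null), function(r) {
        Xp <- X
        for (i in seq_len(dim(X)[2])) {
          perm <- sample.int(dim(X)[1])
          Xp[, i, ] <- X[perm, i, ]
        }
        C <- matrix(0, n, n)
        for (ax in 1:3) {
          D <- sweep(Xp[, , ax], 2, colMeans(Xp[, , ax]))
          C <- C + crossprod(D) / dim(X)[1]
        }
        if (mode == "normalized") {
          dn <- sqrt(outer(diag(C), diag(C)))
          C <- ifelse(dn > 0, C / dn, 0); diag(C) <- 1
        }
        C
      })
    } else {
      if (is.null(f_n))
        stopf("coupling matrix lacks an n_frames attribute; supply traj or n_frames")
      sd_ax <- sqrt(pmax(v, 0) / 3)
      lapply(seq_len(n_null), function(r) {
        C <- matrix(0, n, n)
        for (ax in 1:3) {
          D <- matrix(stats::rnorm(f_n * n), f_n, n) %*% diag(sd_ax, n)
          D <- sweep(D, 2, colMeans(D))
          C <- C + crossprod(D) / f_n
        }
        if (mode == "normalized") {
          dn <- sqrt(outer(diag(C), diag(C)))
          C <- ifelse(dn > 0, C / dn, 0); diag(C) <- 1
        }
        C
      })
    }
  })
}

#' Dynamical sectors by spectral decomposition and ICA rotation
#'
#' Eigenvalues of the coupling matrix exceeding the largest eigenvalue seen
#' in a null ensemble (per-residue displacement series independently
#' permuted, which preserves variances and destroys coupling) define the
#' retained modes; a fixed `n_components` may be supplied instead. Retained
#' eigenvectors are rotated into independent components (symmetric FastICA,
#' tanh contrast); components are ordered by the coupling variance they
#' explain, with signs flipped so each component's largest-magnitude loading
#' is positive. Loadings are scaled by the square root of the coupling
#' variance their component explains, so a loading is read in units of the
#' coupling it carries; the membership threshold is the `loading_quantile`
#' of the same scaled quantity in the null ensemble (eigenvector entries of
#' the null matrices scaled by the root of their eigenvalues) — i.e. a
#' loading larger than chance produces. Each residue is assigned to the
#' component (and loading sign) of its largest absolute scaled loading.
#' Residues of like sign on a component form a candidate group — opposite
#' signs mark anticorrelated motions and are never pooled directly — and
#' groups whose motions remain positively coupled (signed mean inter-group
#' `c_ij` above the median off-diagonal |c_ij|) are merged into one sector;
#' sectors are numbered by decreasing size.
#'
#' @param cm A `coupling_matrix` (typically normalized).
#' @param n_components `"auto"` (null-thresholded retention) or a fixed
#'   integer number of components.
#' @param loading_quantile Quantile of the null loading distribution used as
#'   the membership threshold (default 0.9).
#' @param null Null model; `"shuffle"` (residue-wise permutation of the
#'   displacement series, or matched independent Gaussian series when no
#'   trajectory is supplied).
#' @param n_null Number of null replicates (default 100).
#' @param seed Seed controlling the null ensemble and the ICA start.
#' @param traj Optional source `trajectory` for the permutation null.
#' @param sel,fit Selection and superposition flag matching the [dccm()] call
#'   that produced `cm` (used only with `traj`).
#' @return An object of class `sector_decomposition`: list with
#'   `eigenvalues`, `n_retained`, `components` (n x k loading matrix),
#'   `assignments` (component index per residue, `NA` for non-members),
#'   `sectors` (named list of residue-label sets), `eigenvalue_threshold`,
#'   `loading_threshold`.
#' @export
spectral_sectors <- function(cm, n_components = "auto", loading_quantile = 0.9,
                             null = "shuffle", n_null = 100L, seed = 1L,
                             traj = NULL, sel = ca_selection(), fit = TRUE) {
  null <- match.arg(null, "shuffle")
  M <- unclass(cm)
  attributes(M)[setdiff(names(attributes(M)), c("dim", "dimnames"))] <- NULL
  if (max(abs(M - t(M))) > 1e-10) stopf("coupling matrix must be symmetric")
  n <- nrow(M)
  labels <- rownames(M) %||% as.character(seq_len(n))
  e <- eigen(M, symmetric = TRUE)
  nulls <- null_coupling(cm, traj, sel, fit, n_null, seed)
  null_eigs <- lapply(nulls, function(N) eigen(N, symmetric = TRUE))
  lambda_max_null <- max(vapply(null_eigs, function(x) x$values[1], numeric(1)))
  if (identical(n_components, "auto")) {
    k <- sum(e$values > lambda_max_null)
  } else {
    k <- min(as.integer(n_components), n)
  }
  res <- list(eigenvalues = e$values, n_retained = k,
              eigenvalue_threshold = lambda_max_null,
              labels = labels,
              params = list(n_components = n_components,
                            loading_quantile = loading_quantile,
                            null = null, n_null = n_null, seed = seed))
  if (k == 0L) {
    res$components <- matrix(numeric(0), n, 0)
    res$assignments <- rep(NA_integer_, n)
    res$loading_threshold <- NA_real_
    res$sectors <- list()
    class(res) <- "sector_decomposition"
    return(res)
  }
  V <- e$vectors[, seq_len(k), drop = FALSE]
  S <- fastica_rotate(V, seed = seed)
  # canonical order: decreasing explained coupling variance; canonical sign:
  # largest-|loading| entry positive
  expl <- vapply(seq_len(ncol(S)), function(c)
    as.numeric(t(S[, c]) %*% M %*% S[, c]), numeric(1))
  ord <- order(-expl)
  S <- S[, ord, drop = FALSE]
  expl <- expl[ord]
  for (c in seq_len(ncol(S))) {
    i <- which.max(abs(S[, c]))
    if (S[i, c] < 0) S[, c] <- -S[, c]
  }
  rownames(S) <- labels
  # loadings in units of the coupling variance the component explains
  Ssc <- sweep(S, 2, sqrt(pmax(expl, 0)), "*")
  # membership threshold: same scaled quantity under the null
  null_loadings <- unlist(lapply(null_eigs, function(x) {
    kk <- seq_len(min(k, n))
    abs(sweep(x$vectors[, kk, drop = FALSE], 2,
              sqrt(pmax(x$values[kk], 0)), "*"))
  }))
  thr <- stats::quantile(null_loadings, loading_quantile, names = FALSE)
  best <- apply(abs(Ssc), 1, which.max)
  best_val <- abs(Ssc)[cbind(seq_len(n), best)]
  best_sign <- sign(Ssc)[cbind(seq_len(n), best)]
  assignments <- ifelse(best_val >= thr, best, NA_integer_)
  # candidate groups: like-sign members of each component
  groups <- list()
  for (c in seq_len(ncol(S))) {
    for (sgn in c(1, -1)) {
      g <- which(assignments == c & best_sign == sgn)
      if (length(g)) groups[[length(groups) + 1L]] <- g
    }
  }
  # merge groups whose motions stay positively coupled
  med <- stats::median(abs(M[upper.tri(M)]))
  ng <- length(groups)
  parent <- seq_len(max(ng, 1L))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (ng > 1L) {
    for (a in seq_len(ng - 1L)) {
      for (b in (a + 1L):ng) {
        inter <- mean(M[groups[[a]], groups[[b]], drop = FALSE])
        if (inter > med) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  sector_sets <- list()
  if (ng) {
    roots <- vapply(seq_len(ng), find, integer(1))
    sector_sets <- lapply(unique(roots), function(r)
      labels[sort(unique(unlist(groups[roots == r])))])
    sector_sets <- sector_sets[order(-lengths(sector_sets))]
    names(sector_sets) <- paste0("sector_", seq_along(sector_sets))
  }
  res$components <- S
  res$scaled_loadings <- Ssc
  res$assignments <- assignments
  res$loading_threshold <- thr
  res$sectors <- sector_sets
  class(res) <- "sector_decomposition"
  res
}

#' @export
print.sector_decomposition <- function(x, ...) {
  cat(sprintf("<sector_decomposition> %d retained mode(s), %d sector(s)\n",
              x$n_retained, length(x$sectors)))
  for (nm in names(x$sectors))
    cat(sprintf("  %s: %d residues\n", nm, length(x$sectors[[nm]])))
  invisible(x)
}

#' Write a coupling matrix as labelled TSV
#' @param cm A `coupling_matrix`.
#' @param path Output path.
#' @export
write_coupling_tsv <- function(cm, path) {
  utils::write.table(as.data.frame(unclass(cm)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' Read a coupling matrix from labelled TSV
#' @param path Input path.
#' @param mode Matrix mode recorded on the result.
#' @param n_frames Frame count of the source trajectory (needed for the
#'   simulated null in [spectral_sectors()]).
#' @return A `coupling_matrix`.
#' @export
read_coupling_tsv <- function(path, mode = "normalized", n_frames = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  C <- as.matrix(df)
  attr(C, "mode") <- mode
  if (!is.null(n_frames)) attr(C, "n_frames") <- as.integer(n_frames)
  attr(C, "variances") <- diag(C)
  class(C) <- c("coupling_matrix", class(C))
  C
}
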