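# Optimal rigid-body superposition (Kabsch) and pairwise RMSD.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between paired coordinate sets, mapping `X` onto `Y` (reflections are
#' excluded).
#'
#' @param X,Y n x 3 matrices of paired coordinates (Angstrom).
#' @param weights Optional non-negative per-pair weights.
#' @return An object of class `superposition_result`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3) such that
#'   `X %*% t(rotation) + translation` superposes onto `Y`, and `rmsd`.
#' @export
kabsch <- function(X, Y, weights = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    stopf("X and Y must be equal-size n x 3 matrices")
  n <- nrow(X)
  if (n < 3L) stopf("need at least 3 paired points")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0)
    stopf("weights must be non-negative with positive sum")
  w <- w / sum(w)
  cx <- colSums(X * w); cy <- colSums(Y * w)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc * sqrt(w))$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1))
    stopf("points are (nearly) collinear; superposition is degenerate")
  H <- crossprod(Xc * w, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cy - as.numeric(R %*% cx)
  Xt <- X %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((Xt - Y)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

apply_transform <- function(coords, sr) {
  coords %*% t(sr$rotation) +
    matrix(sr$translation, nrow(coords), 3, byrow = TRUE)
}

# Shared (chain, resid) pairs carrying the selected atom in both models.
shared_pairs <- function(a, b, sel) {
  ia <- select_atoms(a, sel); ib <- select_atoms(b, sel)
  ka <- paste(a$atoms$chain[ia], a$atoms$resid[ia])
  kb <- paste(b$atoms$chain[ib], b$atoms$resid[ib])
  common <- intersect(ka, kb)
  list(a = ia[match(common, ka)], b = ib[match(common, kb)], keys = common)
}

#' Pairwise RMSD matrix over structure models
#'
#' Entry (a, b) is the Kabsch RMSD over the residues shared between the two
#' models (paired by chain and author residue number on the selected atoms;
#' residues unresolved in either model are dropped pairwise). Pairs sharing
#' fewer than 3 residues are flagged `NA`.
#'
#' @param models List of `structure_model`s (length >= 2).
#' @param sel Atom selection used for pairing; default CA.
#' @return Symmetric numeric matrix of RMSDs (Angstrom), zero diagonal.
#' @export
pairwise_rmsd <- function(models, sel = ca_selection()) {
  m <- length(models)
  if (m < 2L) stopf("need at least 2 models")
  out <- matrix(0, m, m)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      p <- shared_pairs(models[[a]], models[[b]], sel)
      if (length(p$a) < 3L) {
        out[a, b] <- out[b, a] <- NA_real_
        next
      }
      r <- kabsch(coords_matrix(models[[a]])[p$a, , drop = FALSE],
                  coords_matrix(models[[b]])[p$b, , drop = FALSE])$rmsd
      out[a, b] <- out[b, a] <- r
    }
  }
  out
}
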