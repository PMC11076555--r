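# Independent oracles and small fixture builders used across the suite.
# Each oracle re-derives the quantity it checks by a different route than the
# implementation (explicit enumeration, closed form, or an alternative
# algorithm) so agreement is informative.

# -- brute-force motif scanner -----------------------------------------------
# Enumerates every window x template and scores it independently of
# scan_motifs(): direct set lookups, no shared code path.
oracle_scan <- function(seq_string, templates, min_score, max_mm,
                        s_cons = 0.5) {
  groups <- list(c("D", "E"), c("N", "Q"), c("S", "T"), c("K", "R"),
                 c("F", "Y", "W"), c("A", "V", "L", "I", "M"))
  chars <- strsplit(toupper(seq_string), "")[[1]]
  hits <- list()
  for (ti in seq_along(templates)) {
    tmpl <- templates[[ti]]
    w <- length(tmpl$sets)
    if (length(chars) < w) next
    for (start in 1:(length(chars) - w + 1)) {
      scores <- numeric(w)
      for (p in 1:w) {
        res <- chars[start + p - 1]
        set <- tmpl$sets[[p]]
        if (res %in% set) {
          scores[p] <- 1
        } else if (res %in% c("X", "-")) {
          scores[p] <- 0
        } else {
          cons <- FALSE
          for (g in groups)
            if (res %in% g && any(set %in% g)) cons <- TRUE
          scores[p] <- if (cons) s_cons else 0
        }
      }
      if (mean(scores) >= min_score && sum(scores == 0) <= max_mm)
        hits[[length(hits) + 1]] <- data.frame(
          template = tmpl$name, start = start, end = start + w - 1,
          score = mean(scores), mismatches = sum(scores == 0),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(template = character(),
                                       start = integer(), end = integer(),
                                       score = numeric(),
                                       mismatches = integer()))
  do.call(rbind, hits)
}

# -- quaternion (Horn) superposition oracle ----------------------------------
# Closed-form optimal rotation via the largest eigenvector of the 4x4
# quaternion matrix; an algorithm independent of the SVD-based Kabsch.
oracle_quaternion_rmsd <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  M <- crossprod(Xc, Yc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  sqrt(mean(rowSums((Xc %*% t(R) - Yc)^2)))
}

# -- per-frame minimum-distance contact oracle -------------------------------
# Counts contact frames for one residue pair by explicit per-frame, per-atom
# distance loops.
oracle_contact_fraction <- function(traj, pep_atom_idx, dom_atom_idx,
                                    cutoff) {
  f_n <- dim(traj$frames)[1]
  hits <- 0
  for (f in seq_len(f_n)) {
    mind <- Inf
    for (i in pep_atom_idx) for (j in dom_atom_idx) {
      d <- sqrt(sum((traj$frames[f, i, ] - traj$frames[f, j, ])^2))
      if (d < mind) mind <- d
    }
    if (mind < cutoff) hits <- hits + 1
  }
  hits / f_n
}

# -- grid-search K_d oracle --------------------------------------------------
# Profiles the two linear parameters by least squares at each of 1000
# log-spaced K_d values; returns the K_d of minimal RSS and the log-grid step.
oracle_kd_grid <- function(series, n_grid = 1000) {
  L <- series$conc; y <- series$response; R <- series$receptor
  grid <- exp(seq(log(min(L) / 10), log(max(L) * 10), length.out = n_grid))
  rss <- vapply(grid, function(kd) {
    fb <- fraction_bound(L, kd, R)
    fit <- stats::lm(y ~ fb)
    sum(stats::resid(fit)^2)
  }, numeric(1))
  list(kd = grid[which.min(rss)],
       log_step = diff(log(grid[1:2])))
}

# -- small fixture builders --------------------------------------------------
static_frames <- function(model, f_n) {
  co <- as.matrix(model$atoms[, c("x", "y", "z")])
  a <- array(NA_real_, c(f_n, nrow(co), 3))
  for (f in seq_len(f_n)) a[f, , ] <- co
  a
}

static_trajectory <- function(model, f_n) trajectory(model, static_frames(model, f_n))

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3))) -> Q
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

random_aa_string <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
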