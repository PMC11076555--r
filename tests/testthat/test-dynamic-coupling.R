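# DCCM, trajectory merging and sector decomposition.

test_that("DCCM of a static trajectory is zero (raw) and diagonal-1 rule holds", {
  m <- build_chain_structure("GSTFS")
  tr <- static_trajectory(m, 4)
  raw <- dccm(tr, mode = "raw", fit = FALSE)
  expect_equal(max(abs(unclass(raw))), 0)
  norm <- dccm(tr, mode = "normalized", fit = FALSE)
  expect_equal(diag(unclass(norm)), rep(0, 5), ignore_attr = TRUE)

  tr2 <- gen_trajectory(diag(5), 20, seed = 1)
  norm2 <- unclass(dccm(tr2, fit = FALSE))
  expect_equal(diag(norm2), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(abs(norm2) <= 1 + 1e-12))
})

test_that("DCCM equals a hand covariance computation on a listed trajectory", {
  m <- build_chain_structure("AA")
  fr <- array(0, c(4, 2, 3))
  fr[, 1, ] <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 1))
  fr[, 2, ] <- rbind(c(5, 0, 0), c(6, 0, 0), c(6, 1, 0), c(5, 1, 1))
  tr <- trajectory(m, fr)
  got <- unclass(dccm(tr, mode = "raw", fit = FALSE))
  want <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    di <- sweep(fr[, i, ], 2, colMeans(fr[, i, ]))
    dj <- sweep(fr[, j, ], 2, colMeans(fr[, j, ]))
    want[i, j] <- mean(rowSums(di * dj))
  }
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("DCCM matches the independent bio3d implementation", {
  skip_if_not_installed("bio3d")
  cov <- planted_sector_covariance(12, list(list(members = 1:4, rho = 0.6)))
  tr <- gen_trajectory(cov, 300, seed = 7)
  got <- unclass(dccm(tr, fit = FALSE))
  X <- matrix(NA_real_, 300, 36)
  for (f in 1:300) X[f, ] <- t(tr$frames[f, , ])
  want <- unclass(bio3d::dccm.xyz(X))
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("fitted DCCM is invariant to uniform rigid-body frame motion", {
  cov <- planted_sector_covariance(8, list(list(members = 1:3, rho = 0.7)))
  tr <- gen_trajectory(cov, 100, seed = 5)
  moved <- tr
  set.seed(6)
  for (f in 1:100)
    moved$frames[f, , ] <- tr$frames[f, , ] %*% t(random_rotation()) +
      matrix(rnorm(3, sd = 4), 8, 3, byrow = TRUE)
  expect_equal(unclass(dccm(moved, fit = TRUE)),
               unclass(dccm(tr, fit = TRUE)),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("raw DCCM scales quadratically, normalized is scale-invariant", {
  tr <- gen_trajectory(diag(0.5, 6), 50, seed = 8)
  scaled <- tr
  scaled$frames <- tr$frames * 3
  expect_equal(unclass(dccm(scaled, mode = "raw", fit = FALSE)),
               9 * unclass(dccm(tr, mode = "raw", fit = FALSE)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unclass(dccm(scaled, fit = FALSE)),
               unclass(dccm(tr, fit = FALSE)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("normalized DCCM converges to the planted correlation", {
  blocks <- list(list(members = 1:10, rho = 0.8),
                 list(members = 11:20, rho = 0.8))
  cov <- planted_sector_covariance(50, blocks)
  tr <- gen_trajectory(cov, 5000, seed = 13)
  cm <- unclass(dccm(tr, fit = FALSE))
  target <- stats::cov2cor(cov)
  expect_lt(max(abs(cm - target)), 0.05)
})

test_that("merging concatenates frames and checks topology", {
  cov <- diag(4)
  t1 <- gen_trajectory(cov, 100, seed = 1)
  t2 <- gen_trajectory(cov, 100, seed = 2)
  t3 <- gen_trajectory(cov, 100, seed = 3)
  mg <- merge_trajectories(list(t1, t2, t3))
  expect_equal(dim(mg$frames)[1], 300)
  expect_equal(merge_trajectories(list(t1))$frames, t1$frames)
  bad <- gen_trajectory(diag(5), 10, seed = 4)
  expect_error(merge_trajectories(list(t1, bad)), "topology")
})

test_that("DCCM of merged replicates equals the pooled-moment covariance", {
  cov <- planted_sector_covariance(6, list(list(members = 1:2, rho = 0.5)))
  reps <- lapply(1:3, function(s) gen_trajectory(cov, 40, seed = s))
  got <- unclass(dccm(merge_trajectories(reps), mode = "raw", fit = FALSE))
  # pooled oracle: stack all displacement series about the pooled mean
  allfr <- do.call(abind_frames <- function(l) {
    arr <- array(NA_real_, c(120, 6, 3))
    off <- 0
    for (tr in l) { arr[off + 1:40, , ] <- tr$frames; off <- off + 40 }
    arr
  }, list(reps))
  want <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    di <- sweep(allfr[, i, ], 2, colMeans(allfr[, i, ]))
    dj <- sweep(allfr[, j, ], 2, colMeans(allfr[, j, ]))
    want[i, j] <- mean(rowSums(di * dj))
  }
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("eigen-decomposition reproduces a characteristic-polynomial oracle", {
  A <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 1), 3, 3)
  expect_equal(sort(eigen(A, symmetric = TRUE)$values), c(1, 1, 3),
               tolerance = 1e-10)
  # the same eigenvalues drive spectral_sectors retention on this matrix
  cmat <- structure(A, dimnames = list(letters[1:3], letters[1:3]),
                    mode = "raw", n_frames = 100L,
                    variances = stats::setNames(diag(A), letters[1:3]),
                    class = c("coupling_matrix", "matrix", "array"))
  dec <- spectral_sectors(cmat, n_components = 1, seed = 1)
  expect_equal(dec$eigenvalues, c(3, 1, 1), tolerance = 1e-10)
})

test_that("white-noise trajectories yield zero sectors under the shuffle null", {
  tr <- gen_trajectory(diag(30), 500, seed = 2)
  dec <- spectral_sectors(dccm(tr, fit = FALSE), seed = 2)
  expect_equal(dec$n_retained, 0)
  expect_length(dec$sectors, 0)
})

test_that("planted coupled blocks are recovered as sectors", {
  blocks <- list(list(members = 1:10, rho = 0.8),
                 list(members = 11:20, rho = 0.8))
  cov <- planted_sector_covariance(50, blocks)
  tr <- gen_trajectory(cov, 2000, seed = 3)
  cm <- dccm(tr, fit = FALSE)
  dec <- spectral_sectors(cm, seed = 3)
  labs <- rownames(unclass(cm))
  expect_gte(length(dec$sectors), 2)
  j1 <- max(vapply(dec$sectors, jaccard, numeric(1), b = labs[1:10]))
  j2 <- max(vapply(dec$sectors, jaccard, numeric(1), b = labs[11:20]))
  expect_gte(j1, 0.9)
  expect_gte(j2, 0.9)
})

test_that("permutation null from the source trajectory gives the same verdicts", {
  blocks <- list(list(members = 1:6, rho = 0.8))
  cov <- planted_sector_covariance(20, blocks)
  tr <- gen_trajectory(cov, 800, seed = 5)
  cm <- dccm(tr, fit = FALSE)
  dec <- spectral_sectors(cm, seed = 5, traj = tr, fit = FALSE, n_null = 50)
  labs <- rownames(unclass(cm))
  expect_equal(dec$n_retained, 1)
  expect_gte(jaccard(dec$sectors$sector_1, labs[1:6]), 0.9)
})

test_that("sector membership is stable across reseeded ICA restarts", {
  blocks <- list(list(members = 1:10, rho = 0.8),
                 list(members = 11:20, rho = 0.8))
  cov <- planted_sector_covariance(50, blocks)
  tr <- gen_trajectory(cov, 2000, seed = 3)
  cm <- dccm(tr, fit = FALSE)
  sets <- lapply(1:5, function(s)
    lapply(spectral_sectors(cm, seed = s)$sectors, sort))
  for (k in 2:5) expect_identical(sets[[k]], sets[[1]])
})

test_that("a fixed component count mirrors the fixed-IC workflow", {
  blocks <- list(list(members = 1:10, rho = 0.8),
                 list(members = 11:20, rho = 0.8))
  cov <- planted_sector_covariance(50, blocks)
  tr <- gen_trajectory(cov, 2000, seed = 3)
  dec <- spectral_sectors(dccm(tr, fit = FALSE), n_components = 5, seed = 3)
  expect_equal(dec$n_retained, 5)
  expect_equal(ncol(dec$components), 5)
})

test_that("single-frame trajectories are rejected", {
  m <- build_chain_structure("GSTFS")
  tr <- static_trajectory(m, 1)
  expect_error(dccm(tr), "2 frames")
})

test_that("coupling matrices round-trip through labelled TSV", {
  tr <- gen_trajectory(diag(4), 50, seed = 9)
  cm <- dccm(tr, fit = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coupling_tsv(cm, path)
  back <- read_coupling_tsv(path, n_frames = 50)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(rownames(back), rownames(unclass(cm)))
})
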