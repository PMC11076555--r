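# RMSF, contact propensity, secondary-structure propensity, residue deviation.

test_that("RMSF of a static trajectory is zero; two-frame case is closed form", {
  m <- build_chain_structure("GSTFS")
  expect_equal(rmsf(static_trajectory(m, 4), fit = FALSE)$value, rep(0, 5))

  fr <- static_frames(m, 2)
  d <- 0.7
  fr[1, , 1] <- fr[1, , 1] + d
  fr[2, , 1] <- fr[2, , 1] - d
  r <- rmsf(trajectory(m, fr), fit = FALSE)
  expect_equal(r$value, rep(d, 5), tolerance = 1e-12)
})

test_that("RMSF of isotropic Gaussian displacements matches sigma*sqrt(3)", {
  sigma <- 0.5
  tr <- gen_trajectory(diag(sigma^2, 20), 5000, seed = 11)
  r <- rmsf(tr, fit = FALSE)
  expect_true(all(abs(r$value / (sigma * sqrt(3)) - 1) < 0.05))
})

test_that("fitted RMSF is invariant to per-frame rigid-body noise", {
  base <- build_chain_structure("GSTFSLWQDIP")
  tr <- gen_trajectory(diag(0.01, 11), 40, seed = 21)
  jittered <- tr
  set.seed(22)
  for (f in seq_len(dim(tr$frames)[1])) {
    R <- random_rotation()
    shift <- rnorm(3, sd = 5)
    jittered$frames[f, , ] <- tr$frames[f, , ] %*% t(R) +
      matrix(shift, 11, 3, byrow = TRUE)
  }
  expect_equal(rmsf(jittered, fit = TRUE)$value, rmsf(tr, fit = TRUE)$value,
               tolerance = 1e-6)
})

test_that("scripted contact schedules are reproduced exactly", {
  sch <- data.frame(pep_res = c(7, 9, 2), dom_res = c(1, 2, 3),
                    fraction = c(0.3, 1.0, 0))
  tr <- gen_complex_trajectory("GSTFSLWQDIP", 5, sch, n_frames = 10, seed = 4)
  pm <- interaction_propensity(tr, selection(chain = "B"),
                               selection(chain = "A"))
  expect_equal(unname(pm[7, 1]), 0.3)
  expect_equal(unname(pm[9, 2]), 1.0)
  expect_equal(unname(pm[2, 3]), 0)
  expect_equal(sum(pm), 1.3)  # nothing else in contact

  # brute-force per-frame distance oracle on the scheduled pair
  at <- tr$topology$atoms
  pep_idx <- which(at$chain == "B" & at$resid == 7 & at$name == "CB")
  dom_idx <- which(at$chain == "A" & at$resid == 1)
  expect_equal(oracle_contact_fraction(tr, pep_idx, dom_idx, 4.0), 0.3)
})

test_that("propensity is invariant to frame order and rigid whole-frame motion", {
  sch <- data.frame(pep_res = 7, dom_res = 2, fraction = 0.4)
  tr <- gen_complex_trajectory("GSTFSLWQDIP", 3, sch, n_frames = 10, seed = 9)
  pm <- interaction_propensity(tr, selection(chain = "B"),
                               selection(chain = "A"))
  perm <- tr
  set.seed(30)
  perm$frames <- perm$frames[sample(10), , ]
  expect_equal(interaction_propensity(perm, selection(chain = "B"),
                                      selection(chain = "A")), pm)
  rigid <- tr
  for (f in 1:10)
    rigid$frames[f, , ] <- tr$frames[f, , ] %*% t(rotation_z(33)) +
      matrix(c(5, -2, 9), dim(tr$frames)[2], 3, byrow = TRUE)
  expect_equal(interaction_propensity(rigid, selection(chain = "B"),
                                      selection(chain = "A")), pm,
               tolerance = 1e-12)
})

test_that("propensity is monotone non-increasing in the cutoff", {
  sch <- data.frame(pep_res = c(7, 9), dom_res = c(1, 2),
                    fraction = c(0.5, 0.8))
  tr <- gen_complex_trajectory("GSTFSLWQDIP", 4, sch, n_frames = 10, seed = 2)
  cuts <- c(2, 4, 6, 12)
  mats <- lapply(cuts, function(ct)
    interaction_propensity(tr, selection(chain = "B"),
                           selection(chain = "A"), cutoff = ct))
  for (k in seq_along(cuts)[-1])
    expect_true(all(mats[[k]] >= mats[[k - 1]]))
})

test_that("boundary-equal distances are non-contacts (strict inequality)", {
  # place the proxy exactly at the cutoff
  sch <- data.frame(pep_res = 1, dom_res = 1, fraction = 1)
  tr <- gen_complex_trajectory("SS", 2, sch, cutoff = 5, n_frames = 4,
                               seed = 1)
  # contact frames sit at 0.8 * 5 = 4; measuring at cutoff 4 makes them
  # boundary-equal, hence non-contacts
  pm <- interaction_propensity(tr, selection(chain = "B"),
                               selection(chain = "A"), cutoff = 4)
  expect_equal(unname(pm[1, 1]), 0)
})

test_that("ideal strand and helix conformations classify correctly", {
  n <- 7
  strand <- build_backbone_from_dihedrals(strrep("A", n),
                                          rep(-120, n), rep(130, n))
  helix <- build_backbone_from_dihedrals(strrep("A", n),
                                         rep(-57, n), rep(-47, n))
  ss_s <- ss_propensity(static_trajectory(strand, 3))
  ss_h <- ss_propensity(static_trajectory(helix, 3))
  expect_true(all(is.na(ss_s$value[c(1, n)])))   # terminals missing, not 0
  expect_equal(ss_s$value[2:(n - 1)], rep(1, n - 2))
  expect_equal(ss_h$value[2:(n - 1)], rep(0, n - 2))
})

test_that("mixed-conformer trajectories count strand frames exactly", {
  n <- 6
  strand <- build_backbone_from_dihedrals(strrep("A", n),
                                          rep(-120, n), rep(130, n))
  helix <- build_backbone_from_dihedrals(strrep("A", n),
                                         rep(-57, n), rep(-47, n))
  fr <- array(NA_real_, c(10, nrow(strand$atoms), 3))
  sa <- static_frames(strand, 1)[1, , ]
  ha <- static_frames(helix, 1)[1, , ]
  for (f in 1:4) fr[f, , ] <- sa
  for (f in 5:10) fr[f, , ] <- ha
  mix <- trajectory(strand, fr)
  expect_equal(ss_propensity(mix)$value[2:(n - 1)], rep(0.4, n - 2))
})

test_that("SS propensity over trajectory halves averages to the full value", {
  n <- 6
  strand <- build_backbone_from_dihedrals(strrep("A", n),
                                          rep(-120, n), rep(130, n))
  helix <- build_backbone_from_dihedrals(strrep("A", n),
                                         rep(-57, n), rep(-47, n))
  fr <- array(NA_real_, c(10, nrow(strand$atoms), 3))
  sa <- static_frames(strand, 1)[1, , ]
  ha <- static_frames(helix, 1)[1, , ]
  set.seed(40)
  which_s <- sample(10, 7)
  for (f in 1:10) fr[f, , ] <- if (f %in% which_s) sa else ha
  full <- ss_propensity(trajectory(strand, fr))$value
  h1 <- ss_propensity(trajectory(strand, fr[1:5, , , drop = FALSE]))$value
  h2 <- ss_propensity(trajectory(strand, fr[6:10, , , drop = FALSE]))$value
  expect_equal((h1 + h2) / 2, full)
})

test_that("residue deviation removes rigid motion and isolates perturbations", {
  a <- build_chain_structure("GSTFSLWQDIP")
  expect_equal(residue_deviation(a, a)$value, rep(0, 11))

  rot <- a
  co <- as.matrix(a$atoms[, c("x", "y", "z")]) %*% t(rotation_z(50))
  rot$atoms[, c("x", "y", "z")] <- sweep(co, 2, c(1, 1, 1), "+")
  expect_lt(max(residue_deviation(a, rot)$value), 1e-8)

  pert <- a
  pert$atoms[5, c("x", "y", "z")] <-
    pert$atoms[5, c("x", "y", "z")] + c(0, 0, 2)
  dev <- residue_deviation(a, pert, exclude_from_fit = 5)
  expect_equal(dev$value[5], 2, tolerance = 1e-8)
  expect_lt(max(dev$value[-5]), 1e-8)
})

test_that("empty selections and missing atoms raise errors", {
  m <- build_chain_structure("GSTFS")
  tr <- static_trajectory(m, 3)
  expect_error(rmsf(tr, selection(chain = "Z")), "empty")
  expect_error(ss_propensity(tr), "backbone")
  expect_error(residue_deviation(m, m, pairing = data.frame(resid_a = 99,
                                                            resid_b = 99)),
               "empty")
})
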