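test_that("rotamer classification maps the canonical wells and bin edges", {
  expect_identical(classify_rotamer(c(300, 180, 300, 180)), "mtm180")
  expect_identical(classify_rotamer(c(60, 180, 180, 180)), "ptt180")
  expect_identical(classify_rotamer(c(180, 180, 60, 180)), "ttp180")
  expect_identical(classify_rotamer(c(300, 180, 180, 180)), "mtt180")
  # half-open [low, high) bins: 120 belongs to t, 240 to m, 239.9 to "180"
  expect_identical(classify_rotamer(c(119.9, 120.0, 240.0, 239.9)),
                   "ptm180")
  expect_identical(classify_rotamer(c(0, 0, 0, 0)), "ppp85")
  expect_identical(classify_rotamer(c(359.999, 240, 300, 240)), "mmm-85")
})

test_that("rotamer classification is invariant to full turns and vectorises", {
  set.seed(21)
  chi <- matrix(runif(200, 0, 360), ncol = 4)
  base <- classify_rotamer(chi)
  shifted <- chi + 360 * matrix(sample(-3:3, 200, replace = TRUE), ncol = 4)
  expect_identical(classify_rotamer(shifted), base)
  expect_length(base, 50)
})

test_that("rotamer statistics summarise occupancy, transitions and dwells", {
  # pure dwell in the native well
  chi <- matrix(rep(c(300, 180, 300, 180), each = 100), ncol = 4)
  rs <- rotamer_statistics(chi)
  expect_identical(unname(rs$occupancy["mtm180"]), 1)
  expect_identical(rs$transitions, 0L)

  # strictly alternating two-state trace: n - 1 transitions
  alt <- matrix(rep(c(300, 180, 300, 180, 60, 180, 180, 180), 25),
                ncol = 4, byrow = TRUE)
  rs2 <- rotamer_statistics(alt)
  expect_identical(rs2$transitions, nrow(alt) - 1L)
  expect_equal(sum(rs2$occupancy), 1, tolerance = 1e-9)
  expect_identical(sum(rs2$dwell$length), nrow(alt))
})

test_that("occupancies on a Markov trace match the chain's stationary law", {
  # 3-state chain with stationary distribution (0.7, 0.2, 0.1)
  P <- matrix(c(0.96, 0.03, 0.01,
                0.10, 0.87, 0.03,
                0.09, 0.05, 0.86), 3, 3, byrow = TRUE)
  pi_s <- oracle_stationary(P)
  sc <- trajectory_scenario(transition_matrix = P, n_frames = 1e5,
                            kappa = 50, seed = 5)
  tr <- generate_dihedral_trajectory(sc)
  rs <- rotamer_statistics(tr$chi)
  for (k in seq_len(3)) {
    st <- rownames(sc$P)[k]
    expect_lt(abs(rs$occupancy[st] - pi_s[k]), 0.02)
  }
})

test_that("salt-bridge occupancy counts sub-cutoff frames", {
  expect_identical(salt_bridge_occupancy(rep(3.5, 50))$occupancy, 1)
  broken <- salt_bridge_occupancy(rep(6.0, 50))
  expect_identical(broken$occupancy, 0)
  expect_identical(broken$mean_d, 6.0)
  expect_identical(salt_bridge_occupancy(c(rep(3, 25), rep(5, 25)))$occupancy,
                   0.5)
  expect_error(salt_bridge_occupancy(numeric(0)), "empty")
  expect_error(salt_bridge_occupancy(c(3, -1)), "positive")
})

test_that("Kabsch superposition is exact on rigidly moved copies", {
  set.seed(31)
  a <- matrix(rnorm(30), 10, 3)
  same <- kabsch_superpose(a, a)
  expect_equal(same$rmsd, 0, tolerance = 1e-12)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  R <- random_rotation()
  moved <- a %*% R + matrix(c(3, -1, 7), 10, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(a, moved)$rmsd, 0, tolerance = 1e-10)
})

test_that("Kabsch RMSD is symmetric and invariant under joint pre-rotation", {
  set.seed(32)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, 0, 0.3), 8, 3)
  r_ab <- kabsch_superpose(a, b)$rmsd
  expect_equal(kabsch_superpose(b, a)$rmsd, r_ab, tolerance = 1e-10)
  R <- random_rotation()
  expect_equal(kabsch_superpose(a %*% R, b %*% R)$rmsd, r_ab,
               tolerance = 1e-10)
})

test_that("Kabsch RMSD matches brute-force rotation search on 4-atom toys", {
  set.seed(33)
  for (rep in 1:3) {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(12), 4, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_grid_rmsd(a, b),
                 tolerance = 1e-3)
  }
})

test_that("Kabsch superposition agrees with an established structural toolkit", {
  set.seed(34)
  a <- matrix(rnorm(45), 15, 3)
  b <- a %*% random_rotation() + matrix(rnorm(45, 0, 0.5), 15, 3)
  ours <- kabsch_superpose(a, b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) -
                                   b)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate geometry is rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))   # collinear atoms
  expect_error(kabsch_superpose(line, line + 1), "degenerate|collinear")
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "atoms")
})

test_that("RMSD series flags stable ensembles and isolates perturbed frames", {
  set.seed(35)
  base <- matrix(rnorm(60), 20, 3)
  # rigidly moving ensemble: all zero
  frames <- lapply(1:6, function(i)
    base %*% random_rotation() + matrix(rnorm(3), 20, 3, byrow = TRUE))
  rs <- rmsd_series(frames)
  expect_equal(as.numeric(rs), rep(0, 6), tolerance = 1e-10)
  expect_true(attr(rs, "stable"))

  # one perturbed frame: only that frame is nonzero
  frames[[4]] <- frames[[4]] + matrix(rnorm(60, 0, 2), 20, 3)
  rs2 <- rmsd_series(frames)
  expect_equal(as.numeric(rs2)[-4], rep(0, 5), tolerance = 1e-10)
  expect_gt(rs2[4], 1.5)
  expect_false(attr(rs2, "stable"))
})

test_that("RMSF is zero for rigid motion and recovers a single atom's amplitude", {
  set.seed(36)
  base <- matrix(rnorm(600), 200, 3)
  rigid <- lapply(1:8, function(i) base %*% random_rotation())
  expect_equal(rmsf_per_atom(rigid), rep(0, 200), tolerance = 1e-10)

  # one atom oscillating +/- a along x in an otherwise static body; the
  # tiny residual from re-centering scales as a / n_atoms
  a_amp <- 0.5
  osc <- lapply(1:10, function(i) {
    f <- base
    f[7, 1] <- f[7, 1] + a_amp * (-1)^i
    f
  })
  rmsf <- rmsf_per_atom(osc)
  expect_equal(rmsf[7], a_amp, tolerance = 0.02)
  expect_lt(max(rmsf[-7]), a_amp / 50)
})
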