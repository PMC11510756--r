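# Force field, forces, and Langevin integrator.

test_that("pair potentials reproduce hand-computed values", {
  # truncated-shifted LJ: zero at the cutoff by construction
  expect_equal(lj_energy(2.5, eps_lj = 0.6), 0)
  expect_equal(lj_energy(3.1, eps_lj = 0.6), 0)
  # plug-in arithmetic at r = sigma: 4*0.6*((1/2.5)^6 - (1/2.5)^12)
  expect_equal(lj_energy(1, eps_lj = 0.6), 0.0097901346816, tolerance = 1e-10)
  # minimum at 2^(1/6) sigma: derivative vanishes, value -eps + tail shift
  rmin <- 2^(1 / 6)
  h <- 1e-6
  dU <- (lj_energy(rmin + h, 0.6) - lj_energy(rmin - h, 0.6)) / (2 * h)
  expect_lt(abs(dU), 1e-6)
  expect_equal(lj_energy(rmin, 0.6), -0.590209865318, tolerance = 1e-9)
  expect_error(lj_energy(0, 0.6), "positive")

  # Bjerrum-length definition: unit charges at r = lB interact with 1 kT
  expect_equal(coulomb_energy(3, 1, 1, bjerrum = 3), 1)
  expect_equal(coulomb_energy(3, 1, -1, bjerrum = 3), -1)
  expect_equal(coulomb_energy(5, 0, 1, bjerrum = 3), 0)
  expect_error(coulomb_energy(0, 1, 1), "positive")

  expect_equal(fene_energy(0), 0)
  expect_equal(fene_energy(0.75), 9.70926994525, tolerance = 1e-9)
  expect_error(fene_energy(1.5), "rmax")
  expect_error(fene_energy(1.7), "rmax")

  # WCA is purely repulsive: zero at and beyond 2^(1/6) sigma
  expect_equal(wca_energy(2^(1 / 6)), 0)
  expect_gt(wca_energy(1), 0)
})

test_that("forces vanish at the LJ minimum and obey Newton's third law", {
  p <- forcefield_params()
  sys <- make_system(rbind(c(5, 5, 5), c(5 + 2^(1 / 6), 5, 5)),
                     charge = c(0, 0), species = c("A", "A"))
  f <- total_forces(sys, p)
  expect_lt(max(abs(f)), 1e-12)

  set.seed(21)
  sys <- random_test_system()
  f <- total_forces(sys, p)
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("overlapping particles are rejected with an explicit error", {
  sys <- make_system(rbind(c(5, 5, 5), c(5, 5, 5)), charge = c(0, 0),
                     species = c("A", "A"))
  expect_error(total_energy(sys), "overlap")
})

test_that("C++ total energy equals the R-level pairwise sum", {
  set.seed(31)
  p <- forcefield_params()
  sys <- random_test_system()
  u_ref <- 0
  n <- nrow(sys$pos)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sys$pos[i, ] - sys$pos[j, ]
    d <- d - p$box_L * round(d / p$box_L)
    r <- sqrt(sum(d^2))
    ion <- sys$species[i] == "ion" || sys$species[j] == "ion"
    u_ref <- u_ref + if (ion) wca_energy(r, eps = p$eps_wca)
                     else lj_energy(r, p$eps_lj, rc = p$rc_mm)
    qq <- sys$charge[i] * sys$charge[j]
    if (qq != 0 && r < p$rc_coul)
      u_ref <- u_ref + qq * p$bjerrum * (1 / r - 1 / p$rc_coul)
  }
  for (e in seq_len(nrow(sys$bonds))) {
    d <- sys$pos[sys$bonds[e, 1], ] - sys$pos[sys$bonds[e, 2], ]
    u_ref <- u_ref + fene_energy(sqrt(sum(d^2)), p$fene_k, p$fene_rmax)
  }
  expect_equal(total_energy(sys, p), u_ref, tolerance = 1e-10)
})

test_that("analytic forces match central differences of the energy", {
  set.seed(11)
  p <- forcefield_params()
  sys <- random_test_system()
  f <- total_forces(sys, p)
  h <- 1e-5
  fd <- matrix(0, nrow(sys$pos), 3)
  for (i in seq_len(nrow(sys$pos))) {
    for (k in 1:3) {
      sp <- sys; sp$pos[i, k] <- sp$pos[i, k] + h
      sm <- sys; sm$pos[i, k] <- sm$pos[i, k] - h
      fd[i, k] <- -(total_energy(sp, p) - total_energy(sm, p)) / (2 * h)
    }
  }
  rel <- abs(fd - f) / pmax(abs(f), 1)
  expect_lt(max(rel), 1e-6)
})

test_that("zero-friction noiseless limit is ballistic free flight", {
  sys <- make_system(matrix(c(5, 5, 5), 1), charge = 0, species = "ion")
  sys$vel <- matrix(c(0.3, -0.2, 0.1), 1)
  p <- forcefield_params(zeta = 0)
  out <- advance_system(sys, p, t = 1, dt = 0.005, noise = FALSE)
  expect_equal(out$system$pos[1, ], c(5, 5, 5) + c(0.3, -0.2, 0.1),
               tolerance = 1e-12)
})

test_that("bond blow-up is reported as a simulation failure", {
  sys <- make_system(rbind(c(5, 5, 5), c(6.52, 5, 5)), charge = c(0, 0),
                     species = c("A", "A"), bonds = cbind(1L, 2L))
  expect_error(total_energy(sys), "overstretched")
})

test_that("electroneutrality and particle bookkeeping hold for the Q=8 system", {
  set.seed(4)
  seqs <- select_q_ensemble(2000, 8, max_keep = 1)
  sys <- padimer:::build_system(seqs[[1]], n_chains = 2)
  expect_equal(nrow(sys$pos), 216) # 200 monomers + 16 counterions
  expect_equal(sum(sys$charge), 0)
  expect_equal(sum(sys$charge != 0), 68 + 16)
  expect_equal(nrow(sys$bonds), 2 * 99)
  # electroneutrality is static metadata: preserved over any trajectory
  tr <- run_two_chain(seqs[[1]], t_total = 2, stride_t = 1, seed = 1,
                      burn_in = 1)
  expect_equal(sum(tr$charge), 0)
})

test_that("t_total = 0 returns only the initial frame", {
  set.seed(8)
  seqs <- select_q_ensemble(2000, 8, max_keep = 1)
  tr <- run_two_chain(seqs[[1]], t_total = 0, seed = 2)
  expect_equal(dim(tr$pos)[3], 1)
  expect_equal(tr$times, 0)
})

test_that("poor solvent collapses a neutral chain relative to theta", {
  neutral <- padimer:::new_pa_sequence(rep(0L, 60), 60)
  rg2 <- function(eps, seed) {
    p <- forcefield_params(eps_lj = eps)
    tr <- padimer:::run_chains(neutral, 1L, p, t_total = 120, dt = 0.005,
                               stride_t = 2, seed = seed, burn_in = 60,
                               separation = 0, n_counterions = 0)
    mean(rowSums(gyration_eigenvalues(tr, "A")$eigenvalues))
  }
  expect_lt(rg2(0.60, seed = 14), rg2(0.32, seed = 14))
})
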