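# Free-energy profile extraction and radial Fokker-Planck MFPT.

test_that("the entropy term cancels exactly for uniform-in-shell samples", {
  set.seed(1)
  # density proportional to r^2 on [3, 13]: inverse-CDF sampling
  u <- runif(5e4)
  r <- (3^3 + u * (13^3 - 3^3))^(1 / 3)
  h <- hist(r, breaks = seq(3, 13, by = 0.25), plot = FALSE)
  V <- -log(h$counts / sum(h$counts)) + 2 * log(h$mids)
  expect_lt(diff(range(V)), 0.15) # flat potential
  # flat potentials expose no barrier: explicit error, not a bogus geometry
  expect_error(potential_from_trajectory(r), "no barrier")
})

test_that("a known double well is recovered from sampled distances", {
  coef <- double_well_poly(r_dimer = 5, r_unimer = 12, barrier = 4)
  r <- gen_radial_double_well_walk(coef, D = 1, t_total = 4e5, dt = 0.01,
                                   r0 = 5, lo = 2.5, hi = 15.5, stride = 5,
                                   seed = 31)
  prof <- potential_from_trajectory(r, bin_width = 0.25)
  expect_lt(abs(prof$r2 - 5), 0.5)
  expect_lt(abs(prof$r1 - 12), 0.5)
  expect_lt(abs(prof$r_star - 8.5), 0.7)
  # recovered potential matches the input within 0.2 kT across the basins
  rg <- seq(4, 13, by = 0.5)
  v_in <- padimer:::polyval_r(coef, rg) - padimer:::polyval_r(coef, 5)
  v_fit <- padimer:::polyval_r(prof$coef, rg) -
           padimer:::polyval_r(prof$coef, prof$r2)
  expect_lt(max(abs(v_in - v_fit)), 0.25)
  expect_true(prof$degree %in% 6:8)
})

test_that("round trip: resampling the fitted profile reproduces it", {
  coef <- double_well_poly(barrier = 3)
  prof1 <- profile_from_polynomial(coef, c(3, 14))
  r <- gen_radial_double_well_walk(prof1$coef, D = 1, t_total = 3e5,
                                   dt = 0.01, r0 = 5, lo = 3, hi = 14,
                                   stride = 5, seed = 7)
  prof2 <- potential_from_trajectory(r, bin_width = 0.25)
  expect_lt(abs(prof2$r2 - prof1$r2), 0.5)
  expect_lt(abs(prof2$V_star_dissociation - prof1$V_star_dissociation), 0.5)
})

test_that("MFPT in a flat potential matches brute-force radial diffusion", {
  coef <- c(0) # V = 0: free radial diffusion with the entropic drift
  prof <- list(coef = coef, r1 = 10, r2 = 4, r_star = 7, range = c(2, 12))
  class(prof) <- "pa_profile"
  mf <- mfpt_radial(prof, D = 1, "dissociation", inner = 2, n_grid = 6000)
  wk <- fp_walker_times(coef, D = 1, r0 = 4, r_abs = 10, lo = 2, hi = 12,
                        dt = 5e-4, n_walkers = 4000, seed = 3)
  expect_lt(abs(mf$time - wk$mean), 3 * wk$se + 0.5)
  # exact scaling: doubling D halves the time
  mf2 <- mfpt_radial(prof, D = 2, "dissociation", inner = 2, n_grid = 6000)
  expect_equal(mf2$time, mf$time / 2, tolerance = 1e-12)
})

test_that("deep-barrier MFPT approaches the Kramers closed form", {
  coef <- double_well_poly(barrier = 10)
  prof <- profile_from_polynomial(coef, c(2.5, 15))
  mf <- mfpt_radial(prof, D = 1, "dissociation", inner = 2.5)
  # Laplace (saddle-point) oracle evaluated from the polynomial curvatures
  d2 <- function(r) {
    dc <- padimer:::polyder_coef(padimer:::polyder_coef(coef))
    padimer:::polyval_r(dc, r)
  }
  vstar <- prof$V_star_dissociation
  kram <- 2 * pi / (1 * sqrt(d2(prof$r2) * abs(d2(prof$r_star)))) *
          (prof$r2 / prof$r_star)^2 * exp(vstar)
  expect_lt(abs(mf$time - kram) / kram, 0.20)
  # dissociation time grows monotonically with barrier height
  times <- vapply(c(4, 6, 8), function(b) {
    p <- profile_from_polynomial(double_well_poly(barrier = b), c(2.5, 15))
    mfpt_radial(p, 1, "dissociation", inner = 2.5)$time
  }, numeric(1))
  expect_true(all(diff(times) > 0))
})

test_that("the barrier-flux estimate tracks the MFPT within its claimed accuracy", {
  coef <- double_well_poly(barrier = 8)
  prof <- profile_from_polynomial(coef, c(2.5, 15))
  mf <- mfpt_radial(prof, D = 1, "dissociation", inner = 2.5)
  fl <- kramers_flux_estimate(prof, D = 1, "dissociation")
  expect_lt(max(fl$time / mf$time, mf$time / fl$time), 3)
  # linear in the sink volume
  prof2 <- prof
  prof2$sink_volume_dimer <- 2 * prof$sink_volume_dimer
  fl2 <- kramers_flux_estimate(prof2, D = 1, "dissociation")
  expect_equal(fl2$time, 2 * fl$time, tolerance = 1e-12)
  # shallow barriers are flagged invalid
  shallow <- profile_from_polynomial(double_well_poly(barrier = 0.5),
                                     c(2.5, 15))
  expect_warning(kramers_flux_estimate(shallow, 1, "dissociation"), "1 kT")
})

test_that("diffusion coefficient: free-draining formula and measured MSD agree", {
  expect_equal(diffusion_coefficient(n_monomers = 100), 0.02)
  expect_equal(diffusion_coefficient(n_monomers = 1), 2)
  # Brownian center fixture with known D0 = 0.05: each walker's estimate is
  # unbiased but MSD-slope noisy, so average over an ensemble of walkers
  set.seed(9)
  nf <- 4000
  D0 <- 0.05
  est <- replicate(400, {
    steps <- matrix(rnorm(3 * nf, sd = sqrt(2 * D0 * 1)), ncol = 3)
    com <- apply(steps, 2, cumsum)
    as.numeric(diffusion_coefficient(com = com, times = seq_len(nf) - 1,
                                     mode = "measured",
                                     fit_frac = c(0.01, 0.1)))
  })
  expect_lt(abs(mean(est) - 2 * D0) / (2 * D0), 0.05)
})

test_that("dimerization MFPT uses the mirrored quadrature and outer wall", {
  coef <- double_well_poly(barrier = 3)
  prof <- profile_from_polynomial(coef, c(3, 14))
  dim_t <- mfpt_radial(prof, D = 1, "dimerization")
  dis_t <- mfpt_radial(prof, D = 1, "dissociation")
  expect_gt(dim_t$time, 0)
  expect_gt(dis_t$time, 0)
  expect_lt(dim_t$quadrature_error / dim_t$time, 1e-3)
  # basin-edge target absorbs sooner than the far minimum
  dim_edge <- mfpt_radial(prof, D = 1, "dimerization", target = "basin_edge")
  expect_lt(dim_edge$time, dim_t$time)
})
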