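# Dimer/unimer classification, dwell distributions, survival curves, and
# descriptor correlations.

test_that("distance criterion labels scripted frames exactly", {
  script <- data.frame(time = 0:29,
                       distance = rep(c(12, 5, 12), each = 10))
  tr <- gen_toy_two_chain_frames(script)
  st <- classify_states(tr, "distance10")
  expect_equal(unique(st$labels[1:10]), "unimer")
  expect_equal(unique(st$labels[11:20]), "dimer")
  expect_equal(unique(st$labels[21:30]), "unimer")
  expect_equal(st$episodes$n_frames, c(10, 10, 10))
  expect_equal(st$episodes$state, c("unimer", "dimer", "unimer"))
  # first and last episodes are censored by the trajectory ends
  expect_equal(st$episodes$censored, c(TRUE, FALSE, TRUE))
})

test_that("both criteria agree on scripted contact-rich frames", {
  # > 4 contact pairs while centers sit at 9 sigma: dimer under both rules
  script <- data.frame(time = 0:4, distance = 9, n_contacts = 6)
  tr <- gen_toy_two_chain_frames(script, n_chain = 10)
  expect_true(all(classify_states(tr, "distance10")$labels == "dimer"))
  expect_true(all(classify_states(tr, "contacts4")$labels == "dimer"))
  # exactly 4 contacts is not "more than four"
  script$n_contacts <- 4
  tr <- gen_toy_two_chain_frames(script, n_chain = 10)
  expect_true(all(classify_states(tr, "contacts4")$labels == "unimer"))
})

test_that("single-chain trajectories are rejected", {
  tr <- make_traj(list(matrix(rnorm(30), 10, 3)), charge = rep(0, 10),
                  species = rep("A", 10))
  expect_error(classify_states(tr), "two-chain")
})

test_that("debouncing merges episodes shorter than min_frames", {
  d <- rep(c(12, 5), each = 20)
  d[25] <- 12 # single-frame blip inside the dimer episode
  tr <- gen_toy_two_chain_frames(data.frame(time = seq_along(d) - 1,
                                            distance = d))
  st_raw <- classify_states(tr)
  expect_equal(nrow(st_raw$episodes), 4)
  st <- classify_states(tr, min_frames = 3)
  expect_equal(nrow(st$episodes), 2)
})

test_that("dwell bookkeeping separates completed and censored episodes", {
  # constructed series: 5 complete dimer episodes of 100 tau each
  labels <- rep(rep(c("unimer", "dimer"), 6)[1:11], each = 10)
  times <- seq(0, by = 10, length.out = length(labels))
  st <- padimer:::new_pa_states(times, labels, "constructed")
  dw <- dwell_distribution(st, "dimer")
  expect_equal(dw$n, 5)
  expect_equal(unique(dw$durations), 100)
  expect_equal(dw$mean_all, 100)
  expect_equal(dw$censored_n, 0)
  # truncate so the last dimer episode is cut by the trajectory end
  st2 <- padimer:::new_pa_states(times[1:95], labels[1:95], "constructed")
  dw2 <- dwell_distribution(st2, "dimer")
  expect_equal(dw2$n, 4)
  expect_equal(dw2$censored_n, 1)
  # no completed episodes: explicit empty result, not NaN
  st3 <- padimer:::new_pa_states(0:9, rep("dimer", 10), "constructed")
  dw3 <- dwell_distribution(st3, "dimer")
  expect_true(dw3$empty)
  expect_equal(dw3$n, 0)
  expect_true(is.na(dw3$mean_all))
})

test_that("semi-Markov dwell means are recovered within sampling error", {
  st <- gen_semi_markov_states(mean_dimer = 1000, mean_unimer = 400,
                               t_total = 6e5, dt = 2, seed = 42)
  dw <- dwell_distribution(st, "dimer")
  expect_gt(dw$n, 200)
  se <- sd(dw$durations) / sqrt(dw$n)
  expect_lt(abs(dw$mean_all - 1000), 3 * se + 2)
  dwu <- dwell_distribution(st, "unimer")
  seu <- sd(dwu$durations) / sqrt(dwu$n)
  expect_lt(abs(dwu$mean_all - 400), 3 * seu + 2)
  # truncation monotonicity: the matured mean can only exceed the plain mean
  expect_gte(dw$mean_tail, dw$mean_all)
})

test_that("survival curve matches its defining formula and fits the tail", {
  # point mass at 2 tc: a step function
  sv <- survival_curve(rep(500, 50), tc = 250)
  expect_equal(sv$S[sv$t < 500], rep(1, sum(sv$t < 500)))
  expect_equal(sv$S[sv$t >= 500], rep(0, sum(sv$t >= 500)))

  # pure exponential dwells: tau_r recovered within 10% at 500 episodes
  set.seed(1)
  d <- rexp(500, rate = 1 / 4.7e4)
  sv <- survival_curve(d[d > 250], tc = 250)
  expect_lt(abs(sv$tau_r - 4.7e4) / 4.7e4, 0.10)

  # mixture: S depends only on the tail component beyond tc
  set.seed(2)
  tail_part <- 250 + rexp(300, 1 / 2000)
  short_part <- runif(700, 0, 250)
  sv_mix <- survival_curve(c(tail_part, short_part), tc = 250)
  sv_tail <- survival_curve(tail_part, tc = 250)
  expect_equal(sv_mix$tau_r, sv_tail$tau_r, tolerance = 1e-8)

  expect_error(survival_curve(runif(50, 0, 200), tc = 250), "beyond tc")
})

test_that("survival estimator recovers the generator's relaxation time", {
  st <- gen_semi_markov_states(mean_dimer = 4.7e4, mean_unimer = 1.8e4,
                               t_total = 1.5e7, dt = 50, seed = 9)
  dw <- dwell_distribution(st, "dimer")
  sv <- survival_curve(dw, tc = 250)
  se <- sv$tau_r / sqrt(sv$n)
  expect_lt(abs(sv$tau_r - 4.7e4), 3 * se)
})

test_that("dwell-CNC correlation handles linear, shuffled and degenerate data", {
  desc <- data.frame(id = 1:8, cnc = c(1, 2, 3, 4, 5, 6, 7, 8),
                     subgroup = "(-4)x1,(-2)xn")
  lin <- data.frame(id = 1:8, mean_dwell = 100 - 10 * desc$cnc)
  r <- correlate_descriptors(lin, desc, subgroup = "(-4)x1,(-2)xn",
                             seed = 1)
  expect_equal(r$r, -1)
  expect_lt(r$p_perm, 0.05)

  set.seed(3)
  shuf <- data.frame(id = 1:8, mean_dwell = sample(lin$mean_dwell))
  r2 <- correlate_descriptors(shuf, desc, seed = 1)
  expect_gt(r2$p_perm, 0.01)

  const <- data.frame(id = 1:8, mean_dwell = rep(5, 8))
  r3 <- correlate_descriptors(const, desc)
  expect_true(r3$degenerate)
  expect_true(is.na(r3$r))

  expect_error(correlate_descriptors(lin[1:2, ], desc), "insufficient")
})
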