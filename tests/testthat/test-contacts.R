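# Contact maps, dynamic S/M/E windows, block contact kinetics, counterion
# condensation, gyration shape metrics.

test_that("a single scripted contact pair lights exactly one map cell", {
  script <- data.frame(time = 0:4, distance = 9, n_contacts = 1)
  tr <- gen_toy_two_chain_frames(script, n_chain = 10)
  m <- contact_map(tr, "inter")
  expect_equal(sum(m > 0), 1)
  expect_equal(max(m), 1)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("inter-chain maps transpose under chain exchange and intra maps are symmetric", {
  set.seed(5)
  seqs <- select_q_ensemble(2000, 8, max_keep = 1, seed = 5)
  tr <- run_two_chain(seqs[[1]], t_total = 10, stride_t = 1, seed = 3,
                      burn_in = 5, start_dimerized = TRUE)
  m_ab <- contact_map(tr, "inter")
  # relabel the chains and recompute: must be the exact transpose
  tr_sw <- tr
  tr_sw$species <- c(A = "B", B = "A", ion = "ion")[tr$species]
  m_ba <- contact_map(tr_sw, "inter")
  ord <- order(attr(m_ba, "sites_row"))
  expect_equal(unclass(m_ab), t(unclass(m_ba)), ignore_attr = TRUE)

  m_intra <- contact_map(tr, "intra", chain = "A")
  expect_equal(unclass(m_intra), t(unclass(m_intra)), ignore_attr = TRUE)
  expect_error(contact_map(tr, "inter", window = c(1e6, 2e6)), "empty")
})

test_that("difference maps decompose into the dimer and unimer intra maps", {
  d <- rep(c(5, 12), each = 10)
  tr <- gen_toy_two_chain_frames(data.frame(time = seq_along(d) - 1,
                                            distance = d, n_contacts = 2))
  st <- classify_states(tr)
  md <- contact_map(tr, "intra", frames = which(st$labels == "dimer"))
  mu <- contact_map(tr, "intra", frames = which(st$labels == "unimer"))
  diff_map <- contact_map(tr, "difference", series = st)
  expect_equal(unclass(diff_map), unclass(md) - unclass(mu),
               ignore_attr = TRUE)
})

test_that("dynamic maps carve S, M, E windows out of long dimer episodes", {
  d <- c(rep(12, 5), rep(5, 75), rep(12, 5))
  nc <- ifelse(d == 5, 0L, 0L)
  nc[6:30] <- 6L # contacts only during the first 250 tau of the episode
  script <- data.frame(time = (seq_along(d) - 1) * 10, distance = d,
                       n_contacts = nc)
  tr <- gen_toy_two_chain_frames(script, n_chain = 10)
  st <- classify_states(tr)
  dm <- dynamic_maps(tr, st, window_len = 250)
  expect_length(dm, 1)
  expect_gt(sum(dm[[1]]$S), 0)
  expect_equal(sum(dm[[1]]$M), 0)
  expect_equal(sum(dm[[1]]$E), 0)
  # cross-implementation identity: S window equals a restricted contact_map
  ep <- dm[[1]]$episode
  m_ref <- contact_map(tr, "inter", window = c(ep$t_start, ep$t_start + 250))
  expect_equal(unclass(dm[[1]]$S), unclass(m_ref), ignore_attr = TRUE)
  # short episodes are skipped
  short <- classify_states(gen_toy_two_chain_frames(
    data.frame(time = 0:20 * 10, distance = c(12, rep(5, 19), 12))))
  expect_length(dynamic_maps(tr, short, window_len = 1e4), 0)
})

test_that("block contact kinetics recovers renewal dwell means on the grid", {
  pat <- gen_block_contact_pattern(list(list(mean_closed = 100,
                                             mean_open = 48)),
                                   t_total = 6e4, resolution = 5, seed = 21)[[1]]
  # bound probability: phi = 100/148
  expect_lt(abs(pat$bound_prob - 100 / 148),
            3 * sqrt(0.675 * 0.325 / (6e4 / 148)) + 0.02)
  se_c <- 100 / sqrt(pat$n_closed)
  expect_lt(abs(pat$mean_closed - 100), 5 + 3 * se_c)
  se_o <- 48 / sqrt(pat$n_open)
  expect_lt(abs(pat$mean_open - 48), 5 + 3 * se_o)
})

test_that("an always-bound block yields probability one and censored intervals", {
  script <- data.frame(time = 0:9 * 5, distance = 5, n_contacts = 2)
  tr <- gen_toy_two_chain_frames(script, n_chain = 10)
  blk <- list(chain = "A", monomers = 1:2)
  bk <- block_contact_kinetics(tr, blk, resolution = 5)
  expect_equal(bk$bound_prob, 1)
  expect_equal(bk$n_closed, 0) # single interval, censored at both ends
  expect_true(all(bk$intervals$censored))
})

test_that("bound probability equals closed time over conditioned time", {
  set.seed(77)
  seqs <- select_q_ensemble(2000, 8, max_keep = 1, seed = 7)
  tr <- run_two_chain(seqs[[1]], t_total = 40, stride_t = 1, seed = 2,
                      burn_in = 10, start_dimerized = TRUE)
  st <- classify_states(tr)
  dec <- decompose_blocks(seqs[[1]])
  kmin <- which(dec$blocks$sign == -sign(seqs[[1]]$net_charge))[1]
  bk <- block_contact_kinetics(tr, tag_block(dec, kmin), series = st,
                               resolution = 1)
  expect_equal(bk$bound_prob, sum(bk$bound & bk$valid) / sum(bk$valid))
  expect_true(all(bk$intervals$duration > 0))
})

test_that("partner traces separate sliding from hopping", {
  pat <- gen_block_contact_pattern(list(list(mean_closed = 400,
                                             mean_open = 30)),
                                   t_total = 3e4, resolution = 5, seed = 4,
                                   jump_law = "sliding")[[1]]
  expect_equal(jump_statistic(pat$partner_trace), 1, tolerance = 0.15)
  pat2 <- gen_block_contact_pattern(list(list(mean_closed = 400,
                                              mean_open = 30)),
                                    t_total = 3e4, resolution = 5, seed = 4,
                                    jump_law = "hopping")[[1]]
  expect_gt(jump_statistic(pat2$partner_trace), 5)
})

test_that("contact_point_trace follows a walking contact point", {
  # chain B is a 12-bead line; one A monomer touches successive B sites
  n_b <- 12
  frames <- lapply(1:6, function(f) {
    b <- cbind(1.2 * seq_len(n_b), 0, 0) # spacing keeps one site in range
    a <- rbind(c(1.2 * f, 1.5, 0), c(-5, -5, 0), c(-6, -5, 0))
    rbind(a, b)
  })
  tr <- make_traj(frames, charge = rep(1, 3 + n_b),
                  species = c(rep("A", 3), rep("B", n_b)))
  trace <- contact_point_trace(tr, list(chain = "A", monomers = 1L))
  expect_equal(trace$frames, 1:6)
  expect_equal(trace$jump_stat, 1)
})

test_that("counterion condensation counts ions near the aggregate only", {
  mono <- cbind(seq(0, 9), 0, 0)
  ions <- rbind(c(5, 1.0, 0),   # within 1.8 of a monomer: condensed
                c(5, 2.0, 0),   # nearest monomer at 2.0: free
                c(9, 5.0, 0))   # far: free
  tr <- make_traj(list(rbind(mono, ions)), charge = c(rep(1, 10), -1, -1, -1),
                  species = c(rep("A", 10), rep("ion", 3)), box_L = 40)
  cc <- counterion_condensation(tr)
  expect_equal(cc$mean, 1)
  tr_no <- make_traj(list(mono), charge = rep(1, 10),
                     species = rep("A", 10))
  expect_error(counterion_condensation(tr_no), "counterions")
})

test_that("gyration eigenvalues respect symmetry, order and the trace identity", {
  # points on a sphere: three nearly equal eigenvalues
  set.seed(10)
  u <- matrix(rnorm(3000), ncol = 3)
  sphere <- 5 * u / sqrt(rowSums(u^2))
  tr <- make_traj(list(sphere), charge = rep(0, 1000),
                  species = rep("A", 1000))
  ev <- gyration_eigenvalues(tr, "A")$eigenvalues[1, ]
  expect_lt(diff(range(ev)) / mean(ev), 0.2)

  # collinear rod: two zero eigenvalues, flagged degenerate
  rod <- cbind(seq(0, 9), 0, 0)
  tr2 <- make_traj(list(rod), charge = rep(0, 10), species = rep("A", 10))
  sh2 <- gyration_eigenvalues(tr2, "A")
  expect_equal(sh2$eigenvalues[1, 1:2], c(0, 0), tolerance = 1e-10)
  expect_true(sh2$degenerate[1])

  # random cloud: ordering and sum(lambda) = mean squared centroid distance
  set.seed(11)
  cloud <- matrix(rnorm(300), ncol = 3)
  tr3 <- make_traj(list(cloud), charge = rep(0, 100),
                   species = rep("A", 100))
  ev3 <- gyration_eigenvalues(tr3, "A")$eigenvalues[1, ]
  expect_true(all(diff(ev3) >= 0))
  c0 <- sweep(cloud, 2, colMeans(cloud))
  expect_equal(sum(ev3), mean(rowSums(c0^2)), tolerance = 1e-10)

  expect_error(gyration_eigenvalues(
    make_traj(list(matrix(0, 2, 3) + 1:2), charge = c(0, 0),
              species = c("A", "A")), "A"), "3 particles")
})

test_that("a dimerized Q=8 run condenses a third of its counterions", {
  set.seed(55)
  seqs <- select_q_ensemble(2000, 8, max_keep = 1, seed = 50)
  tr <- run_two_chain(seqs[[1]], t_total = 150, stride_t = 1, seed = 51,
                      burn_in = 100, start_dimerized = TRUE)
  st <- classify_states(tr)
  cc <- counterion_condensation(tr, series = st)
  # 16 counterions in the box; the dimer binds roughly 4-5 of them
  expect_gt(cc$mean_dimer, 3)
  expect_lt(cc$mean_dimer, 6.5)
})
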