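#!/usr/bin/env Rscript

# Independent-block renewal model linking block dwell statistics to dimer
# lifetimes.
#
# Uses the measured block contact scales: closed dwells of 34/67/100 tau
# for minority blocks of size 2/3/4 (19 tau for a single charge) and a
# bound probability around 0.675 for a (-2) block. Reports (i) the linear
# monomer-composition fit of closed dwell vs block size, (ii) conditional
# occupancy relaxation, and (iii) how the mean time to simultaneous
# openness of n blocks — with and without a persistence window — compares
# with the ~1e4-1e5 tau dimer dwell scale. Writes
# results/toymodel_firstpassage.csv.

library(padimer)

dir.create("results", showWarnings = FALSE)
set.seed(11235)

# (i) composition heuristic vs the measured dwell ladder
d <- data.frame(size = 1:4, dwell = c(19, 34, 67, 100))
fit <- monomer_composition_estimate(1:4, single_monomer_dwell = 19, data = d)
cat(sprintf("closed dwell vs block size: slope %.1f tau/charge, intercept %.1f, R^2 %.3f\n",
            fit$slope, fit$intercept, fit$r_squared))

# (ii) occupancy relaxation of a (-2) block: phi = 34/(34+16.4) ~ 0.675
b2 <- two_state_block(closed = 34, open = 34 * (1 - 0.675) / 0.675)
cat(sprintf("(-2) block: phi = %.3f, occupancy at t = 50 tau from bound: %.3f\n",
            b2$phi, conditional_occupancy(b2, 50, "bound")))

# (iii) simultaneous openness of n blocks
blocks <- list(
  two_state_block(100, 100 * (1 - 0.898) / 0.898), # (-4)
  two_state_block(67, 67 * (1 - 0.84) / 0.84),     # (-3)
  two_state_block(34, 34 * (1 - 0.675) / 0.675))   # (-2)
rows <- list()
for (n in 1:3) {
  for (ts in c(0, 25)) {
    fp <- all_unbound_first_passage(blocks[seq_len(n)], ts = ts,
                                    reps = 2e4, start = "stationary")
    rows[[length(rows) + 1]] <- data.frame(
      n_blocks = n, ts = ts, mean_time = fp$mean, se = fp$se,
      censored = fp$censored_n)
    cat(sprintf("n = %d blocks, ts = %2.0f: mean all-open time %8.1f tau (se %.1f)\n",
                n, ts, fp$mean, fp$se))
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/toymodel_firstpassage.csv", row.names = FALSE)

cat(sprintf("\nn = 2 exponential cross-check: MC %.1f vs closed form %.1f tau\n",
            all_unbound_first_passage(blocks[1:2], ts = 0, reps = 2e4,
                                      start = "all_bound")$mean,
            analytic_first_passage_exp(blocks[1:2], "all_bound")))
cat("\nEven three blocks give all-open times of only a few hundred tau;\n")
cat("dimer dwell times of 1e4-1e5 tau additionally require the residual\n")
cat("monomer contacts to release, i.e. a persistence window ts shared\n")
cat("across the blocks, which raises the time steeply once ts/n exceeds\n")
cat("the single-block closed dwell.\n")
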