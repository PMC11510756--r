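#!/usr/bin/env Rscript

# Dwell-time and survival analysis of dimer/unimer switching.
#
# The production-scale switching statistics (mean dwells of order 1e4 tau
# over ~1e6 tau trajectories) are emulated by the semi-Markov fixture at
# the group-A1 time scales; the estimator pipeline then recovers the dwell
# means, the matured (> 250 tau) means, and the exponential tail times
# exactly as it would from molecular dynamics state series. Also
# demonstrates the dwell-vs-CNC correlation report on a synthetic subgroup
# table. Writes results/dwell_summary.csv and results/survival_dimer.csv.

library(padimer)

dir.create("results", showWarnings = FALSE)
set.seed(271828)

tc <- pa_defaults()$survival_tc

# A1-scale switching with a transient (short-dwell) component
st <- gen_semi_markov_states(mean_dimer = 4.7e4, mean_unimer = 1.8e4,
                             family = "mixture", mix_frac = 0.5,
                             mix_mean = 100, t_total = 4e7, dt = 25)

rows <- list()
for (state in c("dimer", "unimer")) {
  dw <- dwell_distribution(st, state, tc = tc)
  sv <- survival_curve(dw, tc = tc)
  rows[[state]] <- data.frame(
    state = state, n_episodes = dw$n, censored = dw$censored_n,
    mean_all = dw$mean_all, mean_matured = dw$mean_tail,
    tau_r = sv$tau_r)
  cat(sprintf("%-6s: %4d episodes | mean %8.0f | matured mean %8.0f | tau_r %8.0f tau\n",
              state, dw$n, dw$mean_all, dw$mean_tail, sv$tau_r))
}
summary <- do.call(rbind, rows)
write.csv(summary, "results/dwell_summary.csv", row.names = FALSE)

sv <- survival_curve(dwell_distribution(st, "dimer", tc = tc), tc = tc)
write.csv(data.frame(t = sv$t, S = sv$S), "results/survival_dimer.csv",
          row.names = FALSE)
cat(sprintf("\nmatured/plain dwell ratio (dimer): %.2f\n",
            summary$mean_matured[1] / summary$mean_all[1]))

# CNC correlation within a fixed-blockiness subgroup (synthetic dwells with
# the anticorrelated structure the production ensembles show)
desc <- data.frame(id = 1:5, cnc = c(1, 2, 3, 4, 5),
                   subgroup = "(-3)x1,(-2)x2")
set.seed(99)
dwells <- data.frame(id = 1:5,
                     mean_dwell = 6e4 - 8e3 * desc$cnc + rnorm(5, 0, 3e3))
cr <- correlate_descriptors(dwells, desc, subgroup = "(-3)x1,(-2)x2",
                            seed = 1)
cat(sprintf("dwell-CNC Pearson r = %.2f (n = %d, permutation p = %.3f)\n",
            cr$r, cr$n, cr$p_perm))
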