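#!/usr/bin/env Rscript

# Short two-chain Langevin runs for two contrasting Q = 8 sequences.
#
# Picks one blocky (group A, longest minority block 4+) and one weakly
# blocky (group C) sequence from a fresh ensemble and runs each for a
# desk-scale production window in the poor-solvent force field, once from
# a dimerized start and once from separated chains. Trajectories are
# written under results/ in the native format for the downstream analysis
# drivers; a summary of the center-to-center distance is printed.

library(padimer)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
set.seed(3141)

seqs <- select_q_ensemble(5e4, target_q = 8)
tab <- describe_sequences(seqs)
pick_a <- which(tab$group %in% c("A1", "A2"))[1]
pick_c <- which(tab$group %in% c("C3", "C4"))[1]
picks <- c(blocky = pick_a, weak = pick_c)
print(tab[picks, ])

params <- forcefield_params(eps_lj = 0.60)
t_prod <- 1500  # tau; desk-scale window (production studies use ~1e6 tau)

for (nm in names(picks)) {
  s <- seqs[[picks[nm]]]
  for (start in c("dimer", "unimer")) {
    traj <- run_two_chain(s, params, t_total = t_prod, stride_t = 1,
                          seed = sample.int(2^31 - 1, 1), burn_in = 200,
                          start_dimerized = (start == "dimer"))
    path <- sprintf("scratch/traj_%s_%s.rds", nm, start)
    write_trajectory(traj, path)
    d <- center_distance(traj)
    st <- classify_states(traj)
    cat(sprintf("%-6s %-6s: d_cc %5.1f-%5.1f sigma, dimer fraction %.2f -> %s\n",
                nm, start, min(d), max(d), mean(st$labels == "dimer"), path))
  }
}
cat("\nNote: at this window length most runs stay in their starting basin;\n")
cat("switching statistics at the study's time scales come from the\n")
cat("semi-Markov fixtures in 03_state_kinetics.R.\n")
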