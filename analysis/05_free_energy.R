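#!/usr/bin/env Rscript

# Radial free-energy profile and Fokker-Planck passage times.
#
# The center-to-center coordinate is emulated by an overdamped walk in a
# double-well potential with minima at the dimer (5 sigma) and unimer
# (12 sigma) distances and a 4 kT dissociation barrier — the geometry the
# two-chain distance statistics show. The profile is re-extracted from the
# sampled distances exactly as from molecular dynamics (shell histogram,
# entropy correction, polynomial fit), and the mean first passage times are
# computed three ways: double-integral quadrature, brute-force walkers, and
# the qualitative barrier-flux estimate. Writes results/potential_profile.csv
# and results/mfpt_summary.csv.

library(padimer)

dir.create("results", showWarnings = FALSE)
set.seed(1618)

coef_true <- double_well_poly(r_dimer = 5, r_unimer = 12, barrier = 4)
D <- diffusion_coefficient(n_monomers = 100) # free-draining: 0.02 sigma^2/tau

r <- gen_radial_double_well_walk(coef_true, D = 1, t_total = 6e5, dt = 0.01,
                                 r0 = 5, lo = 2.5, hi = 15.5, stride = 5)
prof <- potential_from_trajectory(r, bin_width = 0.25)
print(prof)
write.csv(data.frame(r = prof$r, P = prof$P, V = prof$V, V_fit = prof$V_fit),
          "results/potential_profile.csv", row.names = FALSE)

mf_diss <- mfpt_radial(prof, D, "dissociation")
mf_dim <- mfpt_radial(prof, D, "dimerization")
fl <- kramers_flux_estimate(prof, D, "dissociation")
wk <- fp_walker_times(prof$coef, D = D, r0 = prof$r2, r_abs = prof$r1,
                      lo = prof$range[1], hi = prof$range[2], dt = 0.02,
                      n_walkers = 2000)

out <- data.frame(
  quantity = c("T_dissociation_quadrature", "T_dissociation_walkers",
               "T_dissociation_flux_estimate", "T_dimerization_quadrature"),
  time_tau = c(mf_diss$time, wk$mean, fl$time, mf_dim$time))
print(out, row.names = FALSE)
write.csv(out, "results/mfpt_summary.csv", row.names = FALSE)
cat(sprintf("\nwalker agreement: |quad - MC| = %.1f tau (MC se %.1f)\n",
            abs(mf_diss$time - wk$mean), wk$se))
cat(sprintf("flux estimate / quadrature = %.2f (order-of-magnitude check)\n",
            fl$time / mf_diss$time))
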