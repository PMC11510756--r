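# System construction and Langevin dynamics drivers. The force loop and
# BAOAB integrator live in src/md_core.cpp; these wrappers build initial
# configurations (self-avoiding chains, randomized counterions), run the
# warm-up / burn-in / production phases, and package trajectories.

species_codes <- function(species) {
  m <- c(A = 0L, B = 1L, ion = 2L)
  out <- m[species]
  if (any(is.na(out))) stop("unknown species label")
  unname(out)
}

grow_chain <- function(n, origin, bond = 0.97, min_sep = 0.9, max_try = 500,
                       avoid = NULL) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- origin
  for (i in seq_len(n)[-1]) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      u <- rnorm(3)
      cand <- pos[i - 1, ] + bond * u / sqrt(sum(u^2))
      ref <- rbind(if (i > 2) pos[seq_len(i - 2), , drop = FALSE], avoid)
      if (is.null(ref) || !nrow(ref)) { ok <- TRUE; break }
      d2 <- rowSums((ref - matrix(cand, nrow(ref), 3, byrow = TRUE))^2)
      if (min(d2) > min_sep^2) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to grow a self-avoiding chain")
    pos[i, ] <- cand
  }
  pos
}

place_ions <- function(n_ions, monomers, box_L, min_sep = 1.0, max_try = 2000) {
  if (n_ions == 0) return(matrix(0, 0, 3))
  out <- matrix(0, n_ions, 3)
  placed <- matrix(0, 0, 3)
  for (i in seq_len(n_ions)) {
    ok <- FALSE
    for (t in seq_len(max_try)) {
      cand <- runif(3, 0, box_L)
      ref <- rbind(monomers, placed)
      d <- ref - matrix(cand, nrow(ref), 3, byrow = TRUE)
      d <- d - box_L * round(d / box_L)
      if (min(rowSums(d^2)) > min_sep^2) { ok <- TRUE; break }
    }
    if (!ok) stop("failed to place counterions without overlap")
    out[i, ] <- cand
    placed <- rbind(placed, cand)
  }
  out
}

#' Build a simulation system of polyampholyte chains and counterions
#'
#' Chains are grown as self-avoiding random walks; monovalent counterions of
#' the opposite sign to the net charge are added so the system is globally
#' electroneutral, placed at random with an overlap check.
#'
#' @param seq A `pa_sequence`; every chain carries this identical sequence.
#' @param n_chains 1 or 2.
#' @param params A `pa_forcefield` (supplies the box edge).
#' @param separation Center-to-center distance (sigma) between the two chain
#'   start points (ignored for one chain).
#' @param n_counterions Number of counterions; default `n_chains * |Q|`.
#' @return A `pa_system` list: `pos`, `vel` (n x 3), `charge`, `species`
#'   (`"A"`, `"B"`, `"ion"`), `bonds` (2-column), `box_L`.
#' @export
build_system <- function(seq, n_chains = 2, params = forcefield_params(),
                         separation = 12,
                         n_counterions = n_chains * abs(seq$net_charge)) {
  stopifnot(inherits(seq, "pa_sequence"), n_chains %in% 1:2)
  L <- params$box_L
  if (!is.finite(L) || L <= 0) stop("build_system needs a finite periodic box")
  n <- seq$length
  centers <- if (n_chains == 2) {
    rbind(c(L / 2 - separation / 2, L / 2, L / 2),
          c(L / 2 + separation / 2, L / 2, L / 2))
  } else {
    matrix(c(L / 2, L / 2, L / 2), 1)
  }
  mono <- NULL
  for (i in seq_len(n_chains)) {
    # recenter each grown walk on its target center, avoiding earlier chains
    for (t in 1:50) {
      p <- grow_chain(n, origin = c(0, 0, 0))
      p <- sweep(p, 2, colMeans(p)) + matrix(centers[i, ], n, 3, byrow = TRUE)
      if (is.null(mono)) break
      d2 <- pair_dist2(p, mono, L)
      if (min(d2) > 0.81) break
      p <- NULL
    }
    if (is.null(p)) stop("failed to place non-overlapping chains")
    mono <- rbind(mono, p)
  }
  ion_sign <- if (seq$net_charge != 0) -sign(seq$net_charge) else -1
  ions <- place_ions(n_counterions, mono, L)
  pos <- rbind(mono, ions)
  charge <- c(rep(seq$charges, n_chains), rep(ion_sign, n_counterions))
  species <- c(rep(c("A", "B")[seq_len(n_chains)], each = n),
               rep("ion", n_counterions))
  bonds <- do.call(rbind, lapply(seq_len(n_chains), function(i) {
    off <- (i - 1) * n
    cbind(off + seq_len(n - 1), off + 2:n)
  }))
  vel <- matrix(rnorm(nrow(pos) * 3, sd = sqrt(params$kT)), ncol = 3)
  structure(list(pos = pos, vel = vel, charge = as.numeric(charge),
                 species = species, bonds = bonds, box_L = L),
            class = "pa_system")
}

#' Total potential energy of a system
#' @param system A `pa_system`.
#' @param params A `pa_forcefield`.
#' @return Potential energy in kT.
#' @export
total_energy <- function(system, params = forcefield_params()) {
  cpp_forces_energy(system$pos, system$charge,
                    species_codes(system$species), system$bonds,
                    unclass(params))$energy
}

#' Analytic forces on every particle
#' @inheritParams total_energy
#' @return An n x 3 matrix of forces (kT/sigma), the exact gradient of the
#'   truncated LJ/WCA + shifted Coulomb + FENE energy.
#' @export
total_forces <- function(system, params = forcefield_params()) {
  cpp_forces_energy(system$pos, system$charge,
                    species_codes(system$species), system$bonds,
                    unclass(params))$forces
}

#' Advance a system by Langevin dynamics
#'
#' One call to the BAOAB integrator (velocity-Verlet structure with an
#' exact Ornstein-Uhlenbeck thermostat step; at `zeta = 0` and `noise =
#' FALSE` it reduces to plain velocity Verlet). Randomness comes from R's
#' RNG stream, so `set.seed()` makes runs reproducible.
#'
#' @param system A `pa_system`.
#' @param params A `pa_forcefield`.
#' @param t Duration in tau.
#' @param dt Timestep (default 0.005 tau).
#' @param stride_t Time between recorded frames (tau); default records only
#'   the final state.
#' @param noise Include the stochastic kick (fluctuation-dissipation
#'   consistent); `FALSE` gives deterministic (damped or Hamiltonian) motion.
#' @param fcap Optional per-particle force cap used to relax overlapping
#'   initial states (0 = off).
#' @return List: updated `system`, recorded `pos` array (n x 3 x frames),
#'   `times`, `potential` and `kinetic` energies per frame.
#' @export
advance_system <- function(system, params = forcefield_params(), t, dt = 0.005,
                           stride_t = t, noise = TRUE, fcap = 0) {
  n_steps <- max(1L, round(t / dt))
  stride <- max(1L, round(stride_t / dt))
  res <- cpp_run_md(system$pos, system$vel, system$charge,
                    species_codes(system$species), system$bonds,
                    unclass(params), n_steps, stride, dt, fcap, noise)
  nfr <- dim(res$pos)[3]
  sys <- system
  sys$pos <- matrix(res$pos[, , nfr], ncol = 3)
  sys$vel <- res$vel
  list(system = sys, pos = res$pos,
       times = seq(0, by = stride * dt, length.out = nfr),
       potential = res$potential, kinetic = res$kinetic)
}

run_chains <- function(seq, n_chains, params, t_total, dt, stride_t, seed,
                       burn_in, separation, n_counterions) {
  if (!is.null(seed)) set.seed(seed)
  sys <- build_system(seq, n_chains, params, separation = separation,
                      n_counterions = n_counterions)
  if (t_total <= 0) {
    pos <- array(sys$pos, dim = c(nrow(sys$pos), 3, 1))
    return(new_pa_traj(pos, times = 0, system = sys, params = params,
                       seq = seq, dt = dt))
  }
  # staged overlap relaxation: raise the pair-force cap gradually so soft
  # cores decompress before full forces act, then thermal burn-in
  for (fcap in c(20, 100, 1000, 1e4)) {
    warm <- advance_system(sys, params, t = 1, dt = dt / 5,
                           noise = TRUE, fcap = fcap)
    sys <- warm$system
  }
  if (burn_in > 0) {
    eq <- advance_system(sys, params, t = burn_in, dt = dt,
                         stride_t = burn_in / 4, noise = TRUE)
    if (!all(is.finite(eq$potential)))
      stop("failed to equilibrate: energy diverged during burn-in")
    sys <- eq$system
  }
  prod <- advance_system(sys, params, t = t_total, dt = dt,
                         stride_t = stride_t, noise = TRUE)
  new_pa_traj(prod$pos, times = prod$times, system = prod$system,
              params = params, seq = seq, dt = dt,
              potential = prod$potential, kinetic = prod$kinetic)
}

#' Simulate two identical polyampholyte chains with counterions
#'
#' The production setup of the dimerization study: two chains carrying the
#' same charge sequence plus `2|Q|` monovalent counterions in a periodic
#' cubic box (default edge 30 sigma, i.e. unimer concentration `2/L^3`).
#' Chains start as separated self-avoiding walks (centers `separation`
#' apart, default in the unimer basin), are relaxed and thermalized for
#' `burn_in` tau, and frames are then recorded every `stride_t` tau.
#'
#' @inheritParams build_system
#' @param t_total Production length in tau (0 returns the initial frame only).
#' @param dt Timestep (tau).
#' @param stride_t Frame spacing (tau).
#' @param seed Optional seed.
#' @param burn_in Discarded equilibration time (tau).
#' @param start_dimerized Start with chain centers 5 sigma apart.
#' @return A `pa_traj` trajectory.
#' @export
run_two_chain <- function(seq, params = forcefield_params(), t_total,
                          dt = 0.005, stride_t = 1, seed = NULL,
                          burn_in = 500, start_dimerized = FALSE) {
  run_chains(seq, 2L, params, t_total, dt, stride_t, seed, burn_in,
             separation = if (start_dimerized) 5 else 12,
             n_counterions = 2L * abs(seq$net_charge))
}

#' Simulate a single chain with its counterions
#'
#' Used for unimer-state properties (counterion condensation, center-of-mass
#' diffusion). The default box edge `30 / 2^(1/3)` sigma keeps the monomer
#' and counterion concentrations equal to those of the two-chain study.
#'
#' @inheritParams run_two_chain
#' @return A `pa_traj`.
#' @export
run_single_chain <- function(seq, params = forcefield_params(box_L = 30 / 2^(1 / 3)),
                             t_total, dt = 0.005, stride_t = 1, seed = NULL,
                             burn_in = 500) {
  run_chains(seq, 1L, params, t_total, dt, stride_t, seed, burn_in,
             separation = 0, n_counterions = abs(seq$net_charge))
}
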