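#' Force-field parameters for the coarse-grained polyampholyte model
#'
#' Bundles the interaction constants of the bead-spring model: a truncated and
#' shifted Lennard-Jones potential between monomers (solvent quality enters
#' through the well depth `eps_lj`: 0.32 is the theta point of this model,
#' 0.60 a moderately poor solvent), a purely repulsive WCA potential for any
#' pair involving a counterion, FENE bonds along each chain, and Coulomb
#' interactions of strength set by the Bjerrum length.
#'
#' Inside the simulator the Coulomb pair energy is evaluated under the minimum
#' image convention, truncated at `rc_coul` (default half the box edge) and
#' shifted so the pair energy is continuous at the cutoff.
#'
#' @param eps_lj Monomer-monomer LJ well depth in kT (0.32 theta, 0.60 poor).
#' @param sigma Bead diameter; the length unit (1).
#' @param rc_mm Monomer-monomer LJ cutoff (2.5 sigma).
#' @param bjerrum Bjerrum length lB in sigma (3.0).
#' @param eps_wca Counterion excluded-volume strength in kT (1.0).
#' @param rc_wca WCA cutoff, `2^(1/6) * sigma` (purely repulsive).
#' @param fene_k FENE spring constant in kT/sigma^2 (Kremer-Grest 30).
#' @param fene_rmax FENE maximum extension (1.5 sigma).
#' @param kT Thermal energy (1).
#' @param zeta Friction coefficient in m/tau (1).
#' @param box_L Cubic box edge in sigma (30, periodic).
#' @param rc_coul Coulomb cutoff (default `box_L / 2`).
#' @return A list of class `pa_forcefield`.
#' @examples
#' forcefield_params()              # poor-solvent defaults of the dimer study
#' forcefield_params(eps_lj = 0.32) # theta solvent
#' @export
forcefield_params <- function(eps_lj = 0.60, sigma = 1, rc_mm = 2.5 * sigma,
                              bjerrum = 3.0 * sigma, eps_wca = 1.0,
                              rc_wca = 2^(1 / 6) * sigma, fene_k = 30,
                              fene_rmax = 1.5 * sigma, kT = 1, zeta = 1,
                              box_L = 30 * sigma, rc_coul = box_L / 2) {
  p <- list(eps_lj = eps_lj, sigma = sigma, rc_mm = rc_mm, bjerrum = bjerrum,
            eps_wca = eps_wca, rc_wca = rc_wca, fene_k = fene_k,
            fene_rmax = fene_rmax, kT = kT, zeta = zeta, box_L = box_L,
            rc_coul = rc_coul)
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all force-field parameters must be numeric")
  pos <- c("eps_lj", "sigma", "rc_mm", "bjerrum", "eps_wca", "rc_wca",
           "fene_k", "fene_rmax", "kT", "box_L", "rc_coul")
  bad <- pos[vapply(p[pos], function(x) !is.finite(x) || x <= 0, logical(1))]
  if (length(bad)) stop("parameters must be positive: ", paste(bad, collapse = ", "))
  if (zeta < 0) stop("zeta must be >= 0")
  if (rc_mm <= sigma) stop("rc_mm must exceed sigma")
  structure(p, class = "pa_forcefield")
}

#' Truncated and shifted Lennard-Jones pair energy
#'
#' \deqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6
#'   - (\sigma/r_c)^{12} + (\sigma/r_c)^6]} for `r < rc`, 0 beyond the cutoff.
#'
#' @param r Pair distance(s), must be positive.
#' @param eps_lj Well depth in kT.
#' @param sigma Length scale.
#' @param rc Cutoff distance.
#' @return Energy in kT (vectorized over `r`).
#' @export
lj_energy <- function(r, eps_lj, sigma = 1, rc = 2.5 * sigma) {
  if (any(r <= 0)) stop("lj_energy: r must be positive")
  s6 <- (sigma / r)^6
  s6c <- (sigma / rc)^6
  u <- 4 * eps_lj * (s6^2 - s6 - s6c^2 + s6c)
  u[r >= rc] <- 0
  u
}

#' Bare Coulomb pair energy
#'
#' `z_i z_j * lB / r` in units of kT, the model's definition of the
#' electrostatic pair interaction. (The simulator additionally truncates and
#' shifts this at its cutoff; see [forcefield_params()].)
#'
#' @param r Pair distance(s), positive.
#' @param zi,zj Charge valences.
#' @param bjerrum Bjerrum length.
#' @return Energy in kT.
#' @export
coulomb_energy <- function(r, zi, zj, bjerrum = 3) {
  if (any(r <= 0)) stop("coulomb_energy: r must be positive")
  zi * zj * bjerrum / r
}

#' FENE bond energy
#'
#' \deqn{U(r) = -\tfrac{1}{2} k r_{max}^2 \log(1 - (r/r_{max})^2)} for
#' `0 <= r < rmax`; the potential diverges at the maximum extension, which is
#' reported as a bond blow-up error.
#'
#' @param r Bond length(s) in `[0, rmax)`.
#' @param k Spring constant (30 kT/sigma^2).
#' @param rmax Maximum extension (1.5 sigma).
#' @return Energy in kT.
#' @export
fene_energy <- function(r, k = 30, rmax = 1.5) {
  if (any(r < 0)) stop("fene_energy: r must be non-negative")
  if (any(r >= rmax)) stop("fene_energy: bond length >= rmax (bond blow-up)")
  -0.5 * k * rmax^2 * log(1 - (r / rmax)^2)
}

#' WCA (purely repulsive LJ) pair energy
#'
#' Used for every pair involving a counterion; equals the truncated-shifted
#' LJ with cutoff at its minimum `2^(1/6) sigma`.
#'
#' @inheritParams lj_energy
#' @param eps Repulsion strength in kT.
#' @return Energy in kT.
#' @export
wca_energy <- function(r, eps = 1, sigma = 1) {
  lj_energy(r, eps_lj = eps, sigma = sigma, rc = 2^(1 / 6) * sigma)
}
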