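---
title: "Modeling charge-sequence effects on polyampholyte dimerization kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling charge-sequence effects on polyampholyte dimerization kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padimer)
```

## The physical problem

A polyampholyte (PA) is a polymer carrying both positive and negative
charges — the minimal physical picture of a charged intrinsically
disordered protein. Two identical PA chains with a non-zero net charge $Q$
sit near the Rayleigh threshold where cohesion (poor-solvent attraction,
plus/minus pairing) barely balances the electrostatic self-repulsion of the
combined charge $2Q$. In that regime the pair switches stochastically
between a bound **dimer** and two separated **unimers**, and the *pattern*
of the charges along the chain — not just $Q$ — controls how fast it
switches. This package implements the full chain of reasoning: sequence
taxonomy, coarse-grained dynamics, two-state kinetics, contact structure,
a one-dimensional Fokker–Planck transition-rate model, and a renewal toy
model that connects single charge-block kinetics to dimer lifetimes.

All quantities are in reduced units: bead diameter $\sigma$ (length),
thermal energy $k_BT = 1$ (energy), bead mass $m = 1$, and
$\tau = \sigma\sqrt{m/k_BT}$ (time).

## Charge sequences and their descriptors

Chains have $N = 100$ beads; charges of $\pm 1$ sit on both end monomers
and on every third monomer, giving 34 charged sites. `generate_sequence()`
draws the 34 signs from a symmetric first-order Markov chain with a
nearest-charged-site correlation $\rho$; the default $\rho = 0$ gives
unbiased i.i.d. signs, so $\langle Q\rangle = 0$ and
$\mathrm{Var}(Q) = 34$. A fixed-$Q$ ensemble (here $Q = 8$, i.e. 21
majority and 13 minority charges) is obtained by rejection from a random
pool (`select_q_ensemble()`).

Three descriptor conventions matter and are deliberately fixed:

* **Blocks are runs over the charged-site subsequence.** Neutral spacer
  monomers are ignored, so a "block of 4" is four consecutive *charged
  sites* of one sign. Tallies such as "one block of $-4$" are only
  meaningful under this convention, because charges are never adjacent
  monomers on this template.
* **Groups** classify the minority-charge blockiness by the longest block
  (4/3/2 → A/B/C families, 5 → AA, 6 → AAA) and its multiplicity (A2, B3,
  B2, B1, C5, C4, C3). Multiplicities outside the canonical taxonomy get
  systematic labels (C2, B4, ...) and an `in_taxonomy = FALSE` flag rather
  than an error, so the classifier is total. The A1 group splits into the
  subgroups `(-4)x1,(-3)x1` (a triplet present — triplet takes precedence)
  and `(-4)x1,(-2)xn` (doublets only).
* **Central net charge (CNC)** is $Q$ minus the majority-sign runs at the
  two chain termini (a terminus whose first charged site is minority-sign
  contributes zero). CNC measures the charge of the collapsed core once
  the majority tails are excluded; a small or negative CNC means the core
  sits safely below the Rayleigh threshold and the dimer is stable. The
  degenerate all-one-sign sequence returns $Q$ minus that single block,
  with a warning.

## The coarse-grained model

`forcefield_params()` collects the interaction constants:

| interaction | form | default |
|---|---|---|
| monomer–monomer | truncated + shifted Lennard-Jones | $\epsilon_{LJ} = 0.60$ (poor solvent; 0.32 is the theta point), $r_c = 2.5\sigma$ |
| bonds | FENE | $k = 30\,k_BT/\sigma^2$, $r_{max} = 1.5\sigma$ |
| electrostatics | $z_i z_j \ell_B / r$ | $\ell_B = 3\sigma$ |
| counterion excluded volume | WCA | $\epsilon = 1$, $r_c = 2^{1/6}\sigma$ |

The two-chain system has 200 monomers (68 charged) plus $2|Q| = 16$
monovalent counterions for exact electroneutrality, in a periodic cubic box
of edge $L = 30\sigma$ (unimer concentration $2/L^3$). Single-chain runs
use $L = 30/2^{1/3}\sigma$ so the monomer and counterion concentrations
match the two-chain study.

**Electrostatics.** Coulomb interactions use the minimum-image convention
truncated at $L/2 = 15\sigma = 5\ell_B$ and energy-shifted so the pair
energy is continuous at the cutoff. At the cutoff the bare pair energy is
$\ell_B/(L/2) = 0.2\,k_BT$ and decays as $1/r$ beyond; with a nearly
neutralized condensed chain the neglected tail is small compared with the
$k_BT$-scale barriers analyzed here. This desk-scale choice replaces a
particle-mesh Ewald sum; it is exact for all pairs closer than $15\sigma$,
which covers the entire dimer and its condensed ion cloud.

**Dynamics.** The Langevin equation (friction $\zeta = 1$, Gaussian noise
obeying fluctuation–dissipation at $k_BT = 1$) is integrated by the BAOAB
splitting with $\Delta t = 0.005\tau$, the standard stable step for FENE
bead-spring chains at this temperature. At $\zeta = 0$ with the noise off
the scheme reduces to velocity Verlet, which the test suite uses to bound
total-energy drift (below $10^{-4}\,k_BT/\tau$) and to verify the analytic
forces against central differences of the energy ($10^{-6}$ relative).
FENE constants are the standard Kremer–Grest values. Initial states are
self-avoiding walks (chain centers $12\sigma$ apart, or $5\sigma$ with
`start_dimerized = TRUE`) with counterions placed at random subject to an
overlap check; residual overlaps are relaxed by a short staged warm-up in
which *non-bonded* pair forces are capped at increasing values
(20, 100, 1000, $10^4$) at $\Delta t/5$ — bonded FENE forces are never
capped, so the relaxation cannot overstretch bonds. A default burn-in of
$500\tau$ is discarded before production.

## Two-state kinetics

`classify_states()` labels each frame **dimer** when the minimum-image
distance between the chain centroids is below $10\sigma$ (the barrier-top
distance of the free-energy profile), or, equivalently, when strictly more
than 4 inter-chain monomer pairs are within $1.8\sigma$. Coordinates are
stored unwrapped, so centroids are always well defined; only relative
separations are minimum-imaged. No smoothing is applied by default —
short-lived transient episodes carry physical information — but a
`min_frames` debounce exists for sensitivity checks.

Dwell times are the durations of completed episodes; episodes truncated by
either trajectory end are censored and counted separately. The survival
curve of "matured" episodes,
$$S(t) = 1 - \frac{\int_{t_c}^{t} p(t')\,dt'}{\int_{t_c}^{\infty} p(t')\,dt'},
\qquad t_c = 250\tau,$$
renormalizes the population to 1 at the maturity cutoff; its exponential
tail time $\tau_r$ is fitted by least squares on $\log S$ from $t_c$ down
to $S = 0.05$ (the fit window is reported). Per-episode (unweighted)
statistics are used throughout. `correlate_descriptors()` reports the
Pearson correlation of mean dwell time with CNC inside a fixed-blockiness
subgroup, with a permutation p-value, refusing fewer than three sequences
and flagging zero-variance inputs.

All analysis thresholds ($10\sigma$, $1.8\sigma$, $>4$ contacts, $250\tau$,
$5\tau$) live in exactly one place, `pa_defaults()`, and every function
default refers to it.

## Contact structure

Contact maps (`contact_map()`) count, per charged-site pair, the fraction
of frames with pair distance below $1.8\sigma$: inter-chain, intra-chain,
or the dimer-minus-unimer difference of intra-chain maps. Dynamic maps
(`dynamic_maps()`) evaluate the inter-chain map in $250\tau$ windows at
the start (S), midpoint (M) and end (E) of each sufficiently long dimer
episode.

A tagged charge block is **closed** in a frame when *any* of its monomers
touches *any* monomer of the other chain — the block acts as a unit.
Block series are sampled at $5\tau$ resolution, and when a state series is
supplied the statistics are conditioned on the dimer state: unimer frames
are discarded and intervals crossing a state change are censored at the
boundary. Reported statistics: mean closed/open dwells over completed
intervals, bound probability (closed time over conditioned time — an
identity the tests check), the apparent short-time power-law exponent of
the closed-dwell distribution below $100\tau$, and the conditional mean of
events longer than $50\tau$. `contact_point_trace()` summarizes whether a
block *slides* (small partner-index jumps between consecutive bound
frames) or *hops* (large jumps).

Counterion condensation counts ions within $1.8\sigma$ of the nearest
monomer of the relevant aggregate (the two-chain dimer, or each chain
separately in the unimer state). Shape is summarized by the ordered
eigenvalues $\lambda_1 \le \lambda_2 \le \lambda_3$ of the mass-uniform
gyration tensor (with unit masses this is proportional to the inertia
shape tensor; the trace identity $\sum_i \lambda_i = \langle |r -
\bar r|^2\rangle$ is tested on every frame).

## Free-energy profile and Fokker–Planck passage times

With the center-to-center distance $r$ as reaction coordinate, the shell
probability $P(r)$ gives the potential of mean force
$$V(r) = -\log P(r) + 2\log (r/\sigma),$$
where the $2\log r$ term removes the entropy of the spherical shell.
`potential_from_trajectory()` bins $r$ (default $0.25\sigma$), applies the
correction, and fits a polynomial of degree 6–8 chosen by 5-fold
cross-validated residual. Basin and barrier geometry (dimer minimum $r_2$,
unimer minimum $r_1$, barrier top $r^*$, barrier heights, the width $L^*$
where $V$ is within $1\,k_BT$ of the top, and the $1\,k_BT$ sink shell
volumes) is located on the fitted polynomial; the additive constant is
fixed by $V(r_2) = 0$. Two numerical guards: extrema within 2% of the fit
range ends are ignored (polynomial edge wiggles), and a candidate barrier
must rise at least $0.2\,k_BT$ above the higher minimum — near-flat data
report "no barrier found" instead of fitting noise.

Passage times come from the stationary-weight double quadrature of the
radial Smoluchowski equation (weight $r^2 e^{-V}$):
$$T_{\mathrm{diss}} = \frac{1}{D}\int_{r_2}^{r_1} dy\, \frac{e^{V(y)}}{y^2}
\int_{r_{in}}^{y} dz\, z^2 e^{-V(z)},$$
mirrored for dimerization with a reflecting outer wall. The inner
reflecting boundary defaults to the smallest sampled $r$ (the dimer hard
core) and the outer to the largest; the absorbing target is the
destination minimum by default, with a `basin_edge` option (absorb at the
barrier top) since either convention is defensible. Quadrature error is
estimated by grid halving and reported. The qualitative barrier-flux
estimate inverts the flux $D\,4\pi r^{*2} e^{-V^*} / (V_{sink} L^*)$; it
is within a factor ~1.3 of the quadrature for deep barriers (the tests
assert a factor 3) and is flagged invalid below $1\,k_BT$, where no
thermalized-sink argument applies.

The coordinate diffusion constant $D$ is twice the center-of-mass
diffusion constant of one unimer: the free-draining value
$2k_BT/(N\zeta) = 0.02\,\sigma^2/\tau$ by default, or a measured mode that
fits the center-of-mass MSD slope over a stated lag window (single-
trajectory MSD slopes are noisy; the tests average an ensemble of walkers
to verify the estimator is unbiased).

## The independent-block toy model

Within a dimer, each minority block alternates between closed and open
with dwell distributions $p_1, p_2$ (exponential or empirical), giving the
equilibrium bound probability $\varphi = \langle t_1\rangle /
(\langle t_1\rangle + \langle t_2\rangle)$. `conditional_occupancy()`
returns the closed-form exponential relaxation
$\varphi + (1-\varphi)e^{-t/\tau_{rel}}$, $\tau_{rel}^{-1} =
\langle t_1\rangle^{-1} + \langle t_2\rangle^{-1}$, or solves the
alternating renewal equations by discrete convolution for empirical
dwells (resampled by inverse CDF on the measurement grid).

`all_unbound_first_passage()` estimates, by event-driven Monte Carlo, the
first time all $n$ independent blocks are simultaneously open — and, with
a persistence window $t_s$, stay open together for a full $t_s$ (the
reported time is the start of the qualifying gap, so with $n = 1$,
$t_s = 0$ and a bound start the mean is exactly $\langle t_1\rangle$).
Blocks start at stationarity (state drawn with probability $\varphi$,
appropriate for dimer-conditioned statistics, and exact for memoryless
dwells) unless an all-bound start is requested. Closed forms for $n \le 2$
exponential blocks (the $n = 2$ case via the four-state continuous-time
Markov chain) serve as oracles, not as the implementation. The model's
punchline survives scaling down: simultaneous openness of a few blocks
takes only hundreds of $\tau$, so the $10^4$–$10^5\tau$ dimer lifetimes
require the persistence window created by residual monomer contacts, and
the mean time grows steeply once $t_s/n$ exceeds the single-block closed
dwell.

`monomer_composition_estimate()` exposes the linear composition heuristic
$\langle t_1\rangle(b) = b \times t_{single}$ with a least-squares fit of
measured (size, dwell) data; it is labeled a heuristic and its fit quality
is reported, not asserted.

## Synthetic fixtures: what they emulate and what they do not

Every analysis stage is testable without molecular dynamics:

* `gen_semi_markov_states()` — alternating two-state series with
  exponential (optionally short-dwell mixture) dwells on a frame grid;
  emulates dimer/unimer switching including the excess of transient
  events below $250\tau$.
* `gen_radial_double_well_walk()` / `fp_walker_times()` — overdamped
  radial diffusion with drift $-DV'(r) + 2D/r$, whose stationary law
  $\propto r^2 e^{-V}$ is verified in the tests; the end-to-end oracle for
  the profile extraction and MFPT quadrature.
* `gen_block_contact_pattern()` — independent renewal bound/open series on
  the $5\tau$ grid, with optional sliding/hopping partner traces.
* `gen_toy_two_chain_frames()` — scripted frames realizing an exact
  center distance and contact count per frame, for exact classifier and
  map tests (contradictory scripts are rejected).

The fixtures reproduce only the statistical structure the estimators
consume — dwell laws, the radial stationary law, contact grids. They do
not contain polymer physics: passing fixture tests validates the
*estimators*, while the scaled-down Langevin runs validate the *model*
qualitatively (collapse ordering with solvent quality, dimer persistence
of blocky sequences, counterion condensation levels). What the fixture
suite cannot show is quantitative agreement of full production kinetics,
which requires trajectory lengths far beyond a desk-scale run.

## Problem sizes used by the tests and scripts

The default test suite runs two-chain dynamics only for tens of $\tau$
(structure and identity checks) and validates statistics on fixtures:
~500 dwell episodes at the study's $4.7\times10^4 / 1.8\times10^4\tau$
dimer/unimer scales, $10^4$ Fokker–Planck walkers in a $4\,k_BT$ double
well, and $10^5$ Monte Carlo replicates for the toy-model closed forms.
`scripts/acceptance.R` simulates six independent $Q = 8$ single-chain
systems for $3000\tau$ each (after $300\tau$ burn-in) and reports the mean
number of condensed counterions per unimer chain; the analysis drivers
under `analysis/` use windows of $1500$–$6\times10^5\tau$ per stage. These
sizes were chosen as the smallest at which the assertions' statistical
tolerances (3 standard errors unless a structural identity) are
meaningful.

## Known limitations

* Truncated minimum-image electrostatics rather than a mesh Ewald sum;
  interactions beyond $15\sigma$ (0.2 $k_BT$ bare) are dropped.
* No hydrodynamic interactions (free-draining friction); absolute time
  scales of diffusive approach are correspondingly approximate.
* Two chains only; no multi-chain cluster bookkeeping.
* The radial Fokker–Planck model assumes spherical symmetry; elongated
  pearl-necklace dimers violate it and are expected to deviate.
* Desk-scale trajectory windows: the analysis drivers demonstrate the
  pipeline and qualitative orderings, not converged production kinetics.
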