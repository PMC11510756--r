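# Synthetic fixtures reproducing the statistical structure the analysis
# stages assume (two-state switching, radial double-well diffusion, block
# renewal patterns, scripted two-chain frames), so every estimator is
# testable without molecular dynamics. Realism is minimal-sufficient: only
# the features the estimators consume are reproduced, not polymer physics.

#' Synthetic dimer/unimer state series from a semi-Markov process
#'
#' Alternating dimer/unimer dwells drawn from the stated family
#' (exponential by default; `"mixture"` adds a short-lived transient
#' component to mimic the many fast switchings observed below the maturity
#' cutoff), sampled onto a frame grid of spacing `dt`.
#'
#' @param mean_dimer,mean_unimer Mean dwell times (tau).
#' @param family `"exponential"` or `"mixture"`.
#' @param t_total Series length (tau).
#' @param dt Frame spacing (tau); dwell means far below `dt` alias and
#'   produce a warning.
#' @param seed Optional seed.
#' @param start Initial state.
#' @param mix_frac,mix_mean Mixture parameters: fraction of transient dwells
#'   and their mean.
#' @return A `pa_states` with criterion `"synthetic"`.
#' @export
gen_semi_markov_states <- function(mean_dimer, mean_unimer,
                                   family = c("exponential", "mixture"),
                                   t_total, dt, seed = NULL,
                                   start = "unimer", mix_frac = 0.6,
                                   mix_mean = 100) {
  family <- match.arg(family)
  stopifnot(mean_dimer > 0, mean_unimer > 0, t_total > 0, dt > 0)
  if (dt > min(mean_dimer, mean_unimer))
    warning("frame spacing exceeds a mean dwell: state series will alias")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(m) {
    if (family == "exponential") return(rexp(1, rate = 1 / m))
    if (runif(1) < mix_frac) rexp(1, rate = 1 / mix_mean)
    else rexp(1, rate = 1 / m)
  }
  state <- start
  t_edges <- 0
  states <- character(0)
  while (tail(t_edges, 1) < t_total) {
    d <- draw(if (state == "dimer") mean_dimer else mean_unimer)
    states <- c(states, state)
    t_edges <- c(t_edges, tail(t_edges, 1) + d)
    state <- setdiff(c("dimer", "unimer"), state)
  }
  times <- seq(0, t_total, by = dt)
  idx <- findInterval(times, t_edges, rightmost.closed = FALSE)
  labels <- states[pmin(idx, length(states))]
  new_pa_states(times, labels, criterion = "synthetic")
}

poly_multiply <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
      out[i:(i + length(b) - 1)] + a[i] * b
  out
}

#' Polynomial radial double-well potential
#'
#' Builds quartic coefficients for a double well with minima at the dimer
#' and unimer distances and a barrier of the requested height above the
#' dimer minimum: `V'(r) = c (r - r2)(r - rb)(r - r1)`.
#'
#' @param r_dimer,r_unimer Minima locations (sigma).
#' @param r_barrier Barrier-top location (default midpoint).
#' @param barrier Barrier height above the dimer minimum (kT).
#' @return Coefficient vector (constant term first) with `V(r_dimer) = 0`.
#' @export
double_well_poly <- function(r_dimer = 5, r_unimer = 12,
                             r_barrier = (r_dimer + r_unimer) / 2,
                             barrier = 4) {
  stopifnot(r_dimer < r_barrier, r_barrier < r_unimer, barrier > 0)
  dv <- poly_multiply(poly_multiply(c(-r_dimer, 1), c(-r_barrier, 1)),
                      c(-r_unimer, 1))
  coef <- c(0, dv / seq_along(dv))           # antiderivative
  height <- polyval_r(coef, r_barrier) - polyval_r(coef, r_dimer)
  coef <- coef * (barrier / height)
  coef[1] <- -polyval_r(coef, r_dimer)
  coef
}

#' Overdamped Brownian walk in a radial potential
#'
#' Simulates `dr = (-D V'(r) + 2D/r) dt + sqrt(2 D dt) xi` with reflecting
#' walls, whose stationary law is proportional to `r^2 exp(-V(r))`; the
#' end-to-end fixture for [potential_from_trajectory()] and
#' [mfpt_radial()].
#'
#' @param coef Polynomial coefficients of V (constant first), e.g. from
#'   [double_well_poly()].
#' @param D Diffusion coefficient (sigma^2/tau).
#' @param t_total Total simulated time (tau).
#' @param dt Timestep; must satisfy the drift-stability bound.
#' @param r0 Starting radius.
#' @param lo,hi Reflecting boundaries.
#' @param stride Record every `stride` steps.
#' @param seed Optional seed.
#' @return Numeric vector of recorded radii.
#' @export
gen_radial_double_well_walk <- function(coef, D = 1, t_total, dt = 0.01,
                                        r0 = NULL, lo = 1, hi = 20,
                                        stride = 10, seed = NULL) {
  stopifnot(lo > 0, hi > lo, t_total > 0, dt > 0)
  rg <- seq(lo, hi, length.out = 500)
  dmax <- max(abs(-D * polyval_r(polyder_coef(coef), rg) + 2 * D / rg))
  if (dmax * dt > 0.5 * (hi - lo))
    stop("dt violates drift stability for this potential")
  if (is.null(r0)) r0 <- (lo + hi) / 2
  if (!is.null(seed)) set.seed(seed)
  cpp_radial_walk(coef, D, r0, lo, hi, dt, round(t_total / dt), stride)
}

#' Brute-force first-passage times of radial walkers
#'
#' Monte Carlo oracle for [mfpt_radial()]: `n_walkers` independent
#' overdamped walkers started at `r0`, absorbed at `r_abs`, reflected at
#' `lo` and `hi`.
#'
#' @inheritParams gen_radial_double_well_walk
#' @param r0 Start radius.
#' @param r_abs Absorbing radius.
#' @param n_walkers Number of walkers.
#' @param t_max Censoring horizon.
#' @return List: `times` (uncensored), `mean`, `se`, `censored_n`.
#' @export
fp_walker_times <- function(coef, D = 1, r0, r_abs, lo = 1, hi = 20,
                            dt = 0.01, n_walkers = 1e4, t_max = 1e7,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- cpp_fp_walk_times(coef, D, r0, r_abs, lo, hi, dt,
                          as.integer(n_walkers), t_max)
  ok <- tt < t_max
  list(times = tt[ok], mean = mean(tt[ok]),
       se = sd(tt[ok]) / sqrt(sum(ok)), censored_n = sum(!ok))
}

#' Synthetic block contact patterns
#'
#' Independent alternating-renewal bound/open series per block, sampled on
#' the measurement grid (default 5 tau), as produced by
#' [block_contact_kinetics()] on real trajectories. Optionally attaches a
#' partner-index trace following a sliding (unit steps) or hopping (distant
#' jumps) law for the jump statistic.
#'
#' @param blocks List of `list(mean_closed = , mean_open = )` per block.
#' @param t_total Series length (tau).
#' @param resolution Sampling period (tau).
#' @param seed Optional seed.
#' @param jump_law `"none"`, `"sliding"`, or `"hopping"`.
#' @param n_sites Partner chain length for traces.
#' @return List of `pa_block_series`-like objects (times, bound flags,
#'   intervals, dwell means, bound probability, optional `partner_trace`).
#' @export
gen_block_contact_pattern <- function(blocks, t_total,
                                      resolution = pa_defaults()$block_resolution,
                                      seed = NULL,
                                      jump_law = c("none", "sliding", "hopping"),
                                      n_sites = 34) {
  jump_law <- match.arg(jump_law)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_total, by = resolution)
  lapply(blocks, function(b) {
    stopifnot(b$mean_closed > 0, b$mean_open > 0)
    phi <- b$mean_closed / (b$mean_closed + b$mean_open)
    state <- runif(1) < phi
    edges <- 0
    states <- logical(0)
    while (tail(edges, 1) < t_total) {
      d <- rexp(1, rate = 1 / if (state) b$mean_closed else b$mean_open)
      states <- c(states, state)
      edges <- c(edges, tail(edges, 1) + d)
      state <- !state
    }
    idx <- findInterval(times, edges, rightmost.closed = FALSE)
    bound <- states[pmin(idx, length(states))]
    iv <- intervals_from_flags(times, bound, rep(TRUE, length(times)))
    comp <- iv[!iv$censored, , drop = FALSE]
    closed <- comp$duration[comp$state == "closed"]
    open <- comp$duration[comp$state == "open"]
    trace <- NULL
    if (jump_law != "none") {
      trace <- rep(NA_real_, length(times))
      pos <- sample.int(n_sites, 1)
      for (i in which(bound)) {
        step <- if (jump_law == "sliding") sample(c(-1, 1), 1)
                else sample(5:15, 1) * sample(c(-1, 1), 1)
        pos <- min(max(pos + step, 1), n_sites)
        trace[i] <- pos
      }
    }
    structure(list(times = times, bound = bound,
                   valid = rep(TRUE, length(times)), intervals = iv,
                   resolution = resolution,
                   mean_closed = if (length(closed)) mean(closed) else NA_real_,
                   mean_open = if (length(open)) mean(open) else NA_real_,
                   n_closed = length(closed), n_open = length(open),
                   bound_prob = mean(bound),
                   partner_trace = trace,
                   phi_true = phi,
                   empty = !any(bound)),
              class = "pa_block_series")
  })
}

#' Jump statistic of a partner-index series
#'
#' Mean absolute index change between consecutive bound frames; the
#' sliding/hopping summary used by [contact_point_trace()].
#'
#' @param trace Numeric series of partner indices, `NA` when unbound.
#' @return Mean absolute jump.
#' @export
jump_statistic <- function(trace) {
  bound <- !is.na(trace)
  consec <- which(bound[-1] & bound[-length(bound)])
  if (!length(consec)) return(NA_real_)
  mean(abs(trace[consec + 1] - trace[consec]))
}

#' Minimal scripted two-chain frames
#'
#' Builds a toy trajectory realizing a prescribed per-frame center-to-center
#' distance and number of inter-chain contacts, for exact classifier and
#' contact-map tests. Each chain is `n_chain` monomers; contact pairs are
#' placed midway between the chain centers at the scripted pair gap, and the
#' remaining monomers rebalance each chain's centroid.
#'
#' @param script Data frame with columns `time`, `distance`, and optionally
#'   `n_contacts` (default 0) and `contact_distance` (default 1.0 sigma).
#' @param n_chain Monomers per chain (>= 2 + max contacts).
#' @param cutoff Contact cutoff the script must respect.
#' @return A `pa_traj` with two all-charged chains and no counterions.
#' @export
gen_toy_two_chain_frames <- function(script, n_chain = 10,
                                     cutoff = pa_defaults()$contact_cutoff) {
  stopifnot(is.data.frame(script), all(c("time", "distance") %in% names(script)))
  if (is.unsorted(script$time, strictly = TRUE))
    stop("script times must be strictly increasing")
  if (is.null(script$n_contacts)) script$n_contacts <- 0L
  if (is.null(script$contact_distance)) script$contact_distance <- 1.0
  if (any(script$n_contacts > 0 & script$contact_distance >= cutoff))
    stop("contradictory script: contact demanded at pair distance >= cutoff")
  if (any(script$n_contacts > n_chain - 2))
    stop("n_contacts must leave at least 2 balancing monomers per chain")
  nf <- nrow(script)
  pos <- array(0, dim = c(2 * n_chain, 3, nf))
  for (f in seq_len(nf)) {
    d <- script$distance[f]
    k <- script$n_contacts[f]
    g <- script$contact_distance[f]
    cA <- c(0, 0, 0); cB <- c(d, 0, 0)
    offA <- matrix(0, n_chain, 3)
    offB <- matrix(0, n_chain, 3)
    if (k > 0) {
      lat <- (seq_len(k) - (k + 1) / 2) * 3   # separate pairs laterally
      offA[seq_len(k), ] <- cbind(d / 2 - g / 2, lat, 0)
      offB[seq_len(k), ] <- cbind(-d / 2 + g / 2, lat, 0)
    }
    rest <- (k + 1):n_chain
    nr <- length(rest)
    bal_A <- -colSums(offA[seq_len(k), , drop = FALSE]) / nr
    bal_B <- -colSums(offB[seq_len(k), , drop = FALSE]) / nr
    ang <- 2 * pi * (seq_len(nr) - 1) / nr
    ring <- 0.3 * cbind(cos(ang) - mean(cos(ang)), sin(ang) - mean(sin(ang)), 0)
    offA[rest, ] <- matrix(bal_A, nr, 3, byrow = TRUE) + ring
    offB[rest, ] <- matrix(bal_B, nr, 3, byrow = TRUE) + ring
    pos[seq_len(n_chain), , f] <- sweep(offA, 2, cA, "+")
    pos[n_chain + seq_len(n_chain), , f] <- sweep(offB, 2, cB, "+")
  }
  sys <- list(charge = rep(c(1, -1), n_chain),
              species = rep(c("A", "B"), each = n_chain),
              bonds = rbind(cbind(1:(n_chain - 1), 2:n_chain),
                            n_chain + cbind(1:(n_chain - 1), 2:n_chain)),
              box_L = Inf)
  new_pa_traj(pos, script$time, sys, params = NULL)
}
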