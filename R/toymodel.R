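# Independent-block renewal toy model: each charge block alternates between
# a closed (bound) and open (unbound) state with dwell distributions p1 and
# p2; dimer dissociation requires all blocks simultaneously open, possibly
# persisting for a window ts.

normalize_dwell <- function(x, what) {
  if (is.numeric(x) && length(x) == 1) x <- list(family = "exponential", mean = x)
  if (is.numeric(x)) x <- list(family = "empirical", samples = x)
  if (identical(x$family, "exponential")) {
    if (!is.finite(x$mean) || x$mean <= 0)
      stop(what, ": exponential mean must be positive and finite")
    x$m1 <- x$mean
    x$m2 <- 2 * x$mean^2
  } else if (identical(x$family, "empirical")) {
    s <- x$samples
    if (!length(s) || any(!is.finite(s)) || any(s < 0))
      stop(what, ": empirical samples must be non-negative and finite")
    x$m1 <- mean(s)
    x$m2 <- mean(s^2)
    if (x$m1 <= 0) stop(what, ": degenerate (zero-mean) dwell distribution")
  } else stop(what, ": unknown dwell family")
  x
}

#' Two-state (closed/open) block model
#'
#' A single charge block switching between a closed (bound to the foreign
#' chain) and open state, characterized by the dwell distributions `p1`
#' (closed) and `p2` (open) through their first two moments. The
#' equilibrium bound probability is `phi = <t1> / (<t1> + <t2>)`.
#'
#' @param closed Closed-state dwell spec: a single number (exponential
#'   mean), a numeric vector (empirical samples), or a list
#'   `list(family = , mean = / samples = )`.
#' @param open Open-state dwell spec, same forms.
#' @return A `two_state_block` with moments and `phi`.
#' @examples
#' b <- two_state_block(closed = 100, open = 48)
#' b$phi   # ~0.675 bound probability
#' @export
two_state_block <- function(closed, open) {
  p1 <- normalize_dwell(closed, "closed dwell")
  p2 <- normalize_dwell(open, "open dwell")
  phi <- p1$m1 / (p1$m1 + p2$m1)
  structure(list(p1 = p1, p2 = p2, phi = phi), class = "two_state_block")
}

#' @export
print.two_state_block <- function(x, ...) {
  cat("<two_state_block> <t1> =", signif(x$p1$m1, 4), " <t2> =",
      signif(x$p2$m1, 4), " phi =", signif(x$phi, 4), "\n")
  invisible(x)
}

#' Conditional occupancy of a block
#'
#' Probability of finding the block bound at time `t` given its state at
#' time 0. For exponential dwells this is the closed form
#' `P(bound, t | bound, 0) = phi + (1 - phi) exp(-t / tau_rel)` with
#' `tau_rel = (1/<t1> + 1/<t2>)^{-1}`; both start states relax to the
#' equilibrium population `phi`. For empirical dwells the alternating
#' renewal equations are solved by discrete convolution on a grid.
#'
#' @param block A `two_state_block`.
#' @param t Time(s) at which to evaluate (tau).
#' @param start `"bound"` or `"unbound"` state at time 0 (fresh dwell).
#' @param grid_dt Grid step for the empirical convolution (tau).
#' @return Probability/ies of being bound at `t`.
#' @export
conditional_occupancy <- function(block, t, start = c("bound", "unbound"),
                                  grid_dt = 1) {
  stopifnot(inherits(block, "two_state_block"))
  start <- match.arg(start)
  if (any(t < 0)) stop("t must be non-negative")
  phi <- block$phi
  exp_both <- identical(block$p1$family, "exponential") &&
              identical(block$p2$family, "exponential")
  if (exp_both) {
    tau_rel <- 1 / (1 / block$p1$m1 + 1 / block$p2$m1)
    if (start == "bound") return(phi + (1 - phi) * exp(-t / tau_rel))
    return(phi - phi * exp(-t / tau_rel))
  }
  occupancy_by_convolution(block, t, start, grid_dt)
}

dwell_pmf <- function(p, grid_dt, n) {
  # discretize dwell density onto bins [k*dt, (k+1)*dt)
  if (identical(p$family, "exponential")) {
    edges <- seq(0, by = grid_dt, length.out = n + 1)
    diff(pexp(edges, rate = 1 / p$mean))
  } else {
    h <- tabulate(pmin(floor(p$samples / grid_dt) + 1, n), nbins = n)
    h / length(p$samples)
  }
}

occupancy_by_convolution <- function(block, t, start, grid_dt) {
  t_max <- max(t)
  n <- max(16L, ceiling(t_max / grid_dt) + 1L)
  f1 <- dwell_pmf(block$p1, grid_dt, n)
  f2 <- dwell_pmf(block$p2, grid_dt, n)
  S1 <- 1 - cumsum(f1)                    # P(closed dwell > k dt)
  S1 <- c(1, head(S1, -1))
  conv <- function(a, b) {
    out <- convolve(a, rev(b), type = "open")[seq_len(n)]
    pmax(out, 0)
  }
  if (start == "bound") {
    cycle <- conv(f1, f2)                  # closed then open completed
    occ <- S1
    kern <- cycle
  } else {
    cycle <- conv(f2, f1)
    occ <- conv(f2, S1)
    kern <- cycle
  }
  # renewal sum: occ + kern*occ + kern^2*occ + ...
  total <- occ
  term <- occ
  for (i in 1:400) {
    term <- conv(kern, term)
    if (max(term) < 1e-10) break
    total <- total + term
  }
  idx <- pmin(floor(t / grid_dt) + 1L, n)
  pmin(pmax(total[idx], 0), 1)
}

#' Mean first time all blocks are simultaneously open
#'
#' Monte Carlo estimate (event-driven renewal simulation) of the first time
#' `n` independent two-state blocks are all open at once and, when
#' `ts > 0`, stay simultaneously open for a full persistence window `ts`
#' (the reported time is the start of the qualifying gap). This links
#' single-block dwell statistics to the much longer dimer dissociation
#' times: with more blocks, simultaneous openness becomes exponentially
#' rarer, and requiring persistence lengthens the time further once
#' `ts / n` exceeds the single-block closed dwell.
#'
#' @param blocks A `two_state_block`, or a list of them (one per block).
#' @param n Number of blocks when a single template block is given.
#' @param ts Persistence window (tau); 0 requires only instantaneous
#'   simultaneous openness.
#' @param reps Monte Carlo replicates.
#' @param start `"stationary"` draws each initial state with probability
#'   `phi` (dimer-conditioned statistics are near stationary);
#'   `"all_bound"` starts every block closed with a fresh dwell.
#' @param t_max Censoring horizon.
#' @param seed Optional seed.
#' @return List: `mean`, `se`, `times`, `censored_n`, `n_blocks`.
#' @export
all_unbound_first_passage <- function(blocks, n = NULL, ts = 0, reps = 1e4,
                                      start = c("stationary", "all_bound"),
                                      t_max = NULL, seed = NULL) {
  start <- match.arg(start)
  if (inherits(blocks, "two_state_block")) {
    if (is.null(n)) n <- 1L
    blocks <- rep(list(blocks), n)
  }
  stopifnot(all(vapply(blocks, inherits, logical(1), "two_state_block")))
  if (!is.null(seed)) set.seed(seed)
  spec <- function(p) if (identical(p$family, "exponential")) p$mean else p$samples
  ctype <- vapply(blocks, function(b)
    if (identical(b$p1$family, "exponential")) 0L else 1L, integer(1))
  otype <- vapply(blocks, function(b)
    if (identical(b$p2$family, "exponential")) 0L else 1L, integer(1))
  phi <- vapply(blocks, function(b) b$phi, numeric(1))
  if (is.null(t_max))
    t_max <- 1e4 * sum(vapply(blocks, function(b) b$p1$m1 + b$p2$m1,
                              numeric(1)))
  res <- cpp_toy_fp(lapply(blocks, function(b) spec(b$p1)),
                    lapply(blocks, function(b) spec(b$p2)),
                    ctype, otype, phi, ts, as.integer(reps),
                    start == "all_bound", t_max)
  ok <- !res$censored
  times <- res$times[ok]
  list(mean = mean(times), se = sd(times) / sqrt(length(times)),
       times = times, censored_n = sum(!ok), n_blocks = length(blocks),
       ts = ts, start = start)
}

#' Closed-form mean for one or two exponential blocks (ts = 0)
#'
#' Cross-validation oracle for [all_unbound_first_passage()]: for `n = 1`
#' starting bound the mean is `<t1>`; for `n = 2` the four-state
#' continuous-time Markov chain with the all-open state absorbing is solved
#' by linear algebra.
#'
#' @param blocks List of 1 or 2 exponential `two_state_block`s.
#' @param start `"all_bound"` or `"stationary"`.
#' @return Mean first passage time to the all-open state.
#' @export
analytic_first_passage_exp <- function(blocks,
                                       start = c("all_bound", "stationary")) {
  start <- match.arg(start)
  if (inherits(blocks, "two_state_block")) blocks <- list(blocks)
  ok <- vapply(blocks, function(b)
    identical(b$p1$family, "exponential") &&
    identical(b$p2$family, "exponential"), logical(1))
  if (!all(ok)) stop("closed form requires exponential dwells")
  if (length(blocks) == 1) {
    m1 <- blocks[[1]]$p1$m1
    return(if (start == "all_bound") m1 else blocks[[1]]$phi * m1)
  }
  if (length(blocks) != 2) stop("closed form implemented for n <= 2")
  la <- 1 / blocks[[1]]$p1$m1; mua <- 1 / blocks[[1]]$p2$m1
  lb <- 1 / blocks[[2]]$p1$m1; mub <- 1 / blocks[[2]]$p2$m1
  # transient states: 1 = (b,b), 2 = (b,o), 3 = (o,b); (o,o) absorbing
  Q <- rbind(c(-(la + lb), lb,          la),
             c(mub,        -(mub + la), 0),
             c(mua,        0,           -(mua + lb)))
  tt <- solve(-Q, rep(1, 3))
  if (start == "all_bound") return(tt[1])
  pa <- blocks[[1]]$phi; pb <- blocks[[2]]$phi
  w <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb)   # (o,o) contributes 0
  sum(w * tt)
}

#' Linear monomer-composition predictor of block closed dwell times
#'
#' Heuristic: if block unbinding were the independent unbinding of its
#' monomers, the closed dwell time would grow linearly with block size,
#' `<t1>(b) = b * t_single`, with corrections for larger blocks. When
#' measured `(size, dwell)` data are supplied, a linear fit quantifies the
#' actual slope and intercept for comparison.
#'
#' @param block_size Block size(s) in charges, >= 1.
#' @param single_monomer_dwell Dwell time of a single isolated charge (tau).
#' @param data Optional data frame with columns `size` and `dwell`.
#' @return List: `predicted` dwell(s); with `data`, also `slope`,
#'   `intercept`, `r_squared`, `residuals`. Clearly a heuristic, not a fit
#'   of the renewal model.
#' @export
monomer_composition_estimate <- function(block_size, single_monomer_dwell,
                                         data = NULL) {
  if (any(block_size < 1)) stop("block_size must be >= 1 (no zero-size blocks)")
  out <- list(predicted = block_size * single_monomer_dwell)
  if (!is.null(data)) {
    stopifnot(all(c("size", "dwell") %in% names(data)))
    fit <- lm(dwell ~ size, data = data)
    out$slope <- unname(coef(fit)[2])
    out$intercept <- unname(coef(fit)[1])
    out$r_squared <- summary(fit)$r.squared
    out$residuals <- unname(residuals(fit))
  }
  out
}
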