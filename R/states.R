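# Dimer/unimer state classification and two-state kinetics: episode
# extraction, dwell-time distributions, tail survival curves, and the
# correlation of dwell times with sequence descriptors.

#' Analysis thresholds of the dimerization study
#'
#' Single authoritative home of the printed analysis constants: the
#' center-to-center dimer criterion (10 sigma, the location of the barrier
#' top in the free-energy profile), the monomer contact cutoff (1.8 sigma),
#' the alternative dimer criterion (> 4 inter-chain contacts), the survival
#' lower cutoff (250 tau), the dynamic contact-map window (250 tau), and the
#' block-kinetics sampling resolution (5 tau).
#'
#' @return Named list of constants.
#' @export
pa_defaults <- function() {
  list(dimer_distance = 10,
       contact_cutoff = 1.8,
       min_contacts = 4,
       survival_tc = 250,
       dynamic_window = 250,
       block_resolution = 5)
}

episodes_from_labels <- function(times, labels) {
  r <- rle(as.character(labels))
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  dt <- if (length(times) > 1) diff(times[1:2]) else NA_real_
  data.frame(state = r$values,
             t_start = times[starts],
             t_end = times[ends],
             duration = r$lengths * dt,
             n_frames = r$lengths,
             censored = seq_along(r$values) %in% c(1, length(r$values)),
             stringsAsFactors = FALSE)
}

new_pa_states <- function(times, labels, criterion) {
  structure(list(times = times,
                 labels = labels,
                 criterion = criterion,
                 episodes = episodes_from_labels(times, labels)),
            class = "pa_states")
}

#' @export
print.pa_states <- function(x, ...) {
  cat("<pa_states>", length(x$times), "frames,", nrow(x$episodes),
      "episodes, criterion:", x$criterion, "\n")
  cat("  dimer fraction:", round(mean(x$labels == "dimer"), 3), "\n")
  invisible(x)
}

#' Classify trajectory frames as dimer or unimer
#'
#' Two equivalent criteria: `distance10` labels a frame dimer when the
#' minimum-image center-to-center distance of the two chains is below
#' 10 sigma (the barrier top of the free-energy profile); `contacts4` when
#' strictly more than 4 inter-chain monomer pairs lie within 1.8 sigma.
#'
#' @param traj A two-chain `pa_traj`.
#' @param criterion `"distance10"` or `"contacts4"`.
#' @param min_frames Debounce: episodes shorter than this many frames are
#'   merged into their neighbours (default 1 = no smoothing; short-lived
#'   transients are part of the kinetics and are kept by default).
#' @return A `pa_states` with per-frame labels and the episode table.
#' @export
classify_states <- function(traj, criterion = c("distance10", "contacts4"),
                            min_frames = 1) {
  criterion <- match.arg(criterion)
  ia <- chain_index(traj, "A")
  ib <- chain_index(traj, "B")
  if (!length(ia) || !length(ib))
    stop("state classification needs a two-chain trajectory")
  defaults <- pa_defaults()
  if (criterion == "distance10") {
    lab <- ifelse(center_distance(traj) < defaults$dimer_distance,
                  "dimer", "unimer")
  } else {
    nc <- vapply(seq_len(n_frames(traj)), function(f) {
      count_contacts(traj$pos[ia, , f], traj$pos[ib, , f], traj$box_L,
                     defaults$contact_cutoff)
    }, numeric(1))
    lab <- ifelse(nc > defaults$min_contacts, "dimer", "unimer")
  }
  if (min_frames > 1) lab <- debounce_labels(lab, min_frames)
  new_pa_states(traj$times, lab, criterion)
}

count_contacts <- function(pa, pb, L, cutoff) {
  d2 <- pair_dist2(pa, pb, L)
  sum(d2 < cutoff^2)
}

pair_dist2 <- function(pa, pb, L) {
  dx <- min_image(outer(pa[, 1], pb[, 1], "-"), L)
  dy <- min_image(outer(pa[, 2], pb[, 2], "-"), L)
  dz <- min_image(outer(pa[, 3], pb[, 3], "-"), L)
  dx^2 + dy^2 + dz^2
}

debounce_labels <- function(lab, min_frames) {
  repeat {
    r <- rle(lab)
    short <- which(r$lengths < min_frames)
    short <- setdiff(short, c(1, length(r$lengths)))
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    r$values[i] <- r$values[i - 1]
    lab <- inverse.rle(r)
  }
  lab
}

#' Dwell-time distribution of one state
#'
#' Episode durations of the requested state. Episodes truncated by either
#' end of the trajectory are censored: excluded from the distribution and
#' reported in `censored_n`.
#'
#' @param series A `pa_states`.
#' @param state `"dimer"` or `"unimer"` (or any label present).
#' @param tc Maturity cutoff (tau) for the tail mean (default 250).
#' @return A `pa_dwell` list: `durations` (completed episodes), `mean_all`,
#'   `mean_tail` (episodes longer than `tc`), `censored_n`, `n`, and an
#'   `empty` flag when no completed episode exists.
#' @export
dwell_distribution <- function(series, state, tc = pa_defaults()$survival_tc) {
  stopifnot(inherits(series, "pa_states"))
  ep <- series$episodes
  keep <- ep$state == state & !ep$censored
  durations <- ep$duration[keep]
  censored_n <- sum(ep$state == state & ep$censored)
  empty <- length(durations) == 0
  structure(list(
    state = state,
    durations = durations,
    n = length(durations),
    censored_n = censored_n,
    tc = tc,
    mean_all = if (empty) NA_real_ else mean(durations),
    mean_tail = if (any(durations > tc)) mean(durations[durations > tc])
                else NA_real_,
    n_tail = sum(durations > tc),
    empty = empty
  ), class = "pa_dwell")
}

#' @export
print.pa_dwell <- function(x, ...) {
  cat("<pa_dwell>", x$state, ":", x$n, "completed episodes (",
      x$censored_n, "censored )\n")
  cat("  mean:", signif(x$mean_all, 4), " mean(>", x$tc, "):",
      signif(x$mean_tail, 4), "\n")
  invisible(x)
}

#' Tail survival curve and exponential relaxation time
#'
#' The survival probability of matured episodes,
#' \deqn{S(t) = 1 - \int_{t_c}^{t} p(t')dt' / \int_{t_c}^{\infty} p(t')dt',}
#' i.e. the population surviving beyond `t` renormalized to 1 at the lower
#' cutoff `tc` (default 250 tau). The exponential tail time `tau_r` is fitted
#' by least squares on `log S` over the window from `tc` down to `S = s_min`.
#'
#' @param x A `pa_dwell` or a numeric vector of episode durations.
#' @param tc Lower cutoff (tau).
#' @param s_min Lower end of the fit window on S (default 0.05).
#' @return A `pa_survival` list: `t`, `S`, `tau_r`, `fit_window`, `n`.
#' @export
survival_curve <- function(x, tc = pa_defaults()$survival_tc, s_min = 0.05) {
  durations <- if (inherits(x, "pa_dwell")) x$durations else as.numeric(x)
  dd <- durations[durations > tc]
  if (!length(dd)) stop("no dwell mass beyond tc = ", tc)
  tt <- c(tc, sort(unique(dd)))
  S <- vapply(tt, function(t) mean(dd > t), numeric(1))
  S[1] <- 1
  keep <- S > 0 & S >= s_min
  fit_t <- tt[keep]
  fit_S <- S[keep]
  tau_r <- NA_real_
  if (length(fit_t) >= 3) {
    fit <- lm(log(fit_S) ~ fit_t)
    slope <- coef(fit)[2]
    if (is.finite(slope) && slope < 0) tau_r <- -1 / slope
  }
  structure(list(t = tt, S = S, tau_r = unname(tau_r),
                 fit_window = range(fit_t), tc = tc, n = length(dd)),
            class = "pa_survival")
}

#' @export
print.pa_survival <- function(x, ...) {
  cat("<pa_survival> n =", x$n, " tc =", x$tc, " tau_r =",
      signif(x$tau_r, 4), "\n")
  invisible(x)
}

#' Correlate mean dwell times with the central net charge
#'
#' Pearson correlation of per-sequence mean dwell time against CNC within a
#' blockiness subgroup, with a permutation p-value. Within a subgroup of
#' equal block composition, smaller CNC is expected to stabilize dimers
#' (more negative correlation for dimer dwell times).
#'
#' @param dwell_table Data frame with columns `id` and `mean_dwell`.
#' @param descriptor_table Data frame with columns `id`, `cnc`, and
#'   optionally `subgroup` (see [describe_sequences()]).
#' @param subgroup Optional subgroup label to filter on.
#' @param n_perm Number of permutations for the p-value.
#' @param seed Optional seed for the permutation draw.
#' @return List: `r`, `p_perm`, `n`, `subgroup`, `degenerate` flag (zero
#'   variance in either variable).
#' @export
correlate_descriptors <- function(dwell_table, descriptor_table,
                                  subgroup = NULL, n_perm = 1999,
                                  seed = NULL) {
  d <- merge(dwell_table, descriptor_table, by = "id")
  if (!is.null(subgroup)) d <- d[d$subgroup == subgroup, , drop = FALSE]
  d <- d[complete.cases(d[, c("mean_dwell", "cnc")]), , drop = FALSE]
  if (nrow(d) < 3)
    stop("insufficient sequences in subgroup (n = ", nrow(d), " < 3)")
  if (sd(d$mean_dwell) == 0 || sd(d$cnc) == 0) {
    return(list(r = NA_real_, p_perm = NA_real_, n = nrow(d),
                subgroup = subgroup, degenerate = TRUE))
  }
  r <- cor(d$mean_dwell, d$cnc)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- replicate(n_perm, cor(sample(d$mean_dwell), d$cnc))
  p <- (1 + sum(abs(r_perm) >= abs(r))) / (n_perm + 1)
  list(r = r, p_perm = p, n = nrow(d), subgroup = subgroup,
       degenerate = FALSE)
}
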