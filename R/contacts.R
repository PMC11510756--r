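# Contact maps (static, dynamic S/M/E windows), tagged-block inter-chain
# contact kinetics, counterion condensation, and gyration-tensor shape
# metrics. Contacts are pair distances below 1.8 sigma (minimum image).

charged_sites_of <- function(traj, chain) {
  idx <- which(traj$species == chain & traj$charge != 0)
  if (!length(idx)) stop("chain ", chain, " has no charged sites")
  idx
}

frames_in_window <- function(traj, window, frames) {
  if (!is.null(frames)) return(frames)
  if (is.null(window)) return(seq_len(n_frames(traj)))
  which(traj$times >= window[1] & traj$times <= window[2])
}

#' Contact frequency map over charged sites
#'
#' Per-pair fraction of frames in which the two charged monomers are within
#' `cutoff`. `inter` counts pairs across the two chains (rows = chain A
#' sites, columns = chain B sites); `intra` counts pairs within one chain
#' (symmetric); `difference` is the intra-chain map over dimer frames minus
#' the intra-chain map over unimer frames (requires `series`).
#'
#' @param traj A `pa_traj`.
#' @param mode `"inter"`, `"intra"`, or `"difference"`.
#' @param window Optional time window `c(t0, t1)` (tau).
#' @param frames Optional explicit frame indices (overrides `window`).
#' @param chain Chain for intra maps (`"A"` or `"B"`).
#' @param cutoff Contact distance (sigma).
#' @param series A `pa_states`, required for `difference` mode.
#' @return A `pa_contact_map`: the frequency matrix in `[0, 1]` with site
#'   indices and site charges as attributes.
#' @export
contact_map <- function(traj, mode = c("inter", "intra", "difference"),
                        window = NULL, frames = NULL, chain = "A",
                        cutoff = pa_defaults()$contact_cutoff,
                        series = NULL) {
  mode <- match.arg(mode)
  if (mode == "difference") {
    if (is.null(series)) stop("difference mode needs a pa_states series")
    fr <- frames_in_window(traj, window, frames)
    fd <- intersect(fr, which(series$labels == "dimer"))
    fu <- intersect(fr, which(series$labels == "unimer"))
    if (!length(fd) || !length(fu))
      stop("difference map needs both dimer and unimer frames in the window")
    md <- contact_map(traj, "intra", frames = fd, chain = chain, cutoff = cutoff)
    mu <- contact_map(traj, "intra", frames = fu, chain = chain, cutoff = cutoff)
    out <- unclass(md) - unclass(mu)
    attributes(out) <- attributes(unclass(md))
    return(structure(out, mode = "difference", class = "pa_contact_map"))
  }
  fr <- frames_in_window(traj, window, frames)
  if (!length(fr)) stop("empty frame window")
  ia <- charged_sites_of(traj, if (mode == "inter") "A" else chain)
  ib <- if (mode == "inter") charged_sites_of(traj, "B") else ia
  acc <- matrix(0, length(ia), length(ib))
  for (f in fr) {
    d2 <- pair_dist2(frame_coords(traj, ia, f),
                     frame_coords(traj, ib, f), traj$box_L)
    acc <- acc + (d2 < cutoff^2)
  }
  m <- acc / length(fr)
  if (mode == "intra") diag(m) <- 0
  structure(m, sites_row = ia, sites_col = ib,
            charges_row = traj$charge[ia], charges_col = traj$charge[ib],
            mode = mode, n_frames = length(fr),
            window = if (is.null(window)) range(traj$times[fr]) else window,
            class = "pa_contact_map")
}

#' @export
print.pa_contact_map <- function(x, ...) {
  cat("<pa_contact_map>", attr(x, "mode"), dim(x)[1], "x", dim(x)[2],
      "sites,", attr(x, "n_frames"), "frames, max =",
      signif(max(x), 3), "\n")
  invisible(x)
}

#' Dynamic contact maps at the start, middle and end of dimer episodes
#'
#' For every completed dimer episode at least three windows long, computes
#' inter-chain contact maps over a window of `window_len` tau anchored
#' immediately after dimerization (S), at the episode midpoint (M), and
#' just before dissociation (E).
#'
#' @param traj A two-chain `pa_traj`.
#' @param series A `pa_states` for the same trajectory.
#' @param window_len Window length in tau (default 250).
#' @param cutoff Contact distance.
#' @return List of per-episode lists with elements `S`, `M`, `E` (contact
#'   maps) and `episode` (row of the episode table); episodes too short are
#'   skipped and counted in attribute `"n_skipped"`.
#' @export
dynamic_maps <- function(traj, series, window_len = pa_defaults()$dynamic_window,
                         cutoff = pa_defaults()$contact_cutoff) {
  ep <- series$episodes
  ep <- ep[ep$state == "dimer" & !ep$censored, , drop = FALSE]
  out <- list()
  skipped <- 0L
  for (k in seq_len(nrow(ep))) {
    if (ep$duration[k] < 3 * window_len) { skipped <- skipped + 1L; next }
    t0 <- ep$t_start[k]
    t1 <- ep$t_end[k]
    tm <- (t0 + t1) / 2
    wins <- list(S = c(t0, t0 + window_len),
                 M = c(tm - window_len / 2, tm + window_len / 2),
                 E = c(t1 - window_len, t1))
    maps <- lapply(wins, function(w)
      contact_map(traj, "inter", window = w, cutoff = cutoff))
    out[[length(out) + 1]] <- c(maps, list(episode = ep[k, ]))
  }
  attr(out, "n_skipped") <- skipped
  out
}

block_monomers <- function(traj, block) {
  chain <- block$chain
  sites <- charged_sites_of(traj, chain)
  if (!is.null(block$monomers)) {
    idx <- intersect(block$monomers, which(traj$species == chain))
    if (!length(idx)) stop("block monomers not on chain ", chain)
    return(idx)
  }
  sites[seq(block$start_site, length.out = block$size)]
}

#' Tag a charge block of a decomposition for contact analysis
#'
#' @param dec A `pa_blocks` decomposition of the chain's sequence.
#' @param which_block Row index into `dec$blocks`.
#' @param chain `"A"` or `"B"`.
#' @return A block descriptor for [block_contact_kinetics()].
#' @export
tag_block <- function(dec, which_block, chain = "A") {
  stopifnot(inherits(dec, "pa_blocks"))
  start <- cumsum(c(1, dec$blocks$size))[which_block]
  list(chain = chain, start_site = start,
       size = dec$blocks$size[which_block],
       sign = dec$blocks$sign[which_block])
}

block_bound_flags <- function(traj, block, cutoff) {
  idx <- block_monomers(traj, block)
  other <- setdiff(c("A", "B"), block$chain)
  io <- which(traj$species == other)
  if (!length(io)) stop("no partner chain for block contacts")
  vapply(seq_len(n_frames(traj)), function(f) {
    d2 <- pair_dist2(frame_coords(traj, idx, f),
                     frame_coords(traj, io, f), traj$box_L)
    any(d2 < cutoff^2)
  }, logical(1))
}

intervals_from_flags <- function(times, flags, valid) {
  # valid frames only (dimer-conditioned); intervals are censored where they
  # touch a gap or the series ends
  n <- length(flags)
  runs <- rle(valid)
  seg_end <- cumsum(runs$lengths)
  seg_start <- c(1, head(seg_end, -1) + 1)
  dt <- if (n > 1) diff(times[1:2]) else NA_real_
  out <- NULL
  for (s in which(runs$values)) {
    i0 <- seg_start[s]; i1 <- seg_end[s]
    r <- rle(flags[i0:i1])
    ends <- cumsum(r$lengths)
    starts <- c(1, head(ends, -1) + 1)
    seg <- data.frame(
      state = ifelse(r$values, "closed", "open"),
      t_start = times[i0 + starts - 1],
      t_end = times[i0 + ends - 1],
      duration = r$lengths * dt,
      censored = seq_along(r$values) %in% c(1, length(r$values)))
    out <- rbind(out, seg)
  }
  out
}

#' Inter-chain contact kinetics of a tagged charge block
#'
#' A block is "closed" (bound) in a frame when any of its monomers lies
#' within `cutoff` of any monomer of the other chain, and "open" otherwise.
#' The series is sampled on a grid of `resolution` tau and, when a state
#' series is supplied, conditioned on the dimer state: unimer frames are
#' discarded and intervals spanning a state change are censored at the
#' boundary.
#'
#' @param traj A two-chain `pa_traj`.
#' @param block Block descriptor (see [tag_block()]), or a list with
#'   `chain` and `monomers` (explicit monomer indices).
#' @param series Optional `pa_states` for dimer conditioning.
#' @param cutoff Contact distance (sigma).
#' @param resolution Sampling period (tau, default 5).
#' @return A `pa_block_series`: per-frame `bound` flags, the open/closed
#'   `intervals` table, and statistics: mean closed/open dwells (completed
#'   intervals), `bound_prob` = closed time / total conditioned time, the
#'   short-time power-law exponent of the closed dwell distribution
#'   (t < 100 tau), and the conditional mean of closed dwells > 50 tau.
#' @export
block_contact_kinetics <- function(traj, block, series = NULL,
                                   cutoff = pa_defaults()$contact_cutoff,
                                   resolution = pa_defaults()$block_resolution) {
  fdt <- frame_dt(traj)
  step <- if (is.na(fdt)) 1L else max(1L, round(resolution / fdt))
  fr <- seq(1, n_frames(traj), by = step)
  sub <- subset_frames(traj, fr)
  flags <- block_bound_flags(sub, block, cutoff)
  valid <- if (is.null(series)) rep(TRUE, length(fr))
           else series$labels[fr] == "dimer"
  iv <- intervals_from_flags(sub$times, flags, valid)
  if (is.null(iv) || !any(flags[valid])) {
    return(structure(list(block = block, times = sub$times, bound = flags,
                          valid = valid, intervals = iv,
                          bound_prob = 0, mean_closed = NA_real_,
                          mean_open = NA_real_, empty = TRUE),
                     class = "pa_block_series"))
  }
  comp <- iv[!iv$censored, , drop = FALSE]
  closed <- comp$duration[comp$state == "closed"]
  open <- comp$duration[comp$state == "open"]
  bound_prob <- sum(flags & valid) / sum(valid)
  # short-time power law p1(t) ~ t^-nu for t < 100 tau
  nu <- NA_real_
  short <- closed[closed < 100]
  if (length(short) >= 20 && length(unique(short)) >= 3) {
    h <- table(short)
    tt <- as.numeric(names(h))
    ct <- as.numeric(h)
    ok <- ct > 0 & tt > 0
    if (sum(ok) >= 3) nu <- -unname(coef(lm(log(ct[ok]) ~ log(tt[ok])))[2])
  }
  structure(list(
    block = block, times = sub$times, bound = flags, valid = valid,
    intervals = iv, resolution = step * fdt,
    mean_closed = if (length(closed)) mean(closed) else NA_real_,
    mean_open = if (length(open)) mean(open) else NA_real_,
    n_closed = length(closed), n_open = length(open),
    bound_prob = bound_prob,
    powerlaw_nu = nu,
    mean_closed_gt50 = if (any(closed > 50)) mean(closed[closed > 50])
                       else NA_real_,
    empty = FALSE
  ), class = "pa_block_series")
}

#' @export
print.pa_block_series <- function(x, ...) {
  cat("<pa_block_series> bound prob:", signif(x$bound_prob, 3),
      " mean closed:", signif(x$mean_closed, 4),
      " mean open:", signif(x$mean_open, 4), "\n")
  invisible(x)
}

#' Partner-site trace of a tagged block (sliding vs hopping)
#'
#' For every frame in which the block touches the other chain, records the
#' charged-site indices of the partner chain in contact with the block. The
#' summary jump statistic is the mean absolute change of the mean partner
#' index between consecutive bound frames: small values indicate sliding
#' along the chain, large values hopping to distant sites.
#'
#' @inheritParams block_contact_kinetics
#' @return List: `frames`, `partners` (list of index vectors along the
#'   partner chain's charged sites), `mean_partner`, `jump_stat`.
#' @export
contact_point_trace <- function(traj, block,
                                cutoff = pa_defaults()$contact_cutoff) {
  idx <- block_monomers(traj, block)
  other <- setdiff(c("A", "B"), block$chain)
  sites <- charged_sites_of(traj, other)
  partners <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    d2 <- pair_dist2(frame_coords(traj, idx, f),
                     frame_coords(traj, sites, f), traj$box_L)
    partners[[f]] <- which(apply(d2 < cutoff^2, 2, any))
  }
  bound <- lengths(partners) > 0
  mp <- rep(NA_real_, length(partners))
  mp[bound] <- vapply(partners[bound], mean, numeric(1))
  consec <- which(bound[-1] & bound[-length(bound)])
  jump <- if (length(consec)) mean(abs(mp[consec + 1] - mp[consec])) else NA_real_
  list(frames = which(bound), partners = partners, mean_partner = mp,
       jump_stat = jump)
}

#' Counterion condensation statistics
#'
#' A counterion is condensed when its minimum-image distance to the nearest
#' monomer of the relevant aggregate is below `cutoff` (1.8 sigma). With a
#' state series, dimer frames count condensation on the two-chain aggregate
#' and unimer frames count per chain separately.
#'
#' @param traj A `pa_traj` containing counterions.
#' @param cutoff Condensation distance (sigma).
#' @param series Optional `pa_states` (two-chain trajectories).
#' @return List: `per_frame` counts, `mean` (single aggregate),
#'   and with a series `mean_dimer` (per dimer) and `mean_unimer_per_chain`.
#' @export
counterion_condensation <- function(traj,
                                    cutoff = pa_defaults()$contact_cutoff,
                                    series = NULL) {
  ions <- which(traj$species == "ion")
  if (!length(ions)) stop("trajectory has no counterions")
  chains <- intersect(c("A", "B"), unique(traj$species))
  idx <- lapply(chains, function(ch) which(traj$species == ch))
  names(idx) <- chains
  count_near <- function(mono_idx, f) {
    d2 <- pair_dist2(frame_coords(traj, ions, f),
                     frame_coords(traj, mono_idx, f), traj$box_L)
    sum(apply(d2, 1, min) < cutoff^2)
  }
  nf <- n_frames(traj)
  per_chain <- vapply(seq_len(nf), function(f)
    vapply(idx, count_near, numeric(1), f = f), numeric(length(chains)))
  per_chain <- matrix(per_chain, nrow = length(chains))
  out <- list(per_frame = colSums(matrix(per_chain, nrow = length(chains))),
              mean_per_chain = rowMeans(per_chain),
              cutoff = cutoff)
  if (length(chains) == 1) {
    out$mean <- mean(per_chain[1, ])
    return(out)
  }
  both <- vapply(seq_len(nf), function(f) count_near(unlist(idx), f),
                 numeric(1))
  out$per_frame_aggregate <- both
  if (!is.null(series)) {
    dim_f <- series$labels == "dimer"
    out$mean_dimer <- if (any(dim_f)) mean(both[dim_f]) else NA_real_
    out$mean_unimer_per_chain <-
      if (any(!dim_f)) mean(per_chain[, !dim_f, drop = FALSE]) else NA_real_
  }
  out$mean <- mean(both)
  out
}

#' Gyration-tensor eigenvalues (shape metrics)
#'
#' Eigenvalues `lambda1 <= lambda2 <= lambda3` of the mass-uniform gyration
#' tensor of the selected particle set, per frame (units sigma^2; with unit
#' masses this is proportional to the inertia-shape tensor). Elongated
#' conformations show two large eigenvalues.
#'
#' @param traj A `pa_traj`.
#' @param selection `"both"` (all monomers of both chains), `"A"`, or `"B"`.
#' @param frames Optional frame subset.
#' @param series Optional `pa_states`; when given, means are reported over
#'   dimer frames as well.
#' @return A `pa_shape`: `eigenvalues` (frames x 3, ascending), `mean`,
#'   `mean_dimer` (when a series is given), and a `degenerate` flag for
#'   frames with a collinear particle set.
#' @export
gyration_eigenvalues <- function(traj, selection = c("both", "A", "B"),
                                 frames = NULL, series = NULL) {
  selection <- match.arg(selection)
  idx <- if (selection == "both") which(traj$species %in% c("A", "B"))
         else which(traj$species == selection)
  if (length(idx) < 3) stop("need at least 3 particles for a gyration tensor")
  fr <- if (is.null(frames)) seq_len(n_frames(traj)) else frames
  ev <- t(vapply(fr, function(f) {
    x <- traj$pos[idx, , f]
    x <- sweep(x, 2, colMeans(x))
    sort(eigen(crossprod(x) / nrow(x), symmetric = TRUE,
               only.values = TRUE)$values)
  }, numeric(3)))
  ev[ev < 0 & ev > -1e-12] <- 0
  degenerate <- ev[, 2] < 1e-10
  out <- list(eigenvalues = ev, frames = fr, selection = selection,
              mean = colMeans(ev), degenerate = degenerate)
  if (!is.null(series)) {
    dimf <- series$labels[fr] == "dimer"
    out$mean_dimer <- if (any(dimf)) colMeans(ev[dimf, , drop = FALSE])
                      else rep(NA_real_, 3)
  }
  structure(out, class = "pa_shape")
}

#' @export
print.pa_shape <- function(x, ...) {
  cat("<pa_shape>", length(x$frames), "frames, mean eigenvalues:",
      paste(signif(x$mean, 4), collapse = " <= "), "\n")
  invisible(x)
}
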