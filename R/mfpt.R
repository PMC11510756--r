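# Radial free-energy profile from center-to-center distance statistics and
# mean first passage times from the spherically symmetric Smoluchowski
# (Fokker-Planck) description, plus the qualitative barrier-flux estimate.

polyval_r <- function(coef, r) {
  v <- 0
  for (i in rev(seq_along(coef))) v <- v * r + coef[i]
  v
}

polyder_coef <- function(coef) {
  n <- length(coef)
  if (n < 2) return(0)
  coef[-1] * seq_len(n - 1)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

cum_trapz <- function(x, y) {
  c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
}

locate_extrema <- function(coef, range, n_grid = 2000) {
  r <- seq(range[1], range[2], length.out = n_grid)
  v <- polyval_r(coef, r)
  dv <- diff(v)
  s <- sign(dv)
  idx <- which(s[-1] != s[-length(s)] & s[-1] != 0) + 1
  mins <- idx[dv[idx - 1] < 0 & dv[idx] > 0]
  maxs <- idx[dv[idx - 1] > 0 & dv[idx] < 0]
  # exclude extrema hugging the fit-range ends (polynomial edge wiggles)
  inner <- function(i) i > n_grid * 0.02 & i < n_grid * 0.98
  list(r = r, v = v, minima = r[mins[inner(mins)]],
       maxima = r[maxs[inner(maxs)]])
}

profile_geometry <- function(coef, range, min_prominence = 0.2) {
  ex <- locate_extrema(coef, range)
  if (length(ex$minima) < 2 || !length(ex$maxima))
    stop("no barrier found: potential does not show two minima with a ",
         "maximum between them over the fit range")
  r2 <- min(ex$minima)                       # dimer (near) minimum
  r1 <- max(ex$minima)                       # unimer (far) minimum
  between <- ex$maxima[ex$maxima > r2 & ex$maxima < r1]
  if (!length(between)) stop("no barrier found between the two minima")
  vb <- polyval_r(coef, between)
  r_star <- between[which.max(vb)]
  v2 <- polyval_r(coef, r2)
  v1 <- polyval_r(coef, r1)
  v_star <- polyval_r(coef, r_star)
  # fit wiggles on near-flat data must not masquerade as a barrier
  if (v_star - max(v1, v2) < min_prominence)
    stop("no barrier found: largest interior maximum rises less than ",
         min_prominence, " kT above the higher minimum")
  rg <- ex$r
  vg <- ex$v
  near_top <- vg >= v_star - 1
  grp <- cumsum(c(1, diff(near_top) != 0))
  top_grp <- grp[which.min(abs(rg - r_star))]
  l_star <- diff(range(rg[grp == top_grp & near_top]))
  sink_vol <- function(rmin, vmin) {
    inb <- vg <= vmin + 1
    g <- cumsum(c(1, diff(inb) != 0))
    sel <- g == g[which.min(abs(rg - rmin))] & inb
    trapz(rg[sel], 4 * pi * rg[sel]^2)
  }
  list(r1 = r1, r2 = r2, r_star = r_star,
       V_star_dissociation = v_star - v2,
       V_star_dimerization = v_star - v1,
       L_star = l_star,
       sink_volume_dimer = sink_vol(r2, v2),
       sink_volume_unimer = sink_vol(r1, v1))
}

#' Build a potential profile from polynomial coefficients
#'
#' Constructs the same `pa_profile` object that
#' [potential_from_trajectory()] extracts from data, from a known radial
#' potential `V(r) = sum coef[i] r^(i-1)`. Used for synthetic fixtures and
#' oracle comparisons.
#'
#' @param coef Polynomial coefficients, constant term first.
#' @param range Radial fit range `c(rmin, rmax)` (sigma).
#' @return A `pa_profile`.
#' @export
profile_from_polynomial <- function(coef, range) {
  geom <- profile_geometry(coef, range)
  shift <- polyval_r(coef, geom$r2)
  coef[1] <- coef[1] - shift
  r <- seq(range[1], range[2], length.out = 400)
  structure(c(list(r = r, P = NULL, V = polyval_r(coef, r),
                   V_fit = polyval_r(coef, r), coef = coef,
                   degree = length(coef) - 1, range = range,
                   source = "polynomial"),
              profile_geometry(coef, range)),
            class = "pa_profile")
}

#' Radial free-energy profile from center-to-center distance samples
#'
#' Histograms the samples into shells of width `bin_width`, converts the
#' shell probability P(r) to a potential of mean force
#' \deqn{V(r) = -\log P(r) + 2 \log(r/\sigma),}
#' where the `2 log r` term removes the entropy of the shell volume, and
#' fits a polynomial of degree 6-8 (chosen by cross-validated residual).
#' The additive constant is fixed by `V(r2) = 0` at the dimer minimum.
#' Minima (dimer `r2`, unimer `r1`), the barrier top `r_star`, barrier
#' heights from each minimum, the 1-kT barrier width `L_star`, and the 1-kT
#' sink shell volumes are located on the fitted polynomial.
#'
#' @param r Numeric vector of center-to-center distances (sigma); at least
#'   a few thousand samples spanning both basins.
#' @param bin_width Histogram bin width (sigma).
#' @param degrees Candidate polynomial degrees.
#' @param cv_folds Folds for the degree selection.
#' @return A `pa_profile`: binned `r`, `P`, empirical `V`, fitted `V_fit`
#'   and coefficients, and the basin/barrier geometry.
#' @export
potential_from_trajectory <- function(r, bin_width = 0.25, degrees = 6:8,
                                      cv_folds = 5) {
  r <- r[is.finite(r)]
  if (length(r) < 1000) stop("need at least 1000 distance samples")
  breaks <- seq(floor(min(r) / bin_width) * bin_width,
                ceiling(max(r) / bin_width) * bin_width, by = bin_width)
  h <- hist(r, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  mids <- h$mids[keep]
  P <- h$counts[keep] / sum(h$counts)
  V <- -log(P) + 2 * log(mids)
  # degree selection by k-fold cross-validated residual
  folds <- rep_len(seq_len(cv_folds), length(mids))
  cv_err <- vapply(degrees, function(d) {
    errs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      if (sum(tr) <= d + 1) return(NA_real_)
      fit <- lm(V[tr] ~ poly(mids[tr], d, raw = TRUE))
      pred <- polyval_r(c(coef(fit)), mids[!tr])
      mean((V[!tr] - pred)^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))
  degree <- degrees[which.min(cv_err)]
  fit <- lm(V ~ poly(mids, degree, raw = TRUE))
  coefs <- unname(c(coef(fit)))
  rng <- range(mids)
  geom <- profile_geometry(coefs, rng)
  shift <- polyval_r(coefs, geom$r2)
  coefs[1] <- coefs[1] - shift
  structure(c(list(r = mids, P = P, V = V - shift,
                   V_fit = polyval_r(coefs, mids), coef = coefs,
                   degree = degree, cv_error = cv_err, range = rng,
                   n_samples = length(r), source = "histogram"),
              profile_geometry(coefs, rng)),
            class = "pa_profile")
}

#' @export
print.pa_profile <- function(x, ...) {
  cat("<pa_profile> degree", x$degree, " r2 =", signif(x$r2, 4),
      " r* =", signif(x$r_star, 4), " r1 =", signif(x$r1, 4), "\n")
  cat("  barriers: dissociation", signif(x$V_star_dissociation, 3),
      "kT, dimerization", signif(x$V_star_dimerization, 3), "kT\n")
  invisible(x)
}

#' Mean first passage time of the radial Fokker-Planck model
#'
#' For diffusion on `r > 0` with stationary weight `r^2 exp(-V(r))`,
#' the mean first passage time from the dimer minimum `r2` to an absorbing
#' target at the unimer minimum `r1` (dissociation; reflecting inner wall)
#' is the double quadrature
#' \deqn{T = \frac{1}{D}\int_{r_2}^{r_1} dy\, e^{V(y)} y^{-2}
#'   \int_{r_{in}}^{y} dz\, z^2 e^{-V(z)},}
#' and mirrored for dimerization (start `r1`, absorb at `r2`, reflecting
#' outer wall).
#'
#' @param profile A `pa_profile`.
#' @param D Center-to-center diffusion coefficient (sigma^2/tau); see
#'   [diffusion_coefficient()].
#' @param direction `"dissociation"` or `"dimerization"`.
#' @param target `"minimum"` absorbs at the destination minimum;
#'   `"basin_edge"` absorbs on entering the destination basin (at the
#'   barrier top).
#' @param inner Reflecting inner radius (default: smallest sampled r).
#' @param outer Reflecting outer radius (default: largest sampled r).
#' @param n_grid Quadrature grid size; the result reports a quadrature
#'   error estimate from halving the grid.
#' @return List: `time` (tau), `direction`, `quadrature_error`, boundaries.
#' @export
mfpt_radial <- function(profile, D, direction = c("dissociation", "dimerization"),
                        target = c("minimum", "basin_edge"),
                        inner = NULL, outer = NULL, n_grid = 4000) {
  direction <- match.arg(direction)
  target <- match.arg(target)
  stopifnot(inherits(profile, "pa_profile"), D > 0)
  if (is.null(inner)) inner <- profile$range[1]
  if (is.null(outer)) outer <- profile$range[2]
  if (inner <= 0) stop("inner reflecting radius must be positive")
  a <- if (target == "minimum") {
    if (direction == "dissociation") profile$r1 else profile$r2
  } else profile$r_star
  Vf <- function(r) polyval_r(profile$coef, r)
  compute <- function(ng) {
    if (direction == "dissociation") {
      z <- seq(inner, a, length.out = ng)
      w <- cum_trapz(z, z^2 * exp(-Vf(z)))          # inner integral at z
      sel <- z >= profile$r2
      y <- z[sel]
      integrand <- exp(Vf(y)) / y^2 * w[sel]
      trapz(y, integrand) / D
    } else {
      z <- seq(a, outer, length.out = ng)
      wtot <- cum_trapz(z, z^2 * exp(-Vf(z)))
      w <- wtot[length(wtot)] - wtot                # integral y..outer
      sel <- z <= profile$r1
      y <- z[sel]
      integrand <- exp(Vf(y)) / y^2 * w[sel]
      trapz(y, integrand) / D
    }
  }
  t_full <- compute(n_grid)
  t_half <- compute(n_grid %/% 2)
  if (!is.finite(t_full)) stop("non-integrable potential at the boundary")
  list(time = t_full, direction = direction, target = target,
       D = D, inner = inner, outer = outer,
       quadrature_error = abs(t_full - t_half))
}

#' Kramers-style barrier-flux escape time
#'
#' The qualitative estimate of the escape time over the barrier: the system
#' thermalizes in the starting sink over the shell volume where the free
#' energy is within 1 kT of the minimum, and the flux through the shell at
#' the barrier top is `D * 4 pi r*^2 (exp(-V*)/V_sink)/L*`, with `L*` the
#' barrier width 1 kT below the top. The escape time is the inverse flux.
#' This gives the right order of magnitude for dissociation; for
#' dimerization the barrier is low and the estimate is flagged invalid.
#'
#' @inheritParams mfpt_radial
#' @return List: `time`, `V_star`, `L_star`, `sink_volume`, `valid`.
#' @export
kramers_flux_estimate <- function(profile, D,
                                  direction = c("dissociation", "dimerization")) {
  direction <- match.arg(direction)
  stopifnot(inherits(profile, "pa_profile"))
  v_star <- if (direction == "dissociation") profile$V_star_dissociation
            else profile$V_star_dimerization
  sink <- if (direction == "dissociation") profile$sink_volume_dimer
          else profile$sink_volume_unimer
  valid <- v_star >= 1
  if (!valid)
    warning("barrier below 1 kT: the flux estimate gives the correct order ",
            "of magnitude for dissociation but not for shallow barriers")
  flux <- D * 4 * pi * profile$r_star^2 * exp(-v_star) / sink / profile$L_star
  list(time = 1 / flux, V_star = v_star, L_star = profile$L_star,
       sink_volume = sink, r_star = profile$r_star, valid = valid)
}

#' Center-to-center diffusion coefficient
#'
#' The diffusion constant of the center-to-center distance is twice the
#' center-of-mass diffusion constant of one unimer. In free-draining mode
#' this is `2 kT / (N zeta)`; in measured mode the center-of-mass mean
#' squared displacement of a single-chain trajectory is fitted over a lag
#' window and `D = 2 * slope/6`.
#'
#' @param traj Optional single-chain `pa_traj` (measured mode); or supply
#'   `com` directly.
#' @param com Optional frames x 3 matrix of center positions with attribute
#'   times taken from `times`.
#' @param times Frame times for `com`.
#' @param n_monomers Chain length N (free-draining mode; taken from `traj`
#'   when present).
#' @param zeta Friction per bead.
#' @param kT Thermal energy.
#' @param mode `"free_draining"` or `"measured"`.
#' @param fit_frac Lag window for the MSD fit, as fractions of the maximum
#'   lag.
#' @return Diffusion coefficient `D` (sigma^2/tau) with attributes
#'   describing the fit in measured mode.
#' @export
diffusion_coefficient <- function(traj = NULL, com = NULL, times = NULL,
                                  n_monomers = NULL, zeta = 1, kT = 1,
                                  mode = c("free_draining", "measured"),
                                  fit_frac = c(0.05, 0.4)) {
  mode <- match.arg(mode)
  if (mode == "free_draining") {
    if (is.null(n_monomers)) {
      if (is.null(traj)) stop("free-draining mode needs n_monomers or a trajectory")
      n_monomers <- sum(traj$species == "A")
    }
    return(2 * kT / (n_monomers * zeta))
  }
  if (is.null(com)) {
    if (is.null(traj)) stop("measured mode needs a trajectory or com matrix")
    ia <- chain_index(traj, "A")
    com <- t(apply(traj$pos[ia, , , drop = FALSE], c(2, 3), mean))
    times <- traj$times
  }
  nf <- nrow(com)
  if (nf < 20) stop("need at least 20 frames for an MSD fit")
  dt <- diff(times[1:2])
  lags <- unique(round(seq(max(1, fit_frac[1] * nf), fit_frac[2] * nf,
                           length.out = 30)))
  msd <- vapply(lags, function(l) {
    d <- com[(1 + l):nf, , drop = FALSE] - com[1:(nf - l), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  fit <- lm(msd ~ I(lags * dt))
  slope <- unname(coef(fit)[2])
  if (slope <= 0) stop("MSD fit produced a non-positive slope")
  if (max(lags) * dt < 10 * dt)
    warning("MSD window is short; D estimate may be biased")
  structure(2 * slope / 6, slope = slope, lags = lags * dt, msd = msd)
}
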