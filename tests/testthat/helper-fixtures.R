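# Shared helpers: constructing sequences from explicit charged-site signs and
# small hand-built systems/trajectories for exact geometric tests.

seq_from_signs <- function(signs, length = 100) {
  pos <- charged_positions(length)
  stopifnot(base::length(signs) == base::length(pos))
  ch <- rep("0", length)
  ch[pos] <- ifelse(signs > 0, "+", "-")
  parse_sequence(paste(ch, collapse = ""))
}

# minimal pa_system for force/energy tests
make_system <- function(pos, charge, species, bonds = matrix(integer(0), 0, 2),
                        box_L = 30) {
  structure(list(pos = pos, vel = matrix(0, nrow(pos), 3), charge = charge,
                 species = species, bonds = bonds, box_L = box_L),
            class = "pa_system")
}

# minimal pa_traj from a list of coordinate matrices
make_traj <- function(frames, charge, species, times = seq_along(frames) - 1,
                      box_L = Inf, bonds = matrix(integer(0), 0, 2)) {
  pos <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  sys <- list(charge = charge, species = species, bonds = bonds, box_L = box_L)
  padimer:::new_pa_traj(pos, times, sys, params = NULL)
}

# random 10-particle cluster (two short bonded chains + two counterions),
# with all pair distances kept away from the interaction cutoffs so energy
# finite differences are clean
random_test_system <- function(box_L = 30) {
  rc_set <- c(2.5, 2^(1 / 6))
  repeat {
    walk <- function(n, start) {
      p <- matrix(0, n, 3)
      p[1, ] <- start
      for (i in seq_len(n)[-1]) {
        u <- rnorm(3)
        p[i, ] <- p[i - 1, ] + 1.05 * u / sqrt(sum(u^2))
      }
      p
    }
    pos <- rbind(walk(5, c(5, 5, 5)), walk(3, c(7.5, 6, 5)),
                 c(6, 7.2, 5.4) + runif(3, -0.5, 0.5),
                 c(4.5, 3.5, 5.2) + runif(3, -0.5, 0.5))
    d <- as.matrix(dist(pos))
    diag(d) <- Inf
    if (min(d) < 0.95) next
    if (any(abs(outer(as.vector(d), rc_set, "-")) < 0.02)) next
    bonds <- rbind(cbind(1:4, 2:5), cbind(6:7, 7:8))
    bl <- d[bonds]
    if (any(bl >= 1.4)) next
    break
  }
  make_system(pos,
              charge = c(1, -1, 0, 1, 0, -1, 1, 0, -1, -1),
              species = c(rep("A", 5), rep("B", 3), "ion", "ion"),
              bonds = bonds, box_L = box_L)
}

# deterministic Q=8 site signs: head majority run 3, tail majority run 2
signs_head3_tail2 <- c(1, 1, 1, -1, rep(c(1, -1), 11), rep(1, 5), -1, 1, 1)
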