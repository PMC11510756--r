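# End-to-end pipeline: sequence generation -> dynamics (or fixtures) ->
# state kinetics -> contacts -> free-energy profile -> MFPT, with per-stage
# checkpoints and a manifest. Analysis thresholds live in pa_defaults();
# force-field constants in forcefield_params().

#' Pipeline configuration
#'
#' Collects every knob of a run in one validated list. `mode = "fixture"`
#' drives the analysis stages from synthetic fixtures only (no simulator
#' call); `mode = "simulation"` runs the two-chain Langevin dynamics.
#'
#' @param mode `"fixture"` or `"simulation"`.
#' @param seed Integer master seed.
#' @param out_dir Checkpoint directory.
#' @param params A `pa_forcefield`.
#' @param target_q Ensemble net charge.
#' @param pool_size Sequence pool for the Q-ensemble draw.
#' @param t_total,dt,stride_t,burn_in Simulation settings (tau).
#' @param fixture Fixture settings: `mean_dimer`, `mean_unimer`,
#'   `fixture_dt`, `walk_t`, `barrier`.
#' @param thresholds Analysis thresholds (defaults [pa_defaults()]).
#' @return A validated `pa_config` list.
#' @export
pipeline_config <- function(mode = c("fixture", "simulation"), seed = 1,
                            out_dir = tempfile("parun"),
                            params = forcefield_params(), target_q = 8,
                            pool_size = 2000, t_total = 200, dt = 0.005,
                            stride_t = 1, burn_in = 20,
                            fixture = list(mean_dimer = 4.7e4,
                                           mean_unimer = 1.8e4,
                                           fixture_dt = 25,
                                           walk_t = 2e5, barrier = 4),
                            thresholds = pa_defaults()) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, seed = seed, out_dir = out_dir, params = params,
              target_q = target_q, pool_size = pool_size, t_total = t_total,
              dt = dt, stride_t = stride_t, burn_in = burn_in,
              fixture = fixture, thresholds = thresholds)
  required <- c("mode", "seed", "out_dir", "params", "target_q",
                "pool_size", "t_total", "dt", "stride_t", "burn_in",
                "fixture", "thresholds")
  missing <- required[vapply(cfg[required], is.null, logical(1))]
  if (length(missing))
    stop("pipeline config is missing required field(s): ",
         paste(missing, collapse = ", "))
  for (f in c("mean_dimer", "mean_unimer", "fixture_dt", "walk_t", "barrier"))
    if (is.null(cfg$fixture[[f]]))
      stop("pipeline config is missing required field: fixture$", f)
  structure(cfg, class = "pa_config")
}

stage_checkpoint <- function(out_dir, name, resume, compute) {
  path <- file.path(out_dir, paste0(name, ".rds"))
  if (resume && file.exists(path)) return(readRDS(path))
  value <- compute()
  saveRDS(value, path)
  value
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, checkpointing each result under
#' `config$out_dir` so an interrupted run resumes from the last completed
#' stage. A manifest records the seed, stage file hashes and package
#' version.
#'
#' @param config A `pa_config` (see [pipeline_config()]).
#' @param resume Reuse existing stage checkpoints.
#' @return List of stage results plus `manifest`.
#' @export
run_pipeline <- function(config, resume = TRUE) {
  stopifnot(inherits(config, "pa_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- sample.int(2^31 - 1, 8)
  out <- list()

  out$sequences <- stage_checkpoint(config$out_dir, "01_sequences", resume, function() {
    seqs <- select_q_ensemble(config$pool_size, config$target_q,
                              seed = stage_seeds[1], max_keep = 50)
    list(seqs = seqs, table = describe_sequences(seqs))
  })

  if (config$mode == "simulation") {
    out$trajectory <- stage_checkpoint(config$out_dir, "02_trajectory", resume, function() {
      run_two_chain(out$sequences$seqs[[1]], config$params,
                    t_total = config$t_total, dt = config$dt,
                    stride_t = config$stride_t, seed = stage_seeds[2],
                    burn_in = config$burn_in)
    })
    out$states <- stage_checkpoint(config$out_dir, "03_states", resume, function() {
      classify_states(out$trajectory, "distance10")
    })
    out$contacts <- stage_checkpoint(config$out_dir, "04_contacts", resume, function() {
      list(inter = contact_map(out$trajectory, "inter"),
           condensation = counterion_condensation(out$trajectory,
                                                  series = out$states),
           shape = gyration_eigenvalues(out$trajectory, series = out$states))
    })
    r_samples <- center_distance(out$trajectory)
  } else {
    out$states <- stage_checkpoint(config$out_dir, "03_states", resume, function() {
      gen_semi_markov_states(config$fixture$mean_dimer,
                             config$fixture$mean_unimer,
                             t_total = 400 * (config$fixture$mean_dimer +
                                              config$fixture$mean_unimer),
                             dt = config$fixture$fixture_dt,
                             seed = stage_seeds[2])
    })
    r_samples <- NULL
  }

  out$kinetics <- stage_checkpoint(config$out_dir, "05_kinetics", resume, function() {
    dw <- dwell_distribution(out$states, "dimer",
                             tc = config$thresholds$survival_tc)
    surv <- if (dw$n_tail >= 3)
      survival_curve(dw, tc = config$thresholds$survival_tc) else NULL
    list(dwell = dw, survival = surv)
  })

  out$profile <- stage_checkpoint(config$out_dir, "06_profile", resume, function() {
    if (is.null(r_samples) || length(r_samples) < 1e4) {
      coef <- double_well_poly(barrier = config$fixture$barrier)
      r <- gen_radial_double_well_walk(coef, D = 1,
                                       t_total = config$fixture$walk_t,
                                       dt = 0.01, r0 = 5, lo = 2, hi = 16,
                                       stride = 5, seed = stage_seeds[3])
      potential_from_trajectory(r)
    } else {
      potential_from_trajectory(r_samples)
    }
  })

  out$mfpt <- stage_checkpoint(config$out_dir, "07_mfpt", resume, function() {
    D <- diffusion_coefficient(n_monomers = 100, zeta = config$params$zeta,
                               kT = config$params$kT)
    list(D = D,
         dissociation = mfpt_radial(out$profile, D, "dissociation"),
         dimerization = mfpt_radial(out$profile, D, "dimerization"),
         flux = kramers_flux_estimate(out$profile, D))
  })

  files <- list.files(config$out_dir, pattern = "^[0-9].*\\.rds$",
                      full.names = TRUE)
  out$manifest <- list(seed = config$seed, mode = config$mode,
                       stage_seeds = stage_seeds,
                       package_version = as.character(utils::packageVersion("padimer")),
                       hashes = tools::md5sum(files))
  saveRDS(out$manifest, file.path(config$out_dir, "manifest.rds"))
  out
}
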