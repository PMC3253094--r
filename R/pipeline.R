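#' Folding-run configuration
#'
#' Collects every tunable of the iterative CG-optimisation / refinement
#' loop. Defaults are the package's standard toy-mode settings: a
#' dimensionless CG stage (gamma, k_bond, lambda all 1; epsilon 0.04),
#' contact cutoffs 7 (weight-matrix Laplacian) and 6.5 with sequence
#' separation > 2 (progress metric), 50 recorded frames per CG trajectory,
#' and at most 200 folding steps.
#'
#' @param cutoff_q contact cutoff feeding the weight matrix Q (default 7).
#' @param cutoff_contacts strict cutoff of the native-like contact metric
#'   (default 6.5).
#' @param epsilon positive-definite ridge of Q (default 0.04).
#' @param lambda control (entropy-loss) penalty (default 1).
#' @param gamma friction constant (default 1).
#' @param k_bond covalent spring constant (default 1).
#' @param samples_per_traj frames recorded per CG optimal trajectory
#'   (default 50).
#' @param max_steps maximum folding steps (default 200).
#' @param converge_rmsd stop once the refined conformation's RMSD to native
#'   falls below this (default 0.5, toy-mode units; use ~1.5 for Angstrom
#'   runs).
#' @param schedule a [schedule_config()].
#' @param backend `"mock"` (built-in refiner; self-contained) or
#'   `"export"` (write targeted-MD inputs and stop for an external engine).
#' @param attain_fraction,noise_sigma mock-refiner parameters (defaults
#'   0.6 and 0.05).
#' @param energy_jitter_sd standard deviation of the seeded jitter added to
#'   the mock pseudo-energy column (default 0.1).
#' @param seed base seed; every stochastic draw in the run derives from it.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(cutoff_q = 7, cutoff_contacts = 6.5,
                            epsilon = 0.04, lambda = 1, gamma = 1,
                            k_bond = 1, samples_per_traj = 50L,
                            max_steps = 200L, converge_rmsd = 0.5,
                            schedule = schedule_config(),
                            backend = c("mock", "export"),
                            attain_fraction = 0.6, noise_sigma = 0.05,
                            energy_jitter_sd = 0.1, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(cutoff_q > 0, cutoff_contacts > 0, epsilon > 0, lambda > 0,
            gamma > 0, k_bond > 0, samples_per_traj >= 1L, max_steps >= 1L,
            converge_rmsd > 0, inherits(schedule, "schedule_config"),
            attain_fraction > 0, attain_fraction <= 1, noise_sigma >= 0,
            energy_jitter_sd >= 0)
  if (schedule$max_index != samples_per_traj)
    stop("schedule max_index (", schedule$max_index,
         ") must equal samples_per_traj (", samples_per_traj, ")")
  structure(list(cutoff_q = cutoff_q, cutoff_contacts = cutoff_contacts,
                 epsilon = epsilon, lambda = lambda, gamma = gamma,
                 k_bond = k_bond,
                 samples_per_traj = as.integer(samples_per_traj),
                 max_steps = as.integer(max_steps),
                 converge_rmsd = converge_rmsd, schedule = schedule,
                 backend = backend, attain_fraction = attain_fraction,
                 noise_sigma = noise_sigma,
                 energy_jitter_sd = energy_jitter_sd,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# deterministic per-step seeds derived from the base seed; kept well below
# 2^31 for any step <= max_steps
step_seed <- function(seed, step, offset = 0L) seed + 1000L * step + offset

record_row <- function(step, target_frame, refined, native, sol, cfg) {
  dR <- refined$coords - native$coords
  energy <- harmonic_potential(sol, dR)
  if (cfg$energy_jitter_sd > 0)
    energy <- energy + with_seed(step_seed(cfg$seed, step, 501L),
                                 stats::rnorm(1L, sd = cfg$energy_jitter_sd))
  data.frame(step = step, target_frame = target_frame,
             rmsd_to_native = rmsd_ca(refined, native),
             rg = radius_of_gyration(refined),
             n_contacts = count_native_like_contacts(
               refined, cutoff = cfg$cutoff_contacts),
             n_contacts_q = NA_real_, energy = energy)
}

#' Run the iterative CG-optimisation / refinement folding loop
#'
#' One folding step: (1) superpose the current conformation onto the native
#' frame and rebuild the weight matrix Q from the CURRENT conformation's
#' contacts -- so nonnative contacts enter the CG potential while they
#' persist; (2) solve the LQR with deviations taken from the FINAL native
#' structure; (3) propagate the closed loop and record
#' `samples_per_traj` frames; (4) select the target frame per the schedule;
#' (5) refine toward that target via the backend; (6) record metrics. The
#' loop stops when the RMSD to native drops below `converge_rmsd`, or at
#' `max_steps`. Deterministic given `cfg$seed` with the mock backend.
#'
#' With `backend = "export"` the step's targeted-MD inputs are written to
#' `outdir/step_NNN/` together with a checkpoint, and the run returns so an
#' external engine can refine; continue with [resume_folding()] once the
#' refined structure is available.
#'
#' @param initial starting conformation, a [cg_structure()].
#' @param native native (final) conformation, same bead count.
#' @param cfg a [pipeline_config()].
#' @param outdir optional directory for incremental per-step output (TSV
#'   metrics, trajectory PDB, checkpoints). Required for `"export"`.
#' @param start_step first step number (used by [resume_folding()]).
#' @param prior_records records of already-completed steps (resume only).
#' @return a `folding_trajectory`: list with `records` (data frame: step,
#'   target_frame, rmsd_to_native, rg, n_contacts, n_contacts_q, energy),
#'   `structures` (refined `cg_structure` per step), `converged`,
#'   `final_rmsd`, `native`, `config`.
#' @export
run_folding <- function(initial, native, cfg = pipeline_config(),
                        outdir = NULL, start_step = 1L,
                        prior_records = NULL) {
  stopifnot_cg(initial); stopifnot_cg(native)
  n <- n_beads(initial)
  if (n != n_beads(native))
    stop("residue-count mismatch: initial ", n, ", native ", n_beads(native))
  if (!inherits(cfg, "pipeline_config")) stop("cfg must be a pipeline_config")
  if (cfg$backend == "export" && is.null(outdir))
    stop("export backend needs an outdir")
  if (!is.null(outdir) && !dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE))
    stop("cannot create outdir: ", outdir)

  sys <- build_system(n, gamma = cfg$gamma, k_bond = cfg$k_bond)
  records <- if (is.null(prior_records)) list() else list(prior_records)
  structures <- list()
  current <- initial
  converged <- FALSE
  tsv <- if (!is.null(outdir)) file.path(outdir, "metrics.tsv") else NULL

  # already at the native state: record the initial conformation and stop
  if (rmsd_ca(current, native) < cfg$converge_rmsd) {
    qm <- build_Q(current, cutoff = cfg$cutoff_q, epsilon = cfg$epsilon)
    sol <- solve_lqr(sys, qm, lam = cfg$lambda)
    fitted <- superpose(current, native)$structure
    row <- record_row(start_step, NA_integer_, fitted, native, sol, cfg)
    row$n_contacts_q <- qm$n_contacts
    return(structure(list(records = row, structures = list(fitted),
                          converged = TRUE, final_rmsd = row$rmsd_to_native,
                          native = native, config = cfg),
                     class = "folding_trajectory"))
  }

  for (step in seq.int(start_step, cfg$max_steps)) {
    current <- superpose(current, native)$structure
    qm <- build_Q(current, cutoff = cfg$cutoff_q, epsilon = cfg$epsilon)
    sol <- solve_lqr(sys, qm, lam = cfg$lambda)
    traj <- propagate_closed_loop(sys, sol, current$coords - native$coords,
                                  samples = cfg$samples_per_traj,
                                  native = native)
    j <- select_target_frame(step, traj, current, cfg$schedule)
    target <- traj$absolute_frames[[j]]

    if (cfg$backend == "export") {
      stepdir <- file.path(outdir, sprintf("step_%03d", step))
      spec <- tmd_bias_spec(native, target_rho = rmsd_ca(target, native))
      export_namd_tmd(current, target, spec, outdir = stepdir)
      write_trajectory(list(current), file.path(stepdir, "checkpoint.pdb"))
      writeLines(c(sprintf("step: %d", step),
                   sprintf("seed: %d", cfg$seed),
                   "status: awaiting refined.pdb"),
                 file.path(stepdir, "checkpoint_state.txt"))
      rec_df <- if (length(records)) do.call(rbind, records) else
        data.frame()
      return(structure(list(records = rec_df, structures = structures,
                            converged = FALSE,
                            final_rmsd = rmsd_ca(current, native),
                            native = native, config = cfg,
                            awaiting = stepdir),
                       class = "folding_trajectory"))
    }

    res <- mock_refine(current, target,
                       attain_fraction = cfg$attain_fraction,
                       noise_sigma = cfg$noise_sigma,
                       seed = step_seed(cfg$seed, step))
    refined <- res$refined
    row <- record_row(step, j, refined, native, sol, cfg)
    row$n_contacts_q <- qm$n_contacts
    records[[length(records) + 1L]] <- row
    structures[[length(structures) + 1L]] <- refined
    if (!is.null(tsv))
      utils::write.table(row, tsv, sep = "\t", row.names = FALSE,
                         col.names = !file.exists(tsv), append = file.exists(tsv),
                         quote = FALSE)
    current <- refined
    if (row$rmsd_to_native < cfg$converge_rmsd) { converged <- TRUE; break }
  }

  rec_df <- do.call(rbind, records)
  rownames(rec_df) <- NULL
  out <- structure(list(records = rec_df, structures = structures,
                        converged = converged,
                        final_rmsd = rec_df$rmsd_to_native[nrow(rec_df)],
                        native = native, config = cfg),
                   class = "folding_trajectory")
  if (!is.null(outdir))
    write_trajectory(structures, file.path(outdir, "folding_trajectory.pdb"))
  out
}

#' Resume a folding run from an externally refined structure
#'
#' Continues an export-mode run: reads the refined conformation returned by
#' the external engine for the awaited step, then carries on from the next
#' step. Because every per-step stochastic draw derives from
#' `cfg$seed + step`, the records produced after resumption are identical
#' to an uninterrupted run with the same configuration.
#'
#' @param refined the externally refined conformation: a [cg_structure()],
#'   or a path to a PDB file (the C-alpha trace is extracted).
#' @param step the folding step the refined structure completes.
#' @param native native conformation, as in [run_folding()].
#' @param cfg a [pipeline_config()]; usually with `backend = "mock"` to
#'   finish self-contained, or `"export"` to produce the next step's inputs.
#' @param outdir optional output directory, as in [run_folding()].
#' @return a `folding_trajectory` covering steps `step + 1` onward.
#' @export
resume_folding <- function(refined, step, native, cfg = pipeline_config(),
                           outdir = NULL) {
  if (is.character(refined))
    refined <- extract_calpha(read_pdb(refined))
  stopifnot_cg(refined)
  run_folding(refined, native, cfg, outdir = outdir,
              start_step = as.integer(step) + 1L)
}

#' @export
print.folding_trajectory <- function(x, ...) {
  cat("folding_trajectory: ", nrow(x$records), " step(s), ",
      if (x$converged) "converged" else "not converged",
      ", final RMSD to native ", format(x$final_rmsd, digits = 4), "\n",
      sep = "")
  invisible(x)
}
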