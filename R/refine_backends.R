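#' Targeted-MD bias specification
#'
#' Parameters of the RMSD-restraint bias used by targeted molecular
#' dynamics: the reaction coordinate is rho, the RMSD of the current
#' conformation from the native reference, and the bias pulls rho toward
#' `target_rho`, the RMSD of the target conformation from that same
#' reference.
#'
#' @param native_ref native reference conformation, a [cg_structure()].
#' @param target_rho target value of rho (length units).
#' @param k_spring elastic spring constant (default 2000, the standard
#'   kcal/mol/A^2-scale restraint stiffness).
#' @param n_targeted number of targeted atoms N (defaults to the bead count
#'   of `native_ref`).
#' @return a `tmd_bias_spec`.
#' @export
tmd_bias_spec <- function(native_ref, target_rho, k_spring = 2000,
                          n_targeted = NULL) {
  stopifnot_cg(native_ref)
  if (k_spring <= 0) stop("k_spring must be positive")
  if (is.null(n_targeted)) n_targeted <- n_beads(native_ref)
  if (n_targeted < 1L) stop("n_targeted must be >= 1")
  if (target_rho < 0) stop("target_rho must be >= 0")
  structure(list(k_spring = k_spring, n_targeted = as.integer(n_targeted),
                 native_ref = native_ref, target_rho = target_rho),
            class = "tmd_bias_spec")
}

#' Targeted-MD bias energy
#'
#' \deqn{U = \frac{k}{2N}\,(\rho(x) - \rho^*)^2}
#' with \eqn{\rho(x)} the RMSD of the current conformation from the native
#' reference and \eqn{\rho^*} the target's RMSD from that reference. Zero
#' exactly when the current conformation is as far from native as the
#' target is; the external MD engine differentiates this restraint to force
#' the hop between consecutive CG targets.
#'
#' @param current current conformation, a [cg_structure()].
#' @param spec a [tmd_bias_spec()].
#' @param fit superpose before measuring rho? Default `FALSE` (raw-frame
#'   rho, the engine-side convention for an aligned system).
#' @return scalar bias energy.
#' @export
tmd_bias_energy <- function(current, spec, fit = FALSE) {
  if (!inherits(spec, "tmd_bias_spec")) stop("spec must be a tmd_bias_spec")
  rho <- rmsd_ca(current, spec$native_ref, fit = fit)
  spec$k_spring / (2 * spec$n_targeted) * (rho - spec$target_rho)^2
}

#' Export targeted-MD inputs for an external engine
#'
#' Writes everything an external MD engine needs for one refinement cycle:
#' a reference PDB whose targeted atoms are flagged through the occupancy
#' column (occupancy 1 on the C-alpha atoms, whose coordinates are replaced
#' by the CG target; 0 elsewhere -- the NAMD TMD convention), a plain-text
#' engine configuration fragment carrying the spring constant and the
#' TMD/equilibration durations, and a manifest describing the artifact the
#' pipeline expects back (the final equilibrated frame as a PDB).
#'
#' @param current current conformation ([cg_structure()] or
#'   `allatom_structure`; all-atom input keeps non-CA atoms at their current
#'   positions with occupancy 0).
#' @param target CG target conformation, a [cg_structure()] with the same
#'   residue count.
#' @param spec a [tmd_bias_spec()].
#' @param tmd_duration_ns targeted-MD duration (default 0.01 ns).
#' @param equil_duration_ns follow-up equilibration duration (default
#'   0.05 ns), which relieves the strain left by forcing the C-alpha
#'   positions.
#' @param outdir output directory (created if needed).
#' @return invisibly, named paths of the three written files.
#' @export
export_namd_tmd <- function(current, target, spec,
                            tmd_duration_ns = 0.01, equil_duration_ns = 0.05,
                            outdir = ".") {
  if (!inherits(spec, "tmd_bias_spec")) stop("spec must be a tmd_bias_spec")
  stopifnot_cg(target)
  if (tmd_duration_ns <= 0 || equil_duration_ns <= 0)
    stop("durations must be positive")
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)

  nt <- n_beads(target)
  if (inherits(current, "cg_structure")) {
    if (n_beads(current) != nt)
      stop("residue count mismatch: current ", n_beads(current),
           ", target ", nt)
    atoms <- data.frame(eleno = seq_len(nt), elety = "CA", resid = "ALA",
                        resno = target$residue_ids,
                        x = target$coords[, 1], y = target$coords[, 2],
                        z = target$coords[, 3], o = 1, b = 0)
  } else if (inherits(current, "allatom_structure")) {
    atoms <- current$atoms
    ca <- which(atoms$elety == "CA")
    if (length(ca) != nt)
      stop("residue count mismatch: current has ", length(ca),
           " CA atoms, target ", nt)
    atoms$o <- 0
    atoms$o[ca] <- 1
    atoms$x[ca] <- target$coords[, 1]
    atoms$y[ca] <- target$coords[, 2]
    atoms$z[ca] <- target$coords[, 3]
  } else stop("current must be a cg_structure or allatom_structure")

  ref_pdb <- file.path(outdir, "tmd_reference.pdb")
  bio3d::write.pdb(file = ref_pdb,
                   xyz = as.vector(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$resno, resid = atoms$resid,
                   eleno = atoms$eleno, elety = atoms$elety,
                   chain = rep("A", nrow(atoms)), o = atoms$o, b = atoms$b)

  cfg_path <- file.path(outdir, "tmd_config.namd")
  fs <- 1e6  # steps per ns at 1 fs timestep
  writeLines(c(
    "# targeted-MD fragment: include from the engine master configuration",
    "TMD                 on",
    sprintf("TMDk                %g", spec$k_spring),
    sprintf("TMDFile             %s", basename(ref_pdb)),
    "TMDOutputFreq       100",
    "TMDFirstStep        0",
    sprintf("TMDLastStep         %d", as.integer(round(tmd_duration_ns * fs))),
    sprintf("# equilibration (conventional MD) steps to run after TMD: %d",
            as.integer(round(equil_duration_ns * fs)))),
    cfg_path)

  manifest <- file.path(outdir, "manifest.txt")
  writeLines(c(
    "expected_return: final equilibrated frame, PDB format",
    sprintf("expected_return_file: refined.pdb"),
    sprintf("n_targeted_atoms: %d", spec$n_targeted),
    sprintf("k_spring: %g", spec$k_spring),
    sprintf("target_rho: %.6f", spec$target_rho),
    sprintf("tmd_duration_ns: %g", tmd_duration_ns),
    sprintf("equil_duration_ns: %g", equil_duration_ns)),
    manifest)

  invisible(c(reference_pdb = ref_pdb, config = cfg_path, manifest = manifest))
}

#' Mock refinement backend
#'
#' Desk-scale stand-in for a targeted-MD + equilibration cycle so the full
#' folding loop runs self-contained: the refined conformation moves a
#' fraction `attain_fraction` of the way from `current` to `target`, then
#' receives seeded isotropic Gaussian jitter of scale `noise_sigma` --
#' imperfect attainment plus jitter emulating the strain relief that
#' equilibration applies after the C-alpha positions are forced.
#' Deterministic given `seed`.
#'
#' @param current,target `cg_structure`s with equal bead counts.
#' @param attain_fraction fraction of the current-to-target displacement
#'   achieved, in (0, 1].
#' @param noise_sigma per-coordinate Gaussian jitter scale (>= 0).
#' @param seed RNG seed (required when `noise_sigma > 0`).
#' @return a `refinement_result`: list with `refined` (a `cg_structure`),
#'   `achieved_rmsd_to_target`, `backend_log`.
#' @export
mock_refine <- function(current, target, attain_fraction = 0.6,
                        noise_sigma = 0, seed = NULL) {
  stopifnot_cg(current); stopifnot_cg(target)
  n <- n_beads(current)
  if (n != n_beads(target))
    stop("bead count mismatch: ", n, " vs ", n_beads(target))
  if (attain_fraction <= 0 || attain_fraction > 1)
    stop("attain_fraction must be in (0, 1]")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  coords <- current$coords + attain_fraction * (target$coords - current$coords)
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("seed required when noise_sigma > 0")
    coords <- coords + with_seed(seed, matrix(stats::rnorm(3L * n, sd = noise_sigma), n, 3L))
  }
  refined <- cg_structure(coords, residue_ids = current$residue_ids,
                          name = "mock_refined", units = current$units)
  structure(list(
    refined = refined,
    achieved_rmsd_to_target = rmsd_ca(refined, target, fit = FALSE),
    backend_log = sprintf("mock_refine: attain=%.3f noise=%.3g seed=%s",
                          attain_fraction, noise_sigma,
                          if (is.null(seed)) "NULL" else seed)),
    class = "refinement_result")
}
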