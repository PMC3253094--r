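#' Coarse-grained structure
#'
#' Construct a `cg_structure`: an ordered C-alpha (one bead per residue) trace
#' of a single conformation. This is the basic currency of the package; all
#' coarse-grained operations (contact maps, LQR solves, trajectory metrics)
#' consume and produce it.
#'
#' @param coords numeric n x 3 matrix of bead coordinates (Angstrom, or
#'   dimensionless CG units in toy mode -- same code path, different label).
#' @param residue_ids strictly increasing integer residue labels; defaults to
#'   `1:n`.
#' @param name free-text tag carried through for provenance.
#' @param units `"angstrom"` or `"cg"`; label only, never used in arithmetic.
#' @return an object of class `cg_structure` with fields `coords`,
#'   `residue_ids`, `name`, `units`.
#' @examples
#' s <- cg_structure(matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE))
#' s$coords
#' @export
cg_structure <- function(coords, residue_ids = NULL, name = "", units = "angstrom") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("coords must be an n x 3 matrix")
  n <- nrow(coords)
  if (n < 2L)
    stop("a cg_structure needs at least 2 beads, got ", n)
  if (!all(is.finite(coords)))
    stop("coords contains non-finite values")
  if (is.null(residue_ids)) residue_ids <- seq_len(n)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n)
    stop("residue_ids length (", length(residue_ids), ") != number of beads (", n, ")")
  if (any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  units <- match.arg(units, c("angstrom", "cg"))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(coords = coords, residue_ids = residue_ids,
                 name = name, units = units),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  cat("cg_structure: ", nrow(x$coords), " beads (", x$units, ")",
      if (nzchar(x$name)) paste0("  [", x$name, "]"), "\n", sep = "")
  invisible(x)
}

n_beads <- function(s) nrow(s$coords)

stopifnot_cg <- function(s, arg = deparse(substitute(s))) {
  if (!inherits(s, "cg_structure"))
    stop(arg, " must be a cg_structure")
  invisible(s)
}

#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns an ordered all-atom
#' record table. Only `ATOM` records are kept (waters/ligands in `HETATM`
#' records are dropped); the first model of a multi-model file is used unless
#' `model` says otherwise.
#'
#' @param path path to a PDB file.
#' @param model 1-based model index for multi-model files.
#' @return an `allatom_structure`: a list with `atoms` (data frame with
#'   columns `eleno`, `elety`, `resid`, `resno`, `x`, `y`, `z`, `o`, `b`)
#'   and `name` (the file path).
#' @export
read_pdb <- function(path, model = 1L) {
  if (!file.exists(path))
    stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^ATOM ", lines)
  if (length(atom_lines) == 0L)
    stop("no ATOM records in ", path)
  # validate the fixed-width coordinate columns up front: the backend parser
  # fails on them without saying where
  coord_txt <- substr(lines[atom_lines], 31L, 54L)
  num <- function(a, b) suppressWarnings(as.numeric(substr(coord_txt, a, b)))
  bad <- atom_lines[is.na(num(1L, 8L)) | is.na(num(9L, 16L)) | is.na(num(17L, 24L))]
  if (length(bad) > 0L)
    stop("unparsable coordinate field(s) in ", path, " at line(s) ",
         paste(bad, collapse = ", "))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM"
  atoms <- pdb$atom[keep, c("eleno", "elety", "resid", "chain", "resno",
                            "x", "y", "z", "o", "b"), drop = FALSE]
  n_models <- nrow(pdb$xyz)
  if (model < 1L || model > n_models)
    stop("model ", model, " requested but file has ", n_models, " model(s)")
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  }
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad) > 0L)
    stop("unparsable coordinate field(s) in ", path, " at line(s) ",
         paste(atom_lines[bad], collapse = ", "))
  # first chain only, by default convention
  first_chain <- atoms$chain[1L]
  if (!is.na(first_chain)) {
    same <- is.na(atoms$chain) | atoms$chain == first_chain
    atoms <- atoms[same, , drop = FALSE]
  }
  atoms$chain <- NULL
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, name = path), class = "allatom_structure")
}

#' @export
print.allatom_structure <- function(x, ...) {
  cat("allatom_structure: ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$resno)), " residues",
      if (nzchar(x$name)) paste0("  [", x$name, "]"), "\n", sep = "")
  invisible(x)
}

# three-letter codes accepted as amino acids when pruning CA-less residues
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
          "SER", "THR", "TRP", "TYR", "VAL", "MSE", "SEC", "PYL")

#' Extract the C-alpha trace from an all-atom structure
#'
#' One bead per residue, centred on the CA atom, in residue order. Residues
#' without a CA atom are an error if they are amino acids, and are silently
#' skipped otherwise (e.g. co-crystallised ligands that survived in ATOM
#' records). Alternate locations are resolved by keeping the
#' highest-occupancy CA, with a warning.
#'
#' @param s an `allatom_structure` from [read_pdb()].
#' @return a [cg_structure()] with `n` = number of amino-acid residues.
#' @export
extract_calpha <- function(s) {
  if (!inherits(s, "allatom_structure"))
    stop("s must be an allatom_structure")
  at <- s$atoms
  res_ids <- unique(at$resno)
  coords <- matrix(NA_real_, 0L, 3L)
  kept_ids <- integer(0)
  missing_ca <- integer(0)
  for (rid in res_ids) {
    rows <- at[at$resno == rid, , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) {
      if (rows$resid[1L] %in% .aa3) missing_ca <- c(missing_ca, rid)
      next
    }
    if (nrow(ca) > 1L) {
      warning("residue ", rid, " has ", nrow(ca),
              " CA records (altloc); keeping highest occupancy")
      ca <- ca[which.max(ca$o), , drop = FALSE]
    }
    coords <- rbind(coords, c(ca$x, ca$y, ca$z))
    kept_ids <- c(kept_ids, rid)
  }
  if (length(missing_ca) > 0L)
    stop("amino-acid residue(s) missing a CA atom: ",
         paste(missing_ca, collapse = ", "))
  cg_structure(coords, residue_ids = kept_ids, name = s$name)
}

# Kabsch optimal rotation: returns mobile coordinates after the rigid
# transform minimising the coordinate RMSD to ref. SVD sign correction keeps
# the rotation proper; rank-deficient (collinear/planar) inputs are fine.
kabsch_fit <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(ref, 2L, cr)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2L, cr, "+")
}

#' Superpose one conformation onto another and report the RMSD
#'
#' Rigid-body (Kabsch) superposition of `mobile` onto `ref`, the convention
#' used throughout for RMSD-to-native reporting. Set `fit = FALSE` for the
#' raw coordinate RMSD without superposition, which is the convention the
#' targeted-MD bias bookkeeping uses for its reaction coordinate rho.
#'
#' @param mobile,ref `cg_structure`s with equal bead counts.
#' @param fit superpose before computing the RMSD? Default `TRUE`.
#' @return list with `structure` (mobile after the optimal rigid transform;
#'   unchanged when `fit = FALSE`) and `rmsd`.
#' @export
superpose <- function(mobile, ref, fit = TRUE) {
  stopifnot_cg(mobile); stopifnot_cg(ref)
  if (n_beads(mobile) != n_beads(ref))
    stop("bead count mismatch: ", n_beads(mobile), " vs ", n_beads(ref))
  fitted <- if (fit) kabsch_fit(mobile$coords, ref$coords) else mobile$coords
  out <- mobile
  out$coords <- fitted
  dimnames(out$coords) <- list(NULL, c("x", "y", "z"))
  list(structure = out,
       rmsd = sqrt(sum((fitted - ref$coords)^2) / n_beads(ref)))
}

#' C-alpha RMSD between two conformations
#'
#' Convenience wrapper around [superpose()] returning only the RMSD.
#'
#' @inheritParams superpose
#' @return the RMSD (same length unit as the inputs).
#' @export
rmsd_ca <- function(mobile, ref, fit = TRUE) superpose(mobile, ref, fit)$rmsd

#' Radius of gyration of a C-alpha trace
#'
#' Mass-uniform beads: \eqn{R_g = \sqrt{\sum_i \|r_i - \bar r\|^2 / n}}.
#' Its initial rapid decrease along a folding trajectory signals hydrophobic
#' collapse and chain compaction.
#'
#' @param s a `cg_structure`.
#' @return nonnegative scalar, same unit as the coordinates.
#' @export
radius_of_gyration <- function(s) {
  stopifnot_cg(s)
  centred <- sweep(s$coords, 2L, colMeans(s$coords))
  sqrt(sum(centred^2) / nrow(centred))
}

#' Write a sequence of conformations as a multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame, frame order preserved. CG frames are
#' written as CA-only records (residue name `ALA` placeholder); coordinates
#' survive a round trip through [read_pdb()] to PDB precision (1e-3).
#'
#' @param frames list of `cg_structure`s (equal bead counts).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(frames, path) {
  if (length(frames) == 0L)
    stop("empty frame list")
  lapply(frames, stopifnot_cg, arg = "each frame")
  ns <- vapply(frames, n_beads, integer(1))
  if (length(unique(ns)) != 1L)
    stop("inconsistent bead counts across frames: ", paste(unique(ns), collapse = ", "))
  n <- ns[1L]
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$coords))))
  rid <- frames[[1L]]$residue_ids
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = rid, resid = rep("ALA", n),
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep("A", n), o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read a multi-model PDB back as a list of C-alpha conformations
#'
#' @param path a (possibly multi-model) PDB file.
#' @return list of `cg_structure`s, one per model.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path))
    stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  rid <- pdb$atom$resno[sel$atom]
  lapply(seq_len(nrow(pdb$xyz)), function(m) {
    xyz <- matrix(pdb$xyz[m, sel$xyz], ncol = 3L, byrow = TRUE)
    cg_structure(xyz, residue_ids = rid, name = paste0(path, "#", m))
  })
}
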