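#' Fully extended synthetic chain
#'
#' Collinear beads spaced `bond_length` apart along x -- a geometric
#' stand-in for an unfolded starting conformation. It has no noncovalent
#' contacts at the usual 7-unit cutoff (every pair with sequence separation
#' >= 2 sits at >= 2 bond lengths).
#'
#' @param n bead count (>= 2).
#' @param bond_length consecutive-bead spacing (default 3.8, the C-alpha
#'   virtual bond length in Angstrom).
#' @return a [cg_structure()].
#' @export
make_extended <- function(n, bond_length = 3.8) {
  if (n < 2L) stop("n must be >= 2")
  if (bond_length <= 0) stop("bond_length must be positive")
  cg_structure(cbind(bond_length * (seq_len(n) - 1L), 0, 0),
               name = sprintf("extended_%d", n))
}

#' Ideal alpha-helical C-alpha trace
#'
#' Canonical helix geometry: rise 1.5 per residue, radius 2.3, twist 100
#' degrees per residue, which reproduces the ~3.8 consecutive C-alpha
#' distance and the characteristic i,i+3 / i,i+4 contacts of a folded
#' helix. A compact "native-like" counterpart to [make_extended()].
#'
#' @param n bead count (>= 2).
#' @param rise,radius,twist_deg helix parameters; defaults are the standard
#'   alpha-helix values.
#' @return a [cg_structure()].
#' @export
make_helix <- function(n, rise = 1.5, radius = 2.3, twist_deg = 100) {
  if (n < 2L) stop("n must be >= 2")
  i <- seq_len(n) - 1L
  theta <- i * twist_deg * pi / 180
  cg_structure(cbind(radius * cos(theta), radius * sin(theta), rise * i),
               name = sprintf("helix_%d", n))
}

#' Random collapsed (globule-like) synthetic chain
#'
#' Rejection-sampled self-avoiding walk with exact bond lengths, confined
#' to a sphere of radius `radius_factor * bond_length * n^(1/3)` (globule
#' scaling), with every nonconsecutive pair kept at least
#' `0.9 * bond_length` apart. Used as a synthetic compact "native" state;
#' deterministic for a given seed.
#'
#' @param n bead count (>= 2).
#' @param seed RNG seed.
#' @param bond_length consecutive-bead spacing (default 3.8).
#' @param radius_factor confinement-sphere prefactor (default 1.2).
#' @param max_restarts rejection budget: number of whole-chain restarts
#'   before giving up (default 5000).
#' @return a [cg_structure()].
#' @export
make_collapsed <- function(n, seed, bond_length = 3.8,
                           radius_factor = 1.2, max_restarts = 5000L) {
  if (n < 2L) stop("n must be >= 2")
  if (bond_length <= 0) stop("bond_length must be positive")
  r_max <- radius_factor * bond_length * n^(1 / 3)
  min_sep <- 0.9 * bond_length
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      coords <- matrix(NA_real_, n, 3L)
      coords[1L, ] <- stats::runif(3L, -r_max / 2, r_max / 2)
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (try in seq_len(60L)) {
          u <- stats::rnorm(3L)
          u <- u / sqrt(sum(u^2))
          cand <- coords[i - 1L, ] + bond_length * u
          if (sqrt(sum(cand^2)) > r_max) next
          if (i > 2L) {
            d2 <- colSums((t(coords[seq_len(i - 2L), , drop = FALSE]) - cand)^2)
            if (min(d2) < min_sep^2) next
          }
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok)
        return(cg_structure(coords,
                            name = sprintf("collapsed_%d_seed%d", n, seed)))
    }
    stop("rejection budget exhausted after ", max_restarts,
         " restarts; increase radius_factor or max_restarts")
  })
}
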