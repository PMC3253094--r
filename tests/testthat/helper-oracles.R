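# Shared fixtures and independent oracles for the test suite.

# random point-cloud conformation (not chain-like; exercises generic code paths)
random_cloud <- function(n, seed, scale = 6) {
  set.seed(seed)
  cg_structure(matrix(rnorm(3 * n, sd = scale), n, 3),
               name = sprintf("cloud_%d_%d", n, seed))
}

# apply a random proper rigid transform (rotation via QR, det +1) + translation
rigid_transform <- function(coords, seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, rnorm(3, sd = 10), "+")
}

# O(n^2) double-loop contact recount, independent of the vectorised path
brute_contact_count <- function(coords, cutoff, min_seq_sep, strict = TRUE) {
  n <- nrow(coords)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i < min_seq_sep) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      hit <- if (strict) d < cutoff else d <= cutoff
      if (hit) count <- count + 1L
    }
  }
  count
}

# stationary limit of the finite-horizon Riccati ODE
#   dP/dtau = A' P + P A - c P^2 + Q  (backward time), P(0) = 0,
# integrated with deSolve until the derivative is negligible. Independent
# route to the stabilising ARE solution for general Q.
riccati_ode_limit <- function(A, Q, cc, t_end = 400, tol = 1e-10) {
  n <- nrow(A)
  deriv <- function(t, y, parms) {
    P <- matrix(y, n, n)
    dP <- t(A) %*% P + P %*% A - cc * P %*% P + Q
    list(as.vector(dP))
  }
  out <- deSolve::ode(y = rep(0, n * n), times = c(0, t_end / 2, t_end),
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  P <- matrix(out[nrow(out), -1], n, n)
  resid <- max(abs(t(A) %*% P + P %*% A - cc * P %*% P + Q))
  stopifnot(resid < tol)
  (P + t(P)) / 2
}

# per-mode scalar ARE closed form for commuting A, Q = eps I:
#   p = (a + sqrt(a^2 + c q)) / c  per eigenvalue a of A
modal_gain <- function(A, eps, lam, gamma) {
  cc <- 1 / (lam * gamma^2)
  e <- eigen(A, symmetric = TRUE)
  p <- (e$values + sqrt(e$values^2 + cc * eps)) / cc
  P <- e$vectors %*% (p * t(e$vectors))
  P / (lam * gamma)
}

# 1x1 "free bead" system and weight, for the scalar closed-form checks
free_bead_system <- function(gamma = 1) {
  structure(list(A = matrix(0, 1, 1), gamma = gamma, k_bond = 1, n = 1L),
            class = "cg_system")
}
scalar_weight <- function(q) {
  structure(list(Q = matrix(q, 1, 1), epsilon = q, n_contacts = 0),
            class = "weight_matrix")
}

# minimal noiseless CG trajectory + current conformation, for scheduler tests
sched_fixture <- function(n = 8, samples = 50) {
  native <- make_collapsed(n, 1)
  sys <- build_system(n)
  sol <- solve_lqr(sys, build_Q(native))
  current <- make_extended(n)
  traj <- propagate_closed_loop(sys, sol, current$coords - native$coords,
                                samples = samples, native = native)
  list(traj = traj, current = superpose(current, native)$structure)
}

# minimal two-residue all-atom PDB text fixture
write_minimal_pdb <- function(path, x2 = 3.800) {
  writeLines(c(
    sprintf("ATOM      1  N   ALA A   1      -1.458   0.000   0.000  1.00  0.00"),
    sprintf("ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00"),
    sprintf("ATOM      3  C   ALA A   1       1.524   0.000   0.000  1.00  0.00"),
    sprintf("ATOM      4  N   GLY A   2       2.400   1.000   0.000  1.00  0.00"),
    sprintf("ATOM      5  CA  GLY A   2       %.3f   0.000   0.000  1.00  0.00", x2),
    "END"), path)
  path
}
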