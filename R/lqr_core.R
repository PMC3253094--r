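#' Overdamped coarse-grained chain dynamics
#'
#' System matrix of the bead-spring backbone in deviation coordinates:
#' \eqn{A = -(k_{bond}/\gamma) L_{chain}}, with \eqn{L_{chain}} the covalent
#' path-graph Laplacian. The mass term of the full equation of motion is
#' dropped (overdamped limit), so the state is the C-alpha deviation from
#' the native position and dynamics are first order. A is symmetric negative
#' semidefinite with exactly one zero eigenvalue, the rigid translation the
#' regulator must stabilise.
#'
#' @param n number of beads (>= 2).
#' @param gamma friction constant (> 0). Dimensionless 1 by default.
#' @param k_bond covalent spring constant (> 0). Dimensionless 1 by default.
#' @return a `cg_system`: list with `A`, `gamma`, `k_bond`, `n`.
#' @export
build_system <- function(n, gamma = 1, k_bond = 1) {
  if (n < 2L) stop("system needs at least 2 beads")
  if (gamma <= 0) stop("gamma must be positive")
  if (k_bond <= 0) stop("k_bond must be positive")
  structure(list(A = -(k_bond / gamma) * chain_connectivity(n),
                 gamma = gamma, k_bond = k_bond, n = as.integer(n)),
            class = "cg_system")
}

# Lyapunov solve M X + X M = -W for symmetric stable M (all eigenvalues < 0)
# and symmetric W, via the eigendecomposition of M. Used inside the Newton
# iteration where M = A - c P is symmetric by construction.
lyap_sym <- function(M, W) {
  e <- eigen(M, symmetric = TRUE)
  Wt <- crossprod(e$vectors, W %*% e$vectors)
  X <- Wt / -outer(e$values, e$values, "+")
  e$vectors %*% X %*% t(e$vectors)
}

# Continuous algebraic Riccati equation for the symmetric case
#   A P + P A - c P^2 + Q = 0,   c = 1/(lambda gamma^2) > 0,
# solved by Newton-Kleinman iteration from the stabilising start
# P0 = beta I (A - c P0 then has all eigenvalues <= -c beta < 0).
# Quadratic convergence; every iterate keeps A - c P stable.
solve_care_sym <- function(A, Q, c, tol = 1e-12, max_iter = 60L) {
  n <- nrow(A)
  beta <- sqrt(max(diag(Q)) / c)  # scalar ARE bound for the worst mode
  P <- diag(beta, n)
  for (it in seq_len(max_iter)) {
    M <- A - c * P
    P_new <- lyap_sym(M, Q + c * P %*% P)
    P_new <- (P_new + t(P_new)) / 2
    res <- max(abs(A %*% P_new + P_new %*% A - c * P_new %*% P_new + Q))
    P <- P_new
    if (res <= tol) break
  }
  list(P = P, residual = res, iterations = it)
}

#' Solve the infinite-horizon LQR for the coarse-grained chain
#'
#' Minimises the quadratic objective (elastic-network potential energy plus
#' a control-effort term weighted by `lam`, the entropy-loss penalty) subject
#' to the overdamped chain dynamics, with control matrix \eqn{B = I/\gamma}
#' and control weight \eqn{R = \lambda I}. One n x n Riccati solve is shared
#' by the x, y, z coordinates, since both A and Q are coordinate-independent.
#'
#' The stabilising solution P of
#' \deqn{A^T P + P A - P B R^{-1} B^T P + Q = 0}
#' gives the constant feedback gain \eqn{K = P/(\lambda\gamma)} and the
#' optimal force field \eqn{F^*(\Delta R) = -K\,\Delta R} applied per
#' coordinate. K inherits the structure of Q: it decomposes into an
#' inter-residue harmonic spring matrix with zero row sums plus uniform
#' springs of stiffness \eqn{\alpha = \sqrt{\epsilon/\lambda}} anchoring
#' every bead to its native position (see [decompose_gain()]).
#'
#' @param sys a `cg_system` from [build_system()].
#' @param q a `weight_matrix` from [build_Q()].
#' @param lam control penalty lambda (> 0). Larger values penalise fast,
#'   force-hungry trajectories (entropy loss); default 1.
#' @return an `lqr_solution`: list with `P`, `K`, `lambda`, `gamma`,
#'   `epsilon`, `alpha`, `gamma_star`, `residual` (max-abs ARE residual),
#'   `A` (copied from the system for propagation).
#' @export
solve_lqr <- function(sys, q, lam = 1) {
  if (!inherits(sys, "cg_system")) stop("sys must be a cg_system")
  if (!inherits(q, "weight_matrix")) stop("q must be a weight_matrix")
  if (lam <= 0) stop("lam must be positive")
  if (nrow(q$Q) != sys$n) stop("Q dimension does not match system size")
  cc <- 1 / (lam * sys$gamma^2)
  sol <- solve_care_sym(sys$A, q$Q, cc)
  if (!is.finite(sol$residual) || sol$residual > 1e-8)
    stop("Riccati iteration did not converge: residual ", format(sol$residual),
         " after ", sol$iterations, " iterations (n = ", sys$n,
         ", epsilon = ", q$epsilon, ", lambda = ", lam, ")")
  P <- sol$P
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Riccati solution not positive definite (min eigenvalue ",
         format(min(ev)), ")")
  K <- P / (lam * sys$gamma)
  alpha <- sqrt(q$epsilon / lam)
  structure(list(P = P, K = K, lambda = lam, gamma = sys$gamma,
                 epsilon = q$epsilon, alpha = alpha,
                 gamma_star = K - diag(alpha, sys$n),
                 residual = sol$residual, A = sys$A),
            class = "lqr_solution")
}

#' Split the optimal gain into inter-residue springs and native anchors
#'
#' \eqn{K = \Gamma^* + \alpha I}: `gamma_star` is the optimally assigned
#' harmonic spring-constant matrix between residues (row sums zero, so it
#' exerts no net force under rigid translation), and `alpha`
#' \eqn{= \sqrt{\epsilon/\lambda}} is the uniform stiffness of the springs
#' tying each bead directly to its native position -- the term that
#' stabilises the translational zero mode.
#'
#' @param sol an `lqr_solution`.
#' @return list with `gamma_star` (n x n matrix) and `alpha` (scalar).
#' @export
decompose_gain <- function(sol) {
  if (!inherits(sol, "lqr_solution")) stop("sol must be an lqr_solution")
  list(gamma_star = sol$gamma_star, alpha = sol$alpha)
}

#' Synthesised harmonic potential of the optimal controller
#'
#' \eqn{U(\Delta R) = \tfrac12 \sum_{c \in \{x,y,z\}} \Delta R_c^T K\,
#' \Delta R_c}, the quadratic well around the native state whose negative
#' gradient reproduces the optimal force field \eqn{F^* = -K \Delta R}.
#' Nonnegative, zero exactly at the native state.
#'
#' @param sol an `lqr_solution`.
#' @param dR n x 3 deviation matrix (current minus native coordinates).
#' @return scalar energy (CG units).
#' @export
harmonic_potential <- function(sol, dR) {
  if (!inherits(sol, "lqr_solution")) stop("sol must be an lqr_solution")
  dR <- as.matrix(dR)
  if (nrow(dR) != nrow(sol$K) || ncol(dR) != 3L)
    stop("dR must be ", nrow(sol$K), " x 3, got ", nrow(dR), " x ", ncol(dR))
  0.5 * sum(dR * (sol$K %*% dR))
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Propagate the closed-loop coarse-grained dynamics
#'
#' Integrates \eqn{d\Delta R/dt = (A - K/\gamma)\,\Delta R} per coordinate
#' from `dR0`, returning `samples` frames at equally spaced times
#' \eqn{t_k = k\,h/\mathrm{samples}}, k = 1..samples. The noiseless solution
#' is computed exactly through the eigendecomposition of the symmetric
#' stable closed-loop matrix; with `noise_sigma > 0` a seeded
#' Euler-Maruyama integration (step = horizon/(100 samples)) adds white
#' Langevin forcing, under which the same feedback law remains optimal in
#' expectation.
#'
#' @param sys a `cg_system`.
#' @param sol the matching `lqr_solution`.
#' @param dR0 n x 3 initial deviation from native.
#' @param horizon integration time, or `"auto"` (default): long enough for
#'   the slowest closed-loop mode to decay to 1 percent,
#'   \eqn{h = \ln(100)/\min_i |\mathrm{Re}\,\mu_i|}.
#' @param samples number of recorded frames (default 50).
#' @param noise_sigma Langevin noise strength (default 0, deterministic).
#' @param seed RNG seed for the noise path (required when `noise_sigma > 0`).
#' @param native optional `cg_structure`; when given, absolute frames
#'   \eqn{R(t) = \Delta R(t) + R^N} are attached.
#' @return a `cg_trajectory`: list with `times`, `frames` (list of n x 3
#'   deviation matrices), `absolute_frames` (list of `cg_structure` or NULL),
#'   `horizon`.
#' @export
propagate_closed_loop <- function(sys, sol, dR0, horizon = "auto",
                                  samples = 50L, noise_sigma = 0,
                                  seed = NULL, native = NULL) {
  if (!inherits(sys, "cg_system")) stop("sys must be a cg_system")
  if (!inherits(sol, "lqr_solution")) stop("sol must be an lqr_solution")
  if (samples < 1L) stop("samples must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  dR0 <- as.matrix(dR0)
  if (nrow(dR0) != sys$n || ncol(dR0) != 3L)
    stop("dR0 must be ", sys$n, " x 3")
  Ac <- sys$A - sol$K / sys$gamma
  e <- eigen(Ac, symmetric = TRUE)
  if (max(e$values) >= 0)
    stop("internal error: closed loop not stable (max eigenvalue ",
         format(max(e$values)), ")")
  h <- if (identical(horizon, "auto")) log(100) / min(abs(e$values)) else horizon
  if (!is.numeric(h) || h <= 0) stop("horizon must be positive or \"auto\"")
  times <- h * seq_len(samples) / samples

  if (noise_sigma == 0) {
    V <- e$vectors
    Z0 <- crossprod(V, dR0)           # modal coordinates
    frames <- lapply(times, function(t)
      V %*% (exp(e$values * t) * Z0))
  } else {
    if (is.null(seed)) stop("seed required for stochastic propagation")
    nsub <- 100L
    dt <- h / (nsub * samples)
    frames <- with_seed(seed, {
      X <- dR0
      out <- vector("list", samples)
      for (k in seq_len(samples)) {
        for (j in seq_len(nsub)) {
          X <- X + dt * (Ac %*% X) +
            sqrt(dt) * noise_sigma * matrix(stats::rnorm(3L * sys$n), sys$n, 3L)
        }
        out[[k]] <- X
      }
      out
    })
  }
  absolute <- NULL
  if (!is.null(native)) {
    stopifnot_cg(native)
    if (n_beads(native) != sys$n) stop("native size does not match system")
    absolute <- lapply(seq_along(frames), function(k)
      cg_structure(frames[[k]] + native$coords,
                   residue_ids = native$residue_ids,
                   name = sprintf("frame_%d", k), units = native$units))
  }
  structure(list(times = times, frames = frames,
                 absolute_frames = absolute, horizon = h),
            class = "cg_trajectory")
}
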