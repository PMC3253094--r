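test_that("build_system scales the chain Laplacian by -k_bond/gamma", {
  sys <- build_system(2)
  expect_equal(sys$A, rbind(c(-1, 1), c(1, -1)))

  sys2 <- build_system(10, gamma = 2, k_bond = 3)
  expect_equal(sys2$A, -(3 / 2) * chain_connectivity(10))
  ev <- eigen(sys2$A, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(ev), 1e-12)
  expect_equal(sum(abs(ev) < 1e-10), 1L)

  expect_error(build_system(1), "at least 2")
  expect_error(build_system(5, gamma = 0), "positive")
})

test_that("solve_lqr reproduces the two-bead modal solution", {
  sys <- build_system(2)
  sol <- solve_lqr(sys, build_Q(make_extended(2), epsilon = 0.04), lam = 1)
  # modes: a = 0 gives k = sqrt(0.04) = 0.2; a = -2 gives k = -2 + sqrt(4.04)
  k_slow <- 0.2
  k_fast <- -2 + sqrt(4.04)
  expect_equal(sol$K, rbind(c(k_slow + k_fast, k_slow - k_fast),
                            c(k_slow - k_fast, k_slow + k_fast)) / 2,
               tolerance = 1e-9)
  expect_lt(sol$residual, 1e-8)
  expect_equal(sol$alpha, 0.2)
})

test_that("gain row sums equal sqrt(epsilon/lambda) and gamma_star sums to zero", {
  for (seed in 1:8) {
    n <- c(4, 9, 14, 21, 27, 33, 41, 50)[seed]
    s <- make_collapsed(n, seed)
    eps <- 0.01 + 0.19 * (seed / 8)
    lam <- c(0.1, 0.5, 1, 2, 5, 10, 0.3, 3)[seed]
    sol <- solve_lqr(build_system(n), build_Q(s, epsilon = eps), lam = lam)
    expect_lt(max(abs(rowSums(sol$K) - sqrt(eps / lam))), 1e-8)
    dec <- decompose_gain(sol)
    expect_equal(dec$alpha, sqrt(eps / lam))
    expect_lt(max(abs(rowSums(dec$gamma_star))), 1e-8)
    expect_equal(dec$gamma_star + diag(dec$alpha, n), sol$K)  # exact identity
  }
})

test_that("alpha vanishes in the small-epsilon limit", {
  sol <- solve_lqr(build_system(4), build_Q(make_extended(4), epsilon = 1e-8))
  expect_lt(sol$alpha, 2e-4)
})

test_that("scalar free-bead closed form: P = gamma * sqrt(lambda q)", {
  sol <- solve_lqr(free_bead_system(), scalar_weight(0.04), lam = 1)
  expect_equal(sol$P[1, 1], 0.2, tolerance = 1e-10)
  expect_equal(sol$K[1, 1], 0.2, tolerance = 1e-10)
})

test_that("harmonic potential matches its quadratic form and gradient", {
  sol <- solve_lqr(free_bead_system(), scalar_weight(0.04))
  expect_equal(harmonic_potential(sol, matrix(0, 1, 3)), 0)
  expect_equal(harmonic_potential(sol, matrix(c(2, 0, 0), 1, 3)), 0.4)

  # finite-difference gradient equals -F* = K dR on a random instance
  n <- 5
  sol2 <- solve_lqr(build_system(n), build_Q(make_collapsed(n, 2)))
  set.seed(42)
  dR <- matrix(rnorm(3 * n), n, 3)
  grad_num <- matrix(0, n, 3)
  hstep <- 1e-6
  for (i in seq_len(n)) for (j in 1:3) {
    dp <- dR; dp[i, j] <- dp[i, j] + hstep
    dm <- dR; dm[i, j] <- dm[i, j] - hstep
    grad_num[i, j] <- (harmonic_potential(sol2, dp) -
                       harmonic_potential(sol2, dm)) / (2 * hstep)
  }
  expect_equal(grad_num, sol2$K %*% dR, tolerance = 1e-6)

  expect_error(harmonic_potential(sol2, matrix(0, 3, 3)), "must be 5 x 3")
})

test_that("noiseless propagation follows the matrix exponential", {
  # scalar decay: K = 0.2, dR(t) = exp(-0.2 t)
  sys1 <- free_bead_system()
  sol1 <- solve_lqr(sys1, scalar_weight(0.04))
  tr <- propagate_closed_loop(sys1, sol1, matrix(c(1, 0, 0), 1, 3),
                              horizon = 5, samples = 5)
  expect_equal(tr$frames[[5]][1, 1], exp(-1), tolerance = 1e-8)
  expect_equal(vapply(tr$frames, function(f) f[1, 1], numeric(1)),
               exp(-0.2 * tr$times), tolerance = 1e-8)

  # general instance vs Matrix::expm
  n <- 7
  sys <- build_system(n)
  sol <- solve_lqr(sys, build_Q(make_collapsed(n, 5)))
  dR0 <- make_collapsed(n, 6)$coords - make_collapsed(n, 5)$coords
  tr2 <- propagate_closed_loop(sys, sol, dR0, samples = 10)
  Ac <- sys$A - sol$K / sys$gamma
  for (k in c(1, 5, 10)) {
    ref <- as.matrix(Matrix::expm(Ac * tr2$times[k])) %*% dR0
    expect_equal(tr2$frames[[k]], ref, tolerance = 1e-8, ignore_attr = TRUE)
  }

  # fixed point at the origin
  tr0 <- propagate_closed_loop(sys, sol, matrix(0, n, 3), samples = 4)
  expect_true(all(vapply(tr0$frames, function(f) max(abs(f)), numeric(1)) == 0))
})

test_that("value function decreases along noiseless closed-loop paths", {
  for (seed in 1:5) {
    n <- 5 + 3 * seed
    sys <- build_system(n)
    sol <- solve_lqr(sys, build_Q(make_collapsed(n, seed)))
    dR0 <- make_extended(n)$coords - make_collapsed(n, seed)$coords
    tr <- propagate_closed_loop(sys, sol, dR0, samples = 50)
    V <- vapply(tr$frames, function(f) sum(f * (sol$P %*% f)), numeric(1))
    expect_true(all(diff(V) < 0))
  }
})

test_that("stochastic propagation is seed-deterministic and horizon is auto-set", {
  n <- 6
  sys <- build_system(n)
  sol <- solve_lqr(sys, build_Q(make_collapsed(n, 1)))
  dR0 <- make_extended(n)$coords - make_collapsed(n, 1)$coords
  a <- propagate_closed_loop(sys, sol, dR0, samples = 5, noise_sigma = 0.1, seed = 3)
  b <- propagate_closed_loop(sys, sol, dR0, samples = 5, noise_sigma = 0.1, seed = 3)
  expect_identical(a$frames, b$frames)
  c2 <- propagate_closed_loop(sys, sol, dR0, samples = 5, noise_sigma = 0.1, seed = 4)
  expect_false(identical(a$frames, c2$frames))
  expect_error(propagate_closed_loop(sys, sol, dR0, noise_sigma = 0.1), "seed")

  # auto horizon: slowest closed-loop mode decays to 1% at the horizon
  Ac <- sys$A - sol$K / sys$gamma
  mu <- min(abs(eigen(Ac, symmetric = TRUE, only.values = TRUE)$values))
  expect_equal(a$horizon, log(100) / mu)
})

test_that("optimal force magnitude is non-increasing in the control penalty", {
  n <- 10
  sys <- build_system(n)
  q <- build_Q(make_collapsed(n, 8))
  dR0 <- make_extended(n)$coords - make_collapsed(n, 8)$coords
  lams <- 0.5 * 10^seq(0, 1, length.out = 6)
  fnorm <- vapply(lams, function(l) {
    sol <- solve_lqr(sys, q, lam = l)
    sqrt(sum((sol$K %*% dR0)^2))
  }, numeric(1))
  expect_true(all(diff(fnorm) <= 1e-10))
})
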