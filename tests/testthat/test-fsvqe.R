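# Cost evaluation, SPSA, shot scheduling, refinement and the fsvqe()
# fitting interface.

test_that("the folded cost at an eigenstate is the squared detuning", {
  mi <- h2_integrals()
  h <- build_hamiltonian(mi)
  ans <- uccsd_ansatz("1100", 4, 2)
  # T1 reference is an exact eigenstate at theta = 0
  ref <- reference_state("1010")
  psi <- simulate_statevector(prepare_reference(ref, 4))
  E <- ps_expectation(h, psi)
  for (om in c(E - 0.3, E, E + 0.12)) {
    spec <- cost_spec(fold_spectrum(h, om)$folded, omega = om)
    val <- evaluate_cost(spec, c(0, 0, 0), ans, ref, backend = "statevector")
    expect_equal(val, (E - om)^2, tolerance = 1e-9)
  }
})

test_that("statevector costs equal the dense quadratic form", {
  mi <- h2_integrals()
  h <- build_hamiltonian(mi)
  ans <- uccsd_ansatz("1100", 4, 2)
  ref <- reference_state("0011")
  fo <- fold_spectrum(h, -0.4)
  spec <- cost_spec(fo$folded, omega = -0.4)
  set.seed(30)
  for (i in 1:4) {
    th <- stats::runif(3, -1, 1)
    val <- evaluate_cost(spec, th, ans, ref, backend = "statevector")
    psi0 <- simulate_statevector(prepare_reference(ref, 4))
    psi <- fsvqe:::.ucc_apply(psi0, ans$terms, th)
    oracle <- Re(Conj(psi) %*% osum(fo$folded$labels, fo$folded$coeffs) %*% psi)[1, 1]
    expect_equal(val, oracle, tolerance = 1e-10)
  }
})

test_that("the variance identity holds on the exact backend", {
  mi <- h2_integrals()
  h <- build_hamiltonian(mi)
  ans <- uccsd_ansatz("1100", 4, 2)
  ref <- reference_state("0011")
  om <- -0.2
  spec_f <- cost_spec(fold_spectrum(h, om)$folded, omega = om)
  spec_h <- cost_spec(h)
  spec_h2 <- cost_spec(ps_multiply(h, h))
  set.seed(31)
  for (i in 1:4) {
    th <- stats::runif(3, -1, 1)
    f <- evaluate_cost(spec_f, th, ans, ref, backend = "statevector")
    eh <- evaluate_cost(spec_h, th, ans, ref, backend = "statevector")
    eh2 <- evaluate_cost(spec_h2, th, ans, ref, backend = "statevector")
    expect_equal(f, eh2 - 2 * om * eh + om^2, tolerance = 1e-9)
    expect_equal(f, (eh2 - eh^2) + (eh - om)^2, tolerance = 1e-9)
    expect_gte(f, -1e-12)   # folded cost is nonnegative
  }
})

test_that("the continuity penalty adds eta * ||theta - theta_prev||^2", {
  mi <- h2_integrals()
  h <- build_hamiltonian(mi)
  ans <- uccsd_ansatz("1100", 4, 2)
  ref <- reference_state("0011")
  th <- c(0.3, -0.1, 0.2); prev <- c(0.1, 0.1, 0.1)
  base <- evaluate_cost(cost_spec(h), th, ans, ref, backend = "statevector")
  pen <- evaluate_cost(cost_spec(h, eta = 0.1, theta_prev = prev),
                       th * 1, ans, ref, backend = "statevector")
  expect_equal(pen - base, 0.1 * sum((th - prev)^2), tolerance = 1e-9)
  expect_error(cost_spec(h, eta = 0.1), "theta_prev")
})

test_that("the shot schedule interpolates between its bounds monotonically", {
  sched <- shot_schedule()
  expect_equal(shots_at(sched, 0), 1000L)
  expect_equal(shots_at(sched, 1e6), 10000L)
  s <- vapply(0:1000, shots_at, sched = sched, FUN.VALUE = integer(1))
  expect_true(all(diff(s) >= 0))
  sched2 <- shot_schedule(rate = 0.5)
  s2 <- vapply(0:100, shots_at, sched = sched2, FUN.VALUE = integer(1))
  expect_true(all(diff(s2) >= 0))
  expect_error(shot_schedule(rate = 0), "rate")
})

test_that("SPSA converges on a quadratic bowl with exact evaluations", {
  fn <- function(x, shots = NULL) sum((x - c(1, -2, 0.5))^2)
  set.seed(32)
  res <- spsa_minimize(fn, c(0, 0, 0),
                       spsa_config(a = 1, A = 10, maxiter = 4000,
                                   grad_tol = 1e-6, c0 = 0.05),
                       shot_schedule())
  expect_true(res$converged)
  expect_lt(sqrt(sum((res$theta - c(1, -2, 0.5))^2)), 0.05)
  expect_equal(res$n_evaluations, 2L * res$iterations)
})

test_that("SPSA runs are reproducible under a fixed seed", {
  fn <- function(x, shots) sum(x^2) + stats::rnorm(1, sd = 1 / sqrt(shots))
  run <- function() {
    set.seed(77)
    spsa_minimize(fn, c(0.5, -0.5), spsa_config(maxiter = 50),
                  shot_schedule())
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$trace, r2$trace)
})

test_that("quadratic refinement recovers the vertex of a parabola", {
  fn <- function(x, shots = NULL) 3 * (x[1] - 0.21)^2 + 2 * (x[2] + 0.4)^2 + 1
  out <- quadratic_refine(fn, c(0.15, -0.33), c_scale = 2)
  expect_equal(out, c(0.21 * 1, -0.4), tolerance = 1e-8)
  expect_equal(quadratic_refine(fn, c(0.21, -0.4), c_scale = 2),
               c(0.21, -0.4), tolerance = 1e-8)
  # concave direction is left unchanged
  fn2 <- function(x, shots = NULL) -(x[1]^2)
  expect_equal(quadratic_refine(fn2, 0.3, c_scale = 2), 0.3)
})

test_that("noisy parabola refinement rarely worsens the true cost", {
  truth <- function(x) (x[1] - 0.3)^2 + (x[2] + 0.1)^2
  set.seed(33)
  wins <- replicate(40, {
    fn <- function(x, shots = NULL) truth(x) + stats::rnorm(1, sd = 2e-4)
    x0 <- c(0.25, -0.05)
    xr <- quadratic_refine(fn, x0, c_scale = 2)
    truth(xr) <= truth(x0) + 1e-6
  })
  expect_gte(mean(wins), 0.95)
})

test_that("angle rounding keeps only non-worsening roundings", {
  fn <- function(x, shots = NULL) sum(x^2)    # optimum at exactly zero
  out <- round_parameters(fn, c(1e-7 * 2, 0.3), c_scale = 2)
  expect_identical(out[1], 0)
  expect_identical(out[2], 0.3)
  # near pi with a flat cost rounds to pi
  fn_flat <- function(x, shots = NULL) 0
  out2 <- round_parameters(fn_flat, (pi - 1e-7) * 2, c_scale = 2)
  expect_equal(out2, pi * 2)
  # a rounding that worsens the cost is rejected
  fn_sharp <- function(x, shots = NULL) (x[1] / 2 - 0.01)^2
  out3 <- round_parameters(fn_sharp, 0.01 * 2, c_scale = 2, tol = 0.02)
  expect_equal(out3, 0.01 * 2)
})

test_that("fci_energies returns the ascending spectrum", {
  expect_equal(fci_energies(pauli_sum("Z", 1)), c(-1, 1))
  h <- build_hamiltonian(h2_integrals())
  fci <- fci_energies(h)
  om <- -0.45
  folded_min <- min(fci_energies(fold_spectrum(h, om)$folded))
  expect_equal(folded_min, min((fci - om)^2), tolerance = 1e-9)
})

test_that("fsvqe recovers H2 eigenstates on the exact backend", {
  mi <- h2_integrals()
  h <- build_hamiltonian(mi)
  fci <- fci_energies(h)
  gs <- fsvqe(mi, backend = "statevector", hamiltonian = h, seed = 2)
  expect_equal(gs$energy, min(fci), tolerance = 1e-6)
  for (ref in h2_reference_states()) {
    fit <- fsvqe(mi, reference = ref, omega = "auto",
                 backend = "statevector", hamiltonian = h, seed = 2)
    expect_lt(min(abs(fit$energy - fci)), 1e-6)
  }
})

test_that("fsvqe methods expose the fit consistently", {
  mi <- h2_integrals()
  fit <- fsvqe(mi, backend = "statevector", seed = 3)
  expect_s3_class(fit, "fsvqe")
  expect_length(coef(fit), 3L)
  expect_output(print(fit), "energy")
  expect_output(print(summary(fit)), "FCI")
  cts <- simulate(fit, nsim = 200, seed = 4)
  expect_s3_class(cts, "counts")
  expect_equal(sum(cts$histogram), 200)
})

test_that("a sampled-backend fit stays reproducible and near the target", {
  mi <- h2_integrals()
  h <- build_hamiltonian(mi)
  fci <- fci_energies(h)
  cfg <- spsa_config(maxiter = 120)
  fit1 <- fsvqe(mi, reference = h2_reference_states()$T1, omega = "auto",
                backend = "sampled", hamiltonian = h, seed = 11, spsa = cfg)
  fit2 <- fsvqe(mi, reference = h2_reference_states()$T1, omega = "auto",
                backend = "sampled", hamiltonian = h, seed = 11, spsa = cfg)
  expect_identical(fit1$energy, fit2$energy)
  expect_lt(min(abs(fit1$energy - fci)) * KCAL, 1.5)
})
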