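# Ansatz compilation, reference preparation and the three backends.

test_that("excitation enumeration matches the shipped systems", {
  expect_length(enumerate_excitations("1100", 4), 3L)
  expect_length(enumerate_excitations("111100", 6), 8L)
  expect_length(enumerate_excitations("1111", 4), 0L)  # no virtuals
  # spin conservation and index ranges
  for (e in enumerate_excitations("111100", 6)) {
    occ_spin <- sort(e$occ %% 2L)
    virt_spin <- sort(e$virt %% 2L)
    expect_equal(occ_spin, virt_spin)
    expect_true(all(e$occ < 4L), info = "occupied in reference")
    expect_true(all(e$virt >= 4L))
  }
})

test_that("excitation generators are anti-Hermitian JW images", {
  e1 <- list(rank = 1L, occ = 0L, virt = 2L, slot = 1L)
  g1 <- excitation_generator(e1, 4)
  expect_length(g1$labels, 2L)
  expect_true(all(nchar(gsub("I", "", g1$labels)) == 3L))  # weight 3
  e2 <- list(rank = 2L, occ = c(0L, 1L), virt = c(2L, 3L), slot = 2L)
  g2 <- excitation_generator(e2, 4)
  expect_length(g2$labels, 8L)
  expect_true(all(nchar(gsub("I", "", g2$labels)) == 4L))  # weight 4
  for (g in list(g1, g2)) {
    M <- omat_of_ps(g)
    expect_lt(max(Mod(M + Conj(t(M)))), 1e-12)   # anti-Hermitian
    U <- expm_antiherm(0.37 * M)
    expect_lt(max(Mod(U %*% Conj(t(U)) - diag(16))), 1e-10)
  }
})

test_that("Pauli gadgets use 2(w-1) CNOTs and reproduce the exponentials", {
  ex <- enumerate_excitations("1100", 4)
  qc <- compile_ucc(ex, 4, c_scale = 2)
  # count CNOTs: singles contribute 2 strings of weight 3 each (4 CNOTs),
  # the double 8 strings of weight 4 (6 CNOTs)
  ncx <- sum(vapply(qc$gates, function(g) g$type == "CNOT", logical(1)))
  expect_equal(ncx, 2L * 2L * 4L + 8L * 6L)
  set.seed(20)
  x <- stats::runif(3, -2, 2)
  psi0 <- basis_vec("1100")
  psi_circ <- simulate_statevector(qc, x, psi0 = psi0)
  psi_or <- psi0
  terms <- rev(fsvqe:::.ucc_terms(ex, 4))  # first-enumerated factor leftmost
  for (tt in terms) for (k in seq_along(tt$labels)) {
    A <- 1i * tt$g[[k]] * (x[[tt$slot]] / 2) * omat(tt$labels[[k]])
    psi_or <- expm_antiherm(A) %*% psi_or
  }
  expect_lt(max(Mod(psi_circ - as.vector(psi_or))), 1e-10)
})

test_that("the compiled UCC unitary is the identity at theta = 0", {
  ex <- enumerate_excitations("1100", 4)
  qc <- compile_ucc(ex, 4)
  for (b in c("1100", "1010", "0011")) {
    psi <- simulate_statevector(qc, c(0, 0, 0), psi0 = basis_vec(b))
    expect_lt(max(Mod(psi - basis_vec(b))), 1e-12)
  }
})

test_that("the noiseless ansatz conserves particle number", {
  ex <- enumerate_excitations("111100", 6)
  terms <- fsvqe:::.ucc_terms(ex, 6)
  nop <- jw_number_operator(6)
  set.seed(21)
  for (i in 1:5) {
    psi <- fsvqe:::.ucc_apply(basis_vec("111100"), terms,
                              stats::runif(8, -1.5, 1.5))
    expect_equal(ps_expectation(nop, psi), 4, tolerance = 1e-10)
    expect_equal(sum(Mod(psi)^2), 1, tolerance = 1e-12)
  }
})

test_that("reference circuits prepare the requested states", {
  psi <- simulate_statevector(prepare_reference(reference_state("1100"), 4))
  expect_equal(psi, basis_vec("1100"))
  r <- reference_state(c("1001", "0110"), c(1, 1) / sqrt(2))
  psi <- simulate_statevector(prepare_reference(r, 4))
  expect_equal(Mod(psi[strtoi("1001", 2) + 1]), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(psi[strtoi("1001", 2) + 1], psi[strtoi("0110", 2) + 1],
               tolerance = 1e-12)
  rm <- reference_state(c("1001", "0110"), c(1, -1) / sqrt(2))
  psim <- simulate_statevector(prepare_reference(rm, 4))
  expect_equal(psim[strtoi("1001", 2) + 1], -psim[strtoi("0110", 2) + 1],
               tolerance = 1e-12)
  expect_error(reference_state(c("11", "10", "01")), "at most 2")
  expect_error(reference_state(c("1100", "1110")), "electron count")
  # energy of a single-determinant reference equals its diagonal element
  h <- build_hamiltonian(h2_integrals())
  psi_t1 <- simulate_statevector(prepare_reference(reference_state("1010"), 4))
  Mh <- omat_of_ps(h)
  k <- strtoi("1010", 2) + 1
  expect_equal(ps_expectation(h, psi_t1), Re(Mh[k, k]), tolerance = 1e-12)
})

test_that("statevector simulation agrees with dense unitaries on random circuits", {
  gm <- list(X = .SIG$X, H = matrix(c(1, 1, 1, -1), 2) / sqrt(2) + 0i,
             S = diag(c(1, 1i)), SDG = diag(c(1, -1i)))
  set.seed(22)
  for (rep in 1:5) {
    n <- 3
    qc <- empty_circuit(n)
    U <- diag(2^n) + 0i
    full <- function(m, q) {
      l <- if (q > 0) diag(2^q) else 1
      r <- if (q < n - 1) diag(2^(n - 1 - q)) else 1
      kronecker(kronecker(l, m), r)
    }
    for (i in 1:15) {
      kind <- sample(c("X", "H", "S", "SDG", "RZ", "CNOT"), 1)
      if (kind == "CNOT") {
        qs <- sample(0:(n - 1), 2)
        qc <- qc_gate(qc, "CNOT", qs[1], q2 = qs[2])
        cn <- matrix(0+0i, 2^n, 2^n)
        bc <- bitwShiftL(1L, n - qs[1] - 1L); bt <- bitwShiftL(1L, n - qs[2] - 1L)
        for (ii in 0:(2^n - 1)) {
          jj <- if (bitwAnd(ii, bc) > 0) bitwXor(ii, bt) else ii
          cn[jj + 1, ii + 1] <- 1
        }
        U <- cn %*% U
      } else if (kind == "RZ") {
        q <- sample(0:(n - 1), 1); ang <- stats::runif(1, -pi, pi)
        qc <- qc_gate(qc, "RZ", q, angle = ang)
        U <- full(diag(c(exp(-1i * ang / 2), exp(1i * ang / 2))), q) %*% U
      } else {
        q <- sample(0:(n - 1), 1)
        qc <- qc_gate(qc, kind, q)
        U <- full(gm[[kind]], q) %*% U
      }
    }
    psi0 <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
    psi0 <- psi0 / sqrt(sum(Mod(psi0)^2))
    expect_lt(max(Mod(simulate_statevector(qc, psi0 = psi0) -
                        as.vector(U %*% psi0))), 1e-10)
  }
})

test_that("sampling is seeded, reproducible and binomially concentrated", {
  psi <- basis_vec("010")
  c1 <- sample_counts(psi, 100, seed = 5)
  expect_equal(unname(c1$histogram[["010"]]), 100)
  plus <- c(1, 1) / sqrt(2) + 0i
  c2 <- sample_counts(plus, 1e6, seed = 6)
  freq <- c2$histogram[["0"]] / 1e6
  expect_lt(abs(freq - 0.5), 3 * 5e-4)
  expect_identical(sample_counts(plus, 500, seed = 7)$histogram,
                   sample_counts(plus, 500, seed = 7)$histogram)
})

test_that("noise scaling interpolates the lambda = 0.4 parameter row", {
  base <- noise_params()
  s04 <- scale_noise(base, 0.4)
  expect_equal(s04$T1, 924, tolerance = 1e-3)   # printed precision
  expect_equal(s04$T2, 461, tolerance = 3e-3)
  expect_equal(s04$t_gate1, 14)
  expect_equal(s04$t_gate2, 120)
  expect_equal(s04$p1, 4e-5)
  expect_equal(s04$p2, 4e-4)
  expect_equal(s04$p_spam, 4e-3)
  s0 <- scale_noise(base, 0)
  expect_equal(s0$T1, 2000)
  expect_equal(s0$T2, 1000)
  expect_equal(c(s0$p1, s0$p2, s0$p_spam, s0$t_gate1, s0$t_gate2),
               rep(0, 5))
  s1 <- scale_noise(base, 1)
  expect_equal(s1$T1, base$T1)
  expect_equal(s1$p2, base$p2)
  expect_error(scale_noise(base, 1.2), "lambda")
  expect_error(noise_params(T1 = 10, T2 = 25), "T2")
})

test_that("zero-lambda noise reproduces the ideal sampler", {
  qc <- prepare_reference(reference_state(c("10", "01")), 2)
  np0 <- scale_noise(noise_params(), 0)
  cts <- simulate_noisy(qc, noise = np0, shots = 4000, seed = 8,
                        return_rho = TRUE)
  rho <- attr(cts, "rho")
  psi <- simulate_statevector(qc)
  expect_lt(max(Mod(rho - outer(psi, Conj(psi)))), 1e-12)
})

test_that("T1 relaxation decays the excited population exponentially", {
  np <- noise_params(T1 = 100, T2 = 200, t_gate1 = 2000, p1 = 0, p2 = 0,
                     p_spam = 0)
  # X preparation then k identity-like Rz gates, each adding t_gate1
  for (k in c(5, 20)) {
    qc <- empty_circuit(1)
    qc <- qc_gate(qc, "X", 0)
    for (i in seq_len(k)) qc <- qc_gate(qc, "RZ", 0, angle = 0)
    cts <- simulate_noisy(qc, noise = np, shots = 10, seed = 9,
                          return_rho = TRUE)
    rho <- attr(cts, "rho")
    t_total <- (k + 1) * np$t_gate1 * 1e-3   # us
    expect_equal(Re(rho[2, 2]), exp(-t_total / np$T1), tolerance = 1e-10)
  }
})

test_that("p_spam = 0.5 randomizes the measured bit completely", {
  np <- noise_params(p_spam = 0.5, p1 = 0, p2 = 0, t_gate1 = 0, t_gate2 = 0)
  qc <- qc_gate(empty_circuit(1), "X", 0)
  cts <- simulate_noisy(qc, noise = np, shots = 20000, seed = 10)
  p1 <- cts$histogram[["1"]] / 20000
  expect_lt(abs(p1 - 0.5), 0.02)
})

test_that("per-gate noise channels are trace preserving and completely positive", {
  np <- scale_noise(noise_params(), 0.7)
  kraus <- fsvqe:::.thermal_kraus(np$t_gate1, np$T1, np$T2)
  # completeness: sum K^dagger K = I
  comp <- Reduce(`+`, lapply(kraus, function(K) Conj(t(K)) %*% K))
  expect_lt(max(Mod(comp - diag(2))), 1e-12)
  # compose with depolarizing and check Choi positivity
  dep <- c(lapply(list(sqrt(1 - np$p1) * .SIG$I,
                       sqrt(np$p1 / 3) * .SIG$X,
                       sqrt(np$p1 / 3) * .SIG$Y,
                       sqrt(np$p1 / 3) * .SIG$Z), identity))
  all_kraus <- list()
  for (K in kraus) for (D in dep) {
    all_kraus[[length(all_kraus) + 1L]] <- K %*% D
  }
  choi <- matrix(0+0i, 4, 4)
  for (K in all_kraus) choi <- choi + kronecker(K, Conj(K))
  # reshuffle to the Choi matrix of the channel
  choi_m <- matrix(0+0i, 4, 4)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    E_ij <- matrix(0+0i, 2, 2); E_ij[i, j] <- 1
    out <- Reduce(`+`, lapply(all_kraus, function(K) K %*% E_ij %*% Conj(t(K))))
    choi_m[(i - 1) * 2 + (1:2), (j - 1) * 2 + (1:2)] <-
      choi_m[(i - 1) * 2 + (1:2), (j - 1) * 2 + (1:2)] + out
  }
  eigs <- Re(eigen(choi_m, symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(min(eigs), -1e-10)
  comp2 <- Reduce(`+`, lapply(all_kraus, function(K) Conj(t(K)) %*% K))
  expect_lt(max(Mod(comp2 - diag(2))), 1e-12)
})

test_that("density-matrix simulation preserves the trace through a circuit", {
  np <- scale_noise(noise_params(), 0.5)
  ex <- enumerate_excitations("1100", 4)
  qc <- qc_append(prepare_reference(reference_state("0011"), 4),
                  compile_ucc(ex, 4))
  cts <- simulate_noisy(qc, theta = c(0.2, -0.1, 0.4), noise = np,
                        shots = 100, seed = 11, return_rho = TRUE)
  rho <- attr(cts, "rho")
  expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-10)
  expect_lt(max(Mod(rho - Conj(t(rho)))), 1e-10)
})

test_that("circuit serialization round-trips", {
  ex <- enumerate_excitations("1100", 4)
  qc <- compile_ucc(ex, 4)
  path <- tempfile()
  write_circuit(qc, path)
  back <- read_circuit(path)
  expect_equal(length(back$gates), length(qc$gates))
  x <- c(0.3, -0.2, 0.1)
  expect_equal(simulate_statevector(back, x, psi0 = basis_vec("1100")),
               simulate_statevector(qc, x, psi0 = basis_vec("1100")),
               tolerance = 1e-12)
})
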