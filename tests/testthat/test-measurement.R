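# Commutation graphs, greedy clique cover, post-rotations and
# count-based expectation values.

test_that("commutation graphs follow the textbook examples", {
  s <- pauli_sum(c("XX", "YY", "ZZ"), c(1, 1, 1))
  adj <- commutation_graph(s, "gc")
  expect_true(all(adj))                       # complete graph under GC
  s2 <- pauli_sum(c("XX", "YY"), c(1, 1))
  adj2 <- commutation_graph(s2, "qwc")
  expect_false(adj2["XX", "YY"])              # no edge under QWC
  s3 <- pauli_sum("XYZ", 1)
  expect_equal(dim(commutation_graph(s3, "qwc")), c(1L, 1L))
  expect_error(commutation_graph(pauli_sum(character(0), n_qubits = 2)),
               "empty")
})

test_that("greedy clique cover reproduces the H2 group counts", {
  h <- build_hamiltonian(h2_integrals())
  expect_equal(length(pauli_groups(h, "qwc")), 5L)
  expect_equal(length(pauli_groups(h, "gc")), 2L)
  fo <- fold_spectrum(h, -0.5)
  expect_equal(n_terms(fo$folded), 24L)
  expect_equal(length(pauli_groups(fo$folded, "gc")), 2L)
  # fully mutually commuting set collapses to one group
  s <- pauli_sum(c("ZZ", "ZI", "IZ", "II"), rep(1, 4))
  expect_equal(length(pauli_groups(s, "qwc")), 1L)
})

test_that("group count never exceeds term count and groups partition labels", {
  set.seed(10)
  for (i in 1:5) {
    s <- random_herm_ps(4, 12)
    for (mode in c("qwc", "gc")) {
      gr <- pauli_groups(s, mode)
      expect_lte(length(gr), n_terms(s))
      members <- unlist(lapply(gr, `[[`, "members"))
      expect_setequal(members, s$labels)
      expect_equal(length(members), length(s$labels))  # disjoint
      for (g in gr) {
        for (p in g$members) for (q in g$members) {
          ok <- if (mode == "qwc") commutes_qwc(p, q) else commutes_gc(p, q)
          expect_true(ok)
        }
      }
    }
  }
})

test_that("all Z-containing diagonal strings share one QWC group", {
  # the identity commutes with everything and may be read from any
  # group's counts; every other diagonal string must land together so
  # one measurement serves them all
  h <- build_hamiltonian(h2_integrals())
  gr <- pauli_groups(h, "qwc")
  diag_labels <- h$labels[!grepl("[XY]", h$labels) & grepl("Z", h$labels)]
  holds <- vapply(gr, function(g) all(diag_labels %in% g$members), logical(1))
  expect_equal(sum(holds), 1L)
})

test_that("post-rotations diagonalize every QWC member", {
  g <- structure(list(members = c("IX", "XX", "XI"), mode = "qwc",
                      n_qubits = 2L, post_rotation = NULL),
                 class = "measurement_group")
  g <- assign_post_rotation(g)
  expect_equal(g$post_rotation, c("X", "X"))
  gd <- structure(list(members = c("ZZ", "IZ"), mode = "qwc",
                       n_qubits = 2L, post_rotation = NULL),
                  class = "measurement_group")
  expect_equal(assign_post_rotation(gd)$post_rotation, c("none", "none"))
  gy <- structure(list(members = "ZY", mode = "qwc", n_qubits = 2L,
                       post_rotation = NULL), class = "measurement_group")
  expect_equal(assign_post_rotation(gy)$post_rotation, c("none", "Y"))
  ggc <- structure(list(members = c("XX", "YY"), mode = "gc",
                        n_qubits = 2L, post_rotation = NULL),
                   class = "measurement_group")
  expect_error(assign_post_rotation(ggc), "QWC")
  # string-level diagonality check for every group of a real operator
  h <- build_hamiltonian(h2_integrals())
  for (g in pauli_groups(h, "qwc")) {
    rot <- rotated_members(g)
    expect_false(any(grepl("[XY]", rot$diagonal)))
  }
})

test_that("clifford conjugation matches dense conjugation", {
  set.seed(11)
  qc <- empty_circuit(3)
  qc <- qc_gate(qc, "H", 0)
  qc <- qc_gate(qc, "SDG", 1)
  qc <- qc_gate(qc, "H", 1)
  qc <- qc_gate(qc, "CNOT", 0, q2 = 2)
  qc <- qc_gate(qc, "S", 2)
  U <- diag(8) + 0i
  gm <- list(H = matrix(c(1, 1, 1, -1), 2) / sqrt(2) + 0i,
             S = diag(c(1, 1i)), SDG = diag(c(1, -1i)))
  full <- function(m, q) {
    l <- if (q > 0) diag(2^q) else 1
    r <- if (q < 2) diag(2^(2 - q)) else 1
    kronecker(kronecker(l, m), r)
  }
  cn02 <- matrix(0+0i, 8, 8)
  for (i in 0:7) {
    j <- if (bitwAnd(i, 4L) > 0) bitwXor(i, 1L) else i
    cn02[j + 1, i + 1] <- 1
  }
  for (g in qc$gates) {
    step <- if (g$type == "CNOT") cn02 else full(gm[[g$type]], g$q)
    U <- step %*% U
  }
  for (lab in c("XYZ", "ZZI", "YII", "IXX")) {
    cc <- clifford_conjugate(lab, qc)
    expect_lt(max(Mod(U %*% omat(lab) %*% Conj(t(U)) -
                        cc$sign * omat(cc$label))), 1e-12)
  }
})

test_that("diagonal expectations from counts follow the eigenvalue sum", {
  c1 <- counts(c("00" = 10), 10)
  expect_equal(expectation_from_counts(c1, "ZZ"), 1)
  c2 <- counts(c("01" = 5, "10" = 5), 10)
  expect_equal(expectation_from_counts(c2, "ZI"), 0)
  c3 <- counts(c("00" = 3, "11" = 1), 4)
  expect_equal(expectation_from_counts(c3, "IZ"), 0.5)
  expect_equal(expectation_from_counts(c3, "II"), 1)
  expect_error(expectation_from_counts(c3, "XZ"), "diagonal")
  expect_error(counts(c("00" = 3), 5), "shots")
})

test_that("estimate_operator is exact on exact populations", {
  h <- build_hamiltonian(h2_integrals())
  groups <- pauli_groups(h, "qwc")
  set.seed(12)
  psi <- complex(real = rnorm(16), imaginary = rnorm(16))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  cl <- lapply(groups, function(g) {
    exact_counts(simulate_statevector(rotation_circuit(g), psi0 = psi))
  })
  est <- estimate_operator(h, groups, cl)
  exact <- Re(Conj(psi) %*% omat_of_ps(h) %*% psi)[1, 1]
  expect_equal(est, exact, tolerance = 1e-10)
  # identity-only operator returns its coefficient regardless of counts
  idop <- pauli_sum("IIII", 0.25)
  gid <- pauli_groups(idop, "qwc")
  expect_equal(estimate_operator(idop, gid,
                                 list(counts(c("0000" = 7), 7))), 0.25)
  expect_error(estimate_operator(h, groups[-1], cl[-1]), "cover")
})

test_that("regrouping leaves exact-population estimates unchanged", {
  h <- build_hamiltonian(h2_integrals())
  set.seed(13)
  psi <- complex(real = rnorm(16), imaginary = rnorm(16))
  psi <- psi / sqrt(sum(Mod(psi)^2))
  ests <- vapply(list(pauli_groups(h, "qwc"),
                      rev(pauli_groups(h, "qwc"))), function(groups) {
    cl <- lapply(groups, function(g) {
      exact_counts(simulate_statevector(rotation_circuit(g), psi0 = psi))
    })
    estimate_operator(h, groups, cl)
  }, numeric(1))
  expect_equal(ests[[1]], ests[[2]], tolerance = 1e-12)
})

test_that("sampling error of the estimator scales as 1/sqrt(shots)", {
  h <- build_hamiltonian(h2_integrals())
  groups <- pauli_groups(h, "qwc")
  ref <- reference_state("0011")   # doubly excited determinant: nonzero variance
  ans <- uccsd_ansatz("1100", 4, 2)
  psi0 <- simulate_statevector(prepare_reference(ref, 4))
  psi <- fsvqe:::.ucc_apply(psi0, ans$terms, c(0, 0, 0.35))
  exact <- Re(Conj(psi) %*% omat_of_ps(h) %*% psi)[1, 1]
  shots_grid <- c(200, 800, 3200, 12800)
  set.seed(14)
  rmse <- vapply(shots_grid, function(s) {
    errs <- replicate(40, {
      cl <- lapply(groups, function(g) {
        sample_counts(simulate_statevector(rotation_circuit(g), psi0 = psi), s)
      })
      estimate_operator(h, groups, cl) - exact
    })
    sqrt(mean(errs^2))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(rmse) ~ log(shots_grid)))[[2]]
  expect_lt(abs(slope + 0.5), 0.12)
})
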