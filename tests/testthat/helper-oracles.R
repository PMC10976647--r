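# Independent dense-matrix oracles used across the suite. These are
# written directly from the definitions (explicit 2x2 matrices,
# Kronecker products, eigendecompositions) and never call the package's
# Pauli plumbing beyond reading labels.

.SIG <- list(
  I = diag(2) + 0i,
  X = matrix(c(0, 1, 1, 0), 2) + 0i,
  Y = matrix(c(0+0i, 0-1i, 0+1i, 0+0i), 2, byrow = TRUE),
  Z = diag(c(1, -1)) + 0i)

# dense matrix of a Pauli label (qubit 0 = leftmost = most significant)
omat <- function(label) {
  Reduce(kronecker, .SIG[strsplit(label, "")[[1]]])
}

# dense matrix of a label/coefficient list
osum <- function(labels, coeffs) {
  m <- matrix(0+0i, 2^nchar(labels[[1]]), 2^nchar(labels[[1]]))
  for (i in seq_along(labels)) m <- m + coeffs[[i]] * omat(labels[[i]])
  m
}

omat_of_ps <- function(s) osum(s$labels, s$coeffs)

# exp(A) for anti-Hermitian A via eigendecomposition of iA
expm_antiherm <- function(A) {
  Hm <- 1i * A
  e <- eigen(Hm, symmetric = TRUE)
  e$vectors %*% diag(exp(-1i * e$values), nrow(A)) %*% Conj(t(e$vectors))
}

# random Hermitian pauli_sum on n qubits with k terms (fixed RNG caller)
random_herm_ps <- function(n, k) {
  labs <- unique(replicate(k, paste0(sample(c("I", "X", "Y", "Z"), n,
                                            replace = TRUE), collapse = "")))
  pauli_sum(labs, stats::runif(length(labs), -1, 1), n)
}

basis_vec <- function(bitstring) {
  n <- nchar(bitstring)
  v <- complex(2^n)
  v[strtoi(bitstring, base = 2) + 1] <- 1
  v
}

# --- occupation-number-basis CI oracle -----------------------------------
# Builds the second-quantized Hamiltonian matrix directly in the
# occupation basis by applying ladder operators to basis states with
# explicit fermionic sign bookkeeping; independent of the JW mapping.

.occ_bits <- function(idx, N) {
  # bit of spin-orbital p (0-based) = MSB-first as in the package labels
  vapply(0:(N - 1), function(p) bitwAnd(bitwShiftR(idx, N - 1 - p), 1L),
         integer(1))
}

# apply a_p (dagger = FALSE) or a^dagger_p to |idx>; returns list(sign, idx)
# or NULL if annihilated
.ladder_occ <- function(idx, p, dagger, N) {
  bits <- .occ_bits(idx, N)
  if (dagger && bits[p + 1] == 1L) return(NULL)
  if (!dagger && bits[p + 1] == 0L) return(NULL)
  sgn <- if (p > 0 && sum(bits[seq_len(p)]) %% 2 == 1) -1 else 1
  list(sign = sgn, idx = bitwXor(idx, bitwShiftL(1L, N - 1 - p)))
}

ci_hamiltonian_matrix <- function(mi) {
  N <- mi$n_spin_orbitals
  dim <- 2^N
  H <- matrix(0, dim, dim)
  for (col in 0:(dim - 1)) {
    # one-body
    for (p in 0:(N - 1)) for (q in 0:(N - 1)) {
      c1 <- mi$one_body[p + 1, q + 1]
      if (abs(c1) < 1e-14) next
      s1 <- .ladder_occ(col, q, FALSE, N)
      if (is.null(s1)) next
      s2 <- .ladder_occ(s1$idx, p, TRUE, N)
      if (is.null(s2)) next
      H[s2$idx + 1, col + 1] <- H[s2$idx + 1, col + 1] + c1 * s1$sign * s2$sign
    }
    # two-body, physicist notation: 1/2 <pq|rs> adag_p adag_q a_s a_r
    for (p in 0:(N - 1)) for (q in 0:(N - 1)) {
      if (p == q) next
      for (r in 0:(N - 1)) for (s in 0:(N - 1)) {
        if (r == s) next
        g <- mi$two_body[p + 1, q + 1, r + 1, s + 1]
        if (abs(g) < 1e-14) next
        t1 <- .ladder_occ(col, r, FALSE, N)
        if (is.null(t1)) next
        t2 <- .ladder_occ(t1$idx, s, FALSE, N)
        if (is.null(t2)) next
        t3 <- .ladder_occ(t2$idx, q, TRUE, N)
        if (is.null(t3)) next
        t4 <- .ladder_occ(t3$idx, p, TRUE, N)
        if (is.null(t4)) next
        H[t4$idx + 1, col + 1] <- H[t4$idx + 1, col + 1] +
          0.5 * g * t1$sign * t2$sign * t3$sign * t4$sign
      }
    }
  }
  H + mi$e_nuclear * diag(dim)
}

# shared small fixtures
h2_integrals <- function() read_integrals(fixture_path("H2", 0.74))
lih_integrals <- function() read_integrals(fixture_path("LiH", 1.60))

KCAL <- 627.5094740631
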