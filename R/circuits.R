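# Reference-state preparation, the ordered Trotterized UCC ansatz
# compiled to Pauli gadgets, and three simulation backends: exact
# statevector, finite-shot sampling, and a density-matrix backend under
# a scaled depolarizing + thermal-relaxation noise model.

# circuit container -------------------------------------------------------

#' Create an empty parameterized circuit
#'
#' Gates are stored in application order. Rz gates either carry a fixed
#' `angle` or reference a parameter `slot`; the bound rotation angle is
#' `mult * theta[slot]`.
#'
#' @param n_qubits number of qubits.
#' @return object of class `quantum_circuit`.
#' @export
empty_circuit <- function(n_qubits) {
  structure(list(gates = list(), n_qubits = as.integer(n_qubits),
                 n_slots = 0L), class = "quantum_circuit")
}

#' Append a gate to a circuit
#'
#' @param qc a `quantum_circuit`.
#' @param type one of `"X"`, `"Z"`, `"H"`, `"S"`, `"SDG"`, `"RZ"`,
#'   `"CNOT"`.
#' @param q target qubit (control for CNOT), 0-based.
#' @param q2 CNOT target qubit.
#' @param angle fixed Rz angle (radians).
#' @param slot parameter slot index (1-based) for a parameterized Rz.
#' @param mult multiplier applied to the slot value.
#' @return the extended circuit.
#' @export
qc_gate <- function(qc, type, q, q2 = NA_integer_, angle = NA_real_,
                    slot = NA_integer_, mult = NA_real_) {
  qc$gates[[length(qc$gates) + 1L]] <-
    list(type = type, q = as.integer(q), q2 = as.integer(q2),
         angle = angle, slot = slot, mult = mult)
  if (!is.na(slot)) qc$n_slots <- max(qc$n_slots, as.integer(slot))
  qc
}

#' Concatenate circuits
#' @param a,b `quantum_circuit`s on the same register.
#' @return combined circuit (`a` then `b`).
#' @export
qc_append <- function(a, b) {
  stopifnot(a$n_qubits == b$n_qubits)
  a$gates <- c(a$gates, b$gates)
  a$n_slots <- max(a$n_slots, b$n_slots)
  a
}

#' @export
print.quantum_circuit <- function(x, ...) {
  ncx <- sum(vapply(x$gates, function(g) g$type == "CNOT", logical(1)))
  cat(sprintf("<quantum_circuit: %d qubit(s), %d gate(s) (%d CNOT), %d slot(s)>\n",
              x$n_qubits, length(x$gates), ncx, x$n_slots))
  invisible(x)
}

#' Number of gates in a circuit
#' @param qc a `quantum_circuit`.
#' @return integer gate count.
#' @export
gate_count <- function(qc) length(qc$gates)

#' Serialize a circuit to plain text (one gate per line)
#' @param qc a `quantum_circuit`.
#' @param path output file path.
#' @export
write_circuit <- function(qc, path) {
  lines <- c(sprintf("n_qubits %d", qc$n_qubits),
             vapply(qc$gates, function(g) {
               paste(g$type, g$q, g$q2, g$angle, g$slot, g$mult)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a circuit serialized by [write_circuit()]
#' @param path file path.
#' @return a `quantum_circuit`.
#' @export
read_circuit <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(lines[[1L]], " ")[[1L]][[2L]])
  qc <- empty_circuit(n)
  for (ln in lines[-1L]) {
    p <- strsplit(ln, " ")[[1L]]
    qc <- qc_gate(qc, p[[1L]], as.integer(p[[2L]]),
                  q2 = suppressWarnings(as.integer(p[[3L]])),
                  angle = suppressWarnings(as.numeric(p[[4L]])),
                  slot = suppressWarnings(as.integer(p[[5L]])),
                  mult = suppressWarnings(as.numeric(p[[6L]])))
  }
  qc
}

# excitations -------------------------------------------------------------

.spin_of <- function(p) p %% 2L   # 0 = alpha, 1 = beta (interleaved ordering)

#' Enumerate ordered UCCSD excitations from a reference determinant
#'
#' Iterates the occupied spin-orbital indices `j` in ascending order;
#' for each `j` emits all not-yet-emitted spin-conserving single
#' excitations involving `j`, then all such double excitations involving
#' `j`. This fixed ordering makes the first-order Trotterized UCC ansatz
#' exact in principle for an appropriate parameterization.
#'
#' @param ref_det occupation bitstring of the reference determinant
#'   (leftmost character = qubit 0).
#' @param n number of spin-orbitals (qubits).
#' @return list of excitation objects: `rank` (1 or 2), `occ`, `virt`
#'   (0-based index vectors) and `slot` (parameter index).
#' @export
enumerate_excitations <- function(ref_det, n) {
  bits <- as.integer(strsplit(ref_det, "")[[1L]])
  if (length(bits) != n) stop("determinant length does not match n")
  occ <- which(bits == 1L) - 1L
  virt <- which(bits == 0L) - 1L
  excs <- list()
  seen <- character(0)
  add <- function(rank, o, v) {
    key <- paste(rank, paste(o, collapse = ","), paste(v, collapse = ","))
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    excs[[length(excs) + 1L]] <<- list(rank = rank, occ = o, virt = v,
                                       slot = length(excs) + 1L)
  }
  for (j in occ) {
    for (a in virt) {
      if (.spin_of(a) == .spin_of(j)) add(1L, j, a)
    }
    for (i2 in occ) {
      if (i2 == j) next
      o <- sort(c(j, i2))
      for (a in virt) for (b in virt) {
        if (a >= b) next
        if (identical(sort(c(.spin_of(o[1]), .spin_of(o[2]))),
                      sort(c(.spin_of(a), .spin_of(b))))) {
          add(2L, o, c(a, b))
        }
      }
    }
  }
  excs
}

#' Anti-Hermitian generator of one excitation under JW mapping
#'
#' Returns the JW image of \eqn{\hat T_e - \hat T_e^\dagger} where
#' \eqn{\hat T_e = a^\dagger_a a_i} (single) or
#' \eqn{a^\dagger_a a^\dagger_b a_j a_i} (double). Coefficients are
#' purely imaginary and the matrix realization is anti-Hermitian.
#'
#' @param e an excitation from [enumerate_excitations()].
#' @param n number of qubits.
#' @return a `pauli_sum`.
#' @export
excitation_generator <- function(e, n) {
  if (e$rank == 1L) {
    t_op <- ps_multiply(jw_ladder(e$virt[[1L]], TRUE, n),
                        jw_ladder(e$occ[[1L]], FALSE, n), tol = 0)
  } else {
    t_op <- ps_multiply(
      ps_multiply(jw_ladder(e$virt[[1L]], TRUE, n),
                  jw_ladder(e$virt[[2L]], TRUE, n), tol = 0),
      ps_multiply(jw_ladder(e$occ[[2L]], FALSE, n),
                  jw_ladder(e$occ[[1L]], FALSE, n), tol = 0), tol = 0)
  }
  dag <- t_op
  dag$coeffs <- Conj(dag$coeffs)   # adjoint of a Pauli sum conjugates coeffs
  gen <- ps_add(t_op, ps_scale(dag, -1), tol = 1e-14)
  gen
}

# per-excitation Trotter factors: lexicographically ordered strings with
# real prefactors g (generator term = i * g * P). Each string's action
# on a statevector is precomputed as a signed permutation:
# (P psi) = ph * psi[ip].
.ucc_terms <- function(excitations, n) {
  dim <- 2L^n
  lapply(excitations, function(e) {
    gen <- excitation_generator(e, n)
    ord <- order(gen$labels, method = "radix")
    labels <- gen$labels[ord]
    perms <- lapply(labels, function(lab) {
      idx <- 0:(dim - 1L)
      codes <- .label_codes(lab, n)[1L, ]
      mask <- 0L
      for (q in seq_len(n)) {
        if (codes[[q]] %in% c(1L, 2L)) {
          mask <- bitwOr(mask, bitwShiftL(1L, n - q))
        }
      }
      src <- bitwXor(idx, mask)          # (P psi)[j] = phase[src] psi[src]
      p <- rep(1 + 0i, dim)              # phase picked up by source state
      for (q in seq_len(n)) {
        bit <- bitwAnd(bitwShiftR(idx, n - q), 1L)
        code <- codes[[q]]
        if (code == 2L) p <- p * ifelse(bit == 0L, 1i, -1i)
        else if (code == 3L) p <- p * ifelse(bit == 0L, 1, -1)
      }
      list(ip = src + 1L, ph = p[src + 1L])
    })
    list(labels = labels, g = Im(gen$coeffs[ord]), slot = e$slot,
         perms = perms)
  })
}

#' Compile the ordered Trotterized UCC ansatz to Pauli gadgets
#'
#' Emits one Pauli gadget per generator string (basis changes, CNOT
#' ladder, central Rz, mirrored uncompute). The enumeration order of
#' the excitations fixes the operator product: the first-enumerated
#' excitation is the leftmost factor, i.e. the one applied last to the
#' reference, so the gadgets appear in the circuit in reverse
#' enumeration order. (Either reading of "ordered product" is
#' internally consistent; this one was selected because it makes the
#' disentangled ansatz exactly expressive for the largest number of the
#' shipped reference states.) Within one excitation the generator
#' strings mutually commute and are taken in lexicographic label order.
#' The gadget for a weight-w string uses 2(w-1) CNOT gates. Slot angles
#' are divided by the parameter-scaling constant `c_scale` before
#' binding, so the optimizer works on variables in (-c pi, c pi] while
#' physical angles stay in (-pi, pi].
#'
#' @param excitations list from [enumerate_excitations()].
#' @param n_qubits register size.
#' @param c_scale parameter scaling constant (default 2).
#' @return a `quantum_circuit` with one slot per excitation.
#' @export
compile_ucc <- function(excitations, n_qubits, c_scale = 2) {
  terms <- rev(.ucc_terms(excitations, n_qubits))
  gates <- list()
  push <- function(...) gates[[length(gates) + 1L]] <<- list(...)
  for (tt in terms) {
    for (k in seq_along(tt$labels)) {
      lab <- strsplit(tt$labels[[k]], "")[[1L]]
      active <- which(lab != "I") - 1L
      # exp(i g theta P) = gadget with Rz angle alpha = -2 g theta
      mult <- -2 * tt$g[[k]] / c_scale
      for (q in active) {
        if (lab[[q + 1L]] == "X") {
          push(type = "H", q = q, q2 = NA_integer_, angle = NA_real_,
               slot = NA_integer_, mult = NA_real_)
        } else if (lab[[q + 1L]] == "Y") {
          push(type = "SDG", q = q, q2 = NA_integer_, angle = NA_real_,
               slot = NA_integer_, mult = NA_real_)
          push(type = "H", q = q, q2 = NA_integer_, angle = NA_real_,
               slot = NA_integer_, mult = NA_real_)
        }
      }
      if (length(active) > 1L) {
        for (i in seq_len(length(active) - 1L)) {
          push(type = "CNOT", q = active[[i]], q2 = active[[i + 1L]],
               angle = NA_real_, slot = NA_integer_, mult = NA_real_)
        }
      }
      push(type = "RZ", q = active[[length(active)]], q2 = NA_integer_,
           angle = NA_real_, slot = tt$slot, mult = mult)
      if (length(active) > 1L) {
        for (i in rev(seq_len(length(active) - 1L))) {
          push(type = "CNOT", q = active[[i]], q2 = active[[i + 1L]],
               angle = NA_real_, slot = NA_integer_, mult = NA_real_)
        }
      }
      for (q in rev(active)) {
        if (lab[[q + 1L]] == "X") {
          push(type = "H", q = q, q2 = NA_integer_, angle = NA_real_,
               slot = NA_integer_, mult = NA_real_)
        } else if (lab[[q + 1L]] == "Y") {
          push(type = "H", q = q, q2 = NA_integer_, angle = NA_real_,
               slot = NA_integer_, mult = NA_real_)
          push(type = "S", q = q, q2 = NA_integer_, angle = NA_real_,
               slot = NA_integer_, mult = NA_real_)
        }
      }
    }
  }
  structure(list(gates = gates, n_qubits = as.integer(n_qubits),
                 n_slots = length(excitations)), class = "quantum_circuit")
}

# reference states ---------------------------------------------------------

#' Construct a reference state
#'
#' A single determinant, or an equal-weight superposition
#' \eqn{(|D_1\rangle \pm |D_2\rangle)/\sqrt 2} of two determinants
#' sharing the electron count.
#'
#' @param determinants character vector of one or two occupation
#'   bitstrings (leftmost character = qubit 0).
#' @param amplitudes matching real weights; defaults to 1 or
#'   `c(1, 1)/sqrt(2)`.
#' @return object of class `reference_state`.
#' @export
reference_state <- function(determinants, amplitudes = NULL) {
  k <- length(determinants)
  if (k < 1L || k > 2L) stop("reference states support at most 2 determinants")
  if (is.null(amplitudes)) {
    amplitudes <- if (k == 1L) 1 else c(1, 1) / sqrt(2)
  }
  if (abs(sum(amplitudes^2) - 1) > 1e-10) stop("amplitudes must be normalized")
  nel <- vapply(determinants, function(d) {
    sum(strsplit(d, "")[[1L]] == "1")
  }, numeric(1))
  if (length(unique(nel)) != 1L) {
    stop("determinants differ in electron count")
  }
  structure(list(determinants = determinants, amplitudes = amplitudes),
            class = "reference_state")
}

#' Compile a reference state to a preparation circuit
#'
#' A single determinant becomes X gates on the occupied qubits; two
#' equal-weight determinants become a Hadamard + CNOT + X pattern
#' preparing \eqn{(|D_1\rangle \pm |D_2\rangle)/\sqrt 2} exactly.
#'
#' @param r a `reference_state`.
#' @param n_qubits register size.
#' @return a `quantum_circuit`.
#' @export
prepare_reference <- function(r, n_qubits) {
  qc <- empty_circuit(n_qubits)
  dets <- lapply(r$determinants, function(d) as.integer(strsplit(d, "")[[1L]]))
  if (length(dets) == 1L) {
    for (q in which(dets[[1L]] == 1L) - 1L) qc <- qc_gate(qc, "X", q)
    return(qc)
  }
  if (any(abs(abs(r$amplitudes) - 1 / sqrt(2)) > 1e-10)) {
    stop("two-determinant references must be equal weight")
  }
  d1 <- dets[[1L]]; d2 <- dets[[2L]]
  a1 <- r$amplitudes[[1L]]; a2 <- r$amplitudes[[2L]]
  diffs <- which(d1 != d2)
  if (length(diffs) == 0L) stop("determinants are identical")
  qstar <- diffs[[1L]]
  if (d1[[qstar]] == 1L) {        # put the branch-0 determinant first
    tmp <- d1; d1 <- d2; d2 <- tmp
    tmpa <- a1; a1 <- a2; a2 <- tmpa
  }
  if (a1 < 0) { a1 <- -a1; a2 <- -a2 }   # global phase
  qc <- qc_gate(qc, "H", qstar - 1L)
  if (a2 < 0) qc <- qc_gate(qc, "Z", qstar - 1L)
  for (p in setdiff(diffs, qstar)) {
    qc <- qc_gate(qc, "CNOT", qstar - 1L, q2 = p - 1L)
  }
  for (p in which(d1 == 1L)) qc <- qc_gate(qc, "X", p - 1L)
  qc
}

# statevector backend ------------------------------------------------------

.bitstrings <- function(n) {
  idx <- 0:(2L^n - 1L)
  vapply(idx, function(i) {
    paste(rev(as.integer(intToBits(i))[seq_len(n)]), collapse = "")
  }, character(1))
}

.det_index <- function(bitstring) {
  strtoi(bitstring, base = 2L)    # leftmost char = qubit 0 = MSB
}

.gate_matrix_1q <- function(type, angle = NA) {
  switch(type,
         X = .PAULI_MATS$X,
         Z = .PAULI_MATS$Z,
         H = matrix(c(1, 1, 1, -1), 2) / sqrt(2) + 0i,
         S = diag(c(1, 1i)),
         SDG = diag(c(1, -1i)),
         RZ = diag(c(exp(-1i * angle / 2), exp(1i * angle / 2))),
         stop("unknown 1-qubit gate ", type))
}

.apply_1q <- function(psi, U, q, n) {
  bit <- bitwShiftL(1L, n - q - 1L)
  idx <- 0:(length(psi) - 1L)
  i0 <- which(bitwAnd(idx, bit) == 0L)
  i1 <- i0 + bit
  v0 <- psi[i0]; v1 <- psi[i1]
  psi[i0] <- U[1, 1] * v0 + U[1, 2] * v1
  psi[i1] <- U[2, 1] * v0 + U[2, 2] * v1
  psi
}

.apply_cnot <- function(psi, qc_, qt, n) {
  bitc <- bitwShiftL(1L, n - qc_ - 1L)
  bitt <- bitwShiftL(1L, n - qt - 1L)
  idx <- 0:(length(psi) - 1L)
  sel <- bitwAnd(idx, bitc) > 0L & bitwAnd(idx, bitt) == 0L
  ia <- which(sel); ib <- ia + bitt
  tmp <- psi[ia]; psi[ia] <- psi[ib]; psi[ib] <- tmp
  psi
}

.apply_rz <- function(psi, q, angle, n) {
  bit <- bitwShiftL(1L, n - q - 1L)
  idx <- 0:(length(psi) - 1L)
  ph <- ifelse(bitwAnd(idx, bit) == 0L, exp(-1i * angle / 2),
               exp(1i * angle / 2))
  psi * ph
}

.bound_angle <- function(g, theta) {
  if (!is.na(g$slot)) g$mult * theta[[g$slot]] else g$angle
}

#' Exact statevector simulation of a circuit
#'
#' @param qc a `quantum_circuit` with at most 12 qubits.
#' @param theta parameter vector bound to the Rz slots (slot values are
#'   on the scaled range; gadget multipliers absorb the scaling).
#' @param psi0 optional initial state; defaults to `|0...0>`.
#' @return complex amplitude vector of length `2^n`, norm 1.
#' @export
simulate_statevector <- function(qc, theta = numeric(0), psi0 = NULL) {
  n <- qc$n_qubits
  if (n > 12L) stop("statevector backend guarded at 12 qubits")
  if (qc$n_slots > length(theta)) stop("theta shorter than the slot count")
  psi <- if (is.null(psi0)) {
    v <- complex(2L^n); v[[1L]] <- 1 + 0i; v
  } else psi0
  for (g in qc$gates) {
    psi <- switch(g$type,
      CNOT = .apply_cnot(psi, g$q, g$q2, n),
      RZ = .apply_rz(psi, g$q, .bound_angle(g, theta), n),
      .apply_1q(psi, .gate_matrix_1q(g$type), g$q, n))
  }
  psi
}

# fast exact UCC application: each Trotter factor exp(i g theta P) acts as
# cos(g theta) I + i sin(g theta) P, P a precomputed signed permutation.
.ucc_apply <- function(psi, terms, theta_phys) {
  for (tt in terms) {
    th <- theta_phys[[tt$slot]]
    if (th == 0) next
    for (k in seq_along(tt$labels)) {
      beta <- tt$g[[k]] * th
      if (beta == 0) next
      pp <- tt$perms[[k]]
      psi <- cos(beta) * psi + (1i * sin(beta)) * (pp$ph * psi[pp$ip])
    }
  }
  psi
}

#' Sample measurement counts from a statevector
#'
#' Multinomial draw from the state's computational-basis populations.
#'
#' @param psi complex amplitude vector.
#' @param shots number of shots (>= 1).
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used (callers seed once for a whole run).
#' @return a `counts` object.
#' @export
sample_counts <- function(psi, shots, seed = NULL) {
  if (shots < 1) stop("shots must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  p <- Mod(psi)^2
  p <- p / sum(p)
  n <- as.integer(round(log2(length(psi))))
  draw <- stats::rmultinom(1, shots, p)[, 1L]
  keep <- draw > 0
  counts(stats::setNames(draw[keep], .bitstrings(n)[keep]), shots)
}

#' Exact populations of a statevector as a counts object
#'
#' Probability-weighted histogram with `shots = 1`; feeding it to
#' [expectation_from_counts()] gives exact expectations.
#'
#' @param psi complex amplitude vector.
#' @param tol populations below this are dropped.
#' @return a `counts` object with fractional histogram.
#' @export
exact_counts <- function(psi, tol = 1e-15) {
  p <- Mod(psi)^2
  p <- p / sum(p)
  n <- as.integer(round(log2(length(psi))))
  keep <- p > tol
  counts(stats::setNames(p[keep], .bitstrings(n)[keep]), shots = 1)
}

# noise model --------------------------------------------------------------

#' Construct noise-model parameters
#'
#' Defaults are the order of magnitude of present superconducting
#' hardware: the experimental row of the scaling table (lambda = 1).
#' Relaxation times in microseconds, gate times in nanoseconds.
#'
#' @param T1,T2 relaxation and total coherence times (us); `T2 <= 2*T1`.
#' @param t_gate1,t_gate2 one-/two-qubit gate durations (ns).
#' @param p1,p2 one-/two-qubit depolarizing probabilities.
#' @param p_spam per-qubit readout flip probability.
#' @param lambda_scale scale factor in `[0, 1]` recorded on the object.
#' @param T1_ideal,T2_ideal asymptotic noiseless values (us) used by the
#'   geometric interpolation of [scale_noise()].
#' @return object of class `noise_params`.
#' @export
noise_params <- function(T1 = 290, T2 = 145, t_gate1 = 35, t_gate2 = 300,
                         p1 = 1e-4, p2 = 1e-3, p_spam = 1e-2,
                         lambda_scale = 1, T1_ideal = 2000, T2_ideal = 1000) {
  if (T2 > 2 * T1 + 1e-12) stop("T2 must not exceed 2*T1")
  probs <- c(p1, p2, p_spam)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(T1 = T1, T2 = T2, t_gate1 = t_gate1, t_gate2 = t_gate2,
                 p1 = p1, p2 = p2, p_spam = p_spam,
                 lambda_scale = lambda_scale,
                 T1_ideal = T1_ideal, T2_ideal = T2_ideal),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf(
    "<noise_params (lambda = %g): T1 = %.4g us, T2 = %.4g us, tg1 = %.4g ns, tg2 = %.4g ns,\n  p1 = %.3g, p2 = %.3g, p_spam = %.3g>\n",
    x$lambda_scale, x$T1, x$T2, x$t_gate1, x$t_gate2, x$p1, x$p2, x$p_spam))
  invisible(x)
}

#' Scale noise parameters by a factor lambda
#'
#' Interpolates between the noiseless device (`lambda = 0`) and the
#' experimental values carried by `base` (`lambda = 1`): geometrically
#' for T1 and T2, \eqn{T(\lambda) = T_{ideal}^{1-\lambda}
#' T_{exp}^{\lambda}}, and linearly for all other parameters.
#'
#' @param base `noise_params` holding the experimental (lambda = 1) values.
#' @param lambda scale factor in `[0, 1]`.
#' @return scaled `noise_params`.
#' @export
scale_noise <- function(base, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  noise_params(
    T1 = base$T1_ideal^(1 - lambda) * base$T1^lambda,
    T2 = base$T2_ideal^(1 - lambda) * base$T2^lambda,
    t_gate1 = base$t_gate1 * lambda,
    t_gate2 = base$t_gate2 * lambda,
    p1 = base$p1 * lambda,
    p2 = base$p2 * lambda,
    p_spam = base$p_spam * lambda,
    lambda_scale = lambda,
    T1_ideal = base$T1_ideal, T2_ideal = base$T2_ideal)
}

# full-register operator helpers, cached per simulation
.full_1q_op <- function(U, q, n) {
  left <- if (q > 0L) diag(2L^q) else 1
  right <- if (q < n - 1L) diag(2L^(n - q - 1L)) else 1
  kronecker(kronecker(left, U), right)
}

.full_cnot_op <- function(qc_, qt, n) {
  dim <- 2L^n
  bitc <- bitwShiftL(1L, n - qc_ - 1L)
  bitt <- bitwShiftL(1L, n - qt - 1L)
  idx <- 0:(dim - 1L)
  target <- ifelse(bitwAnd(idx, bitc) > 0L, bitwXor(idx, bitt), idx)
  P <- matrix(0+0i, dim, dim)
  P[cbind(target + 1L, idx + 1L)] <- 1
  P
}

.thermal_kraus <- function(t_ns, T1_us, T2_us) {
  t <- t_ns * 1e-3
  g_ad <- if (is.finite(T1_us)) 1 - exp(-t / T1_us) else 0
  inv_tphi <- 1 / T2_us - 1 / (2 * T1_us)
  if (inv_tphi < -1e-12) stop("T2 exceeds 2*T1")
  p_z <- if (inv_tphi > 0) (1 - exp(-t * inv_tphi)) / 2 else 0
  A0 <- matrix(c(1, 0, 0, sqrt(1 - g_ad)), 2) + 0i
  A1 <- matrix(c(0, 0, sqrt(g_ad), 0), 2) + 0i   # column-major: |0><1|
  D0 <- sqrt(1 - p_z) * .PAULI_MATS$I
  D1 <- sqrt(p_z) * .PAULI_MATS$Z
  list(D0 %*% A0, D0 %*% A1, D1 %*% A0, D1 %*% A1)
}

.apply_kraus_1q <- function(rho, kraus, q, n) {
  out <- matrix(0+0i, nrow(rho), ncol(rho))
  for (K in kraus) {
    Kf <- .full_1q_op(K, q, n)
    out <- out + Kf %*% rho %*% Conj(t(Kf))
  }
  out
}

.apply_depol_1q <- function(rho, p, q, n, cache) {
  if (p == 0) return(rho)
  key <- paste0("pauli1_", q)
  if (is.null(cache[[key]])) {
    cache[[key]] <- lapply(.PAULI_MATS[c("X", "Y", "Z")],
                           .full_1q_op, q = q, n = n)
  }
  mix <- Reduce(`+`, lapply(cache[[key]], function(P) P %*% rho %*% P))
  (1 - p) * rho + (p / 3) * mix
}

.apply_depol_2q <- function(rho, p, qa, qb, n, cache) {
  if (p == 0) return(rho)
  key <- paste0("pauli2_", qa, "_", qb)
  if (is.null(cache[[key]])) {
    ops <- list()
    for (a in .PAULI_LETTERS) for (b in .PAULI_LETTERS) {
      if (a == "I" && b == "I") next
      ops[[length(ops) + 1L]] <-
        .full_1q_op(.PAULI_MATS[[a]], qa, n) %*%
        .full_1q_op(.PAULI_MATS[[b]], qb, n)
    }
    cache[[key]] <- ops
  }
  mix <- Reduce(`+`, lapply(cache[[key]], function(P) P %*% rho %*% P))
  (1 - p) * rho + (p / 15) * mix
}

#' Density-matrix simulation under the scaled noise model
#'
#' After each gate, applies a depolarizing channel (probability `p1` or
#' `p2`) followed by thermal relaxation (amplitude damping from T1) and
#' pure dephasing (rate `1/T2 - 1/(2 T1)`; T2 is the total coherence
#' time) over the gate duration, to the touched qubits only. Readout
#' flips each measured bit independently with probability `p_spam`.
#'
#' @param qc a `quantum_circuit` with at most 8 qubits.
#' @param theta parameter vector for the Rz slots.
#' @param noise a `noise_params` object.
#' @param shots number of measurement shots.
#' @param seed optional integer seed for the sampling step.
#' @param return_rho when `TRUE`, also return the final density matrix.
#' @return a `counts` object (with attribute `rho` when requested).
#' @export
simulate_noisy <- function(qc, theta = numeric(0), noise = noise_params(),
                           shots = 1000, seed = NULL, return_rho = FALSE) {
  n <- qc$n_qubits
  if (n > 8L) stop("density-matrix backend guarded at 8 qubits")
  if (noise$T2 > 2 * noise$T1 + 1e-12) stop("T2 must not exceed 2*T1")
  dim <- 2L^n
  rho <- matrix(0+0i, dim, dim)
  rho[1L, 1L] <- 1
  cache <- new.env(parent = emptyenv())
  th1 <- .thermal_kraus(noise$t_gate1, noise$T1, noise$T2)
  th2 <- .thermal_kraus(noise$t_gate2, noise$T1, noise$T2)
  noiseless1 <- noise$p1 == 0 && noise$t_gate1 == 0
  noiseless2 <- noise$p2 == 0 && noise$t_gate2 == 0
  for (g in qc$gates) {
    if (g$type == "CNOT") {
      key <- paste0("cnot_", g$q, "_", g$q2)
      if (is.null(cache[[key]])) cache[[key]] <- .full_cnot_op(g$q, g$q2, n)
      U <- cache[[key]]
      rho <- U %*% rho %*% Conj(t(U))
      if (!noiseless2) {
        rho <- .apply_depol_2q(rho, noise$p2, g$q, g$q2, n, cache)
        rho <- .apply_kraus_1q(rho, th2, g$q, n)
        rho <- .apply_kraus_1q(rho, th2, g$q2, n)
      }
    } else {
      ang <- if (g$type == "RZ") .bound_angle(g, theta) else NA
      key <- if (g$type == "RZ") NULL else paste0("g_", g$type, "_", g$q)
      U <- if (!is.null(key) && !is.null(cache[[key]])) {
        cache[[key]]
      } else {
        Uf <- .full_1q_op(.gate_matrix_1q(g$type, ang), g$q, n)
        if (!is.null(key)) cache[[key]] <- Uf
        Uf
      }
      rho <- U %*% rho %*% Conj(t(U))
      if (!noiseless1) {
        rho <- .apply_depol_1q(rho, noise$p1, g$q, n, cache)
        rho <- .apply_kraus_1q(rho, th1, g$q, n)
      }
    }
  }
  tr <- Re(sum(diag(rho)))
  if (abs(tr - 1) > 1e-8) stop("density matrix trace drifted: ", tr)
  probs <- pmax(Re(diag(rho)), 0)
  probs <- probs / sum(probs)
  if (noise$p_spam > 0) {
    flip <- matrix(c(1 - noise$p_spam, noise$p_spam,
                     noise$p_spam, 1 - noise$p_spam), 2)
    A <- Reduce(kronecker, rep(list(flip), n))
    probs <- as.vector(A %*% probs)
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- stats::rmultinom(1, shots, probs)[, 1L]
  keep <- draw > 0
  out <- counts(stats::setNames(draw[keep], .bitstrings(n)[keep]), shots)
  if (return_rho) attr(out, "rho") <- rho
  out
}
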