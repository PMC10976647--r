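# Restricted Hartree-Fock engine for contracted s-type Gaussian bases.
#
# The shipped systems (H2/STO-3G and LiH in an s-orbitals-only minimal
# basis) involve s functions exclusively, for which overlap, kinetic,
# nuclear-attraction and electron-repulsion integrals have closed forms
# built on the Boys function F0. This engine generates the packaged
# integral fixtures; it is not a general-purpose SCF code.

.ANGSTROM_TO_BOHR <- 1.88972612462577

# STO-3G exponents/contractions (s functions; Li 2s taken from the sp
# shell's s contraction, p functions deliberately omitted).
.STO3G <- list(
  H = list(list(exps = c(3.42525091, 0.62391373, 0.16885540),
                coefs = c(0.15432897, 0.53532814, 0.44463454))),
  Li = list(list(exps = c(16.1195750, 2.4362897, 0.6157928),
                 coefs = c(0.15432897, 0.53532814, 0.44463454)),
            list(exps = c(0.6362897, 0.1478601, 0.0480887),
                 coefs = c(-0.09996723, 0.39951283, 0.70011547))))

.ATOMIC_NUMBER <- c(H = 1, Li = 3)

.boys_f0 <- function(x) {
  ifelse(x < 1e-12, 1 - x / 3,
         0.5 * sqrt(pi / pmax(x, 1e-300)) *
           (2 * stats::pnorm(sqrt(2 * pmax(x, 0))) - 1))
}

.prim_norm <- function(a) (2 * a / pi)^0.75

# primitive s-orbital integrals between centers A, B (3-vectors, Bohr)
.prim_overlap <- function(a, b, AB2) {
  (pi / (a + b))^1.5 * exp(-a * b / (a + b) * AB2)
}
.prim_kinetic <- function(a, b, AB2) {
  mu <- a * b / (a + b)
  mu * (3 - 2 * mu * AB2) * .prim_overlap(a, b, AB2)
}
.prim_nuclear <- function(a, b, A, B, C) {
  p <- a + b
  AB2 <- sum((A - B)^2)
  P <- (a * A + b * B) / p
  -2 * pi / p * exp(-a * b / p * AB2) * .boys_f0(p * sum((P - C)^2))
}
.prim_eri <- function(a, b, c, d, A, B, C, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p
  Q <- (c * C + d * D) / q
  2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((A - B)^2) - c * d / q * sum((C - D)^2)) *
    .boys_f0(p * q / (p + q) * sum((P - Q)^2))
}

# basis: list of shells, each list(exps, coefs, center = 3-vector Bohr)
.contracted_s_basis <- function(atoms, coords_bohr) {
  shells <- list()
  for (k in seq_along(atoms)) {
    for (sh in .STO3G[[atoms[[k]]]]) {
      shells[[length(shells) + 1L]] <- list(
        exps = sh$exps,
        coefs = sh$coefs * .prim_norm(sh$exps),
        center = coords_bohr[k, ])
    }
  }
  # renormalize each contracted function
  for (i in seq_along(shells)) {
    s <- shells[[i]]
    norm2 <- 0
    for (u in seq_along(s$exps)) for (v in seq_along(s$exps)) {
      norm2 <- norm2 + s$coefs[u] * s$coefs[v] *
        .prim_overlap(s$exps[u], s$exps[v], 0)
    }
    shells[[i]]$coefs <- s$coefs / sqrt(norm2)
  }
  shells
}

.ao_integrals <- function(shells, atoms, coords_bohr) {
  nbf <- length(shells)
  S <- T_ <- V <- matrix(0, nbf, nbf)
  charges <- .ATOMIC_NUMBER[atoms]
  for (i in seq_len(nbf)) for (j in seq_len(nbf)) {
    si <- shells[[i]]; sj <- shells[[j]]
    AB2 <- sum((si$center - sj$center)^2)
    for (u in seq_along(si$exps)) for (v in seq_along(sj$exps)) {
      cc <- si$coefs[u] * sj$coefs[v]
      S[i, j] <- S[i, j] + cc * .prim_overlap(si$exps[u], sj$exps[v], AB2)
      T_[i, j] <- T_[i, j] + cc * .prim_kinetic(si$exps[u], sj$exps[v], AB2)
      for (k in seq_along(atoms)) {
        V[i, j] <- V[i, j] + cc * charges[[k]] *
          .prim_nuclear(si$exps[u], sj$exps[v], si$center, sj$center,
                        coords_bohr[k, ])
      }
    }
  }
  eri <- array(0, rep(nbf, 4))
  for (i in seq_len(nbf)) for (j in seq_len(nbf))
    for (k in seq_len(nbf)) for (l in seq_len(nbf)) {
      si <- shells[[i]]; sj <- shells[[j]]
      sk <- shells[[k]]; sl <- shells[[l]]
      val <- 0
      for (u in seq_along(si$exps)) for (v in seq_along(sj$exps))
        for (w in seq_along(sk$exps)) for (x in seq_along(sl$exps)) {
          val <- val + si$coefs[u] * sj$coefs[v] * sk$coefs[w] * sl$coefs[x] *
            .prim_eri(si$exps[u], sj$exps[v], sk$exps[w], sl$exps[x],
                      si$center, sj$center, sk$center, sl$center)
        }
      eri[i, j, k, l] <- val
    }
  list(S = S, T = T_, V = V, eri = eri)
}

.nuclear_repulsion <- function(atoms, coords_bohr) {
  z <- .ATOMIC_NUMBER[atoms]
  e <- 0
  n <- length(atoms)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    e <- e + z[[i]] * z[[j]] / sqrt(sum((coords_bohr[i, ] - coords_bohr[j, ])^2))
  }
  e
}

.rhf <- function(S, Hcore, eri, n_electrons, e_nuc,
                 tol = 1e-12, max_iter = 500) {
  nbf <- nrow(S)
  nocc <- n_electrons / 2
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), nbf) %*% t(es$vectors)
  P <- matrix(0, nbf, nbf)
  C <- NULL; eps <- NULL; E_old <- 0
  for (iter in seq_len(max_iter)) {
    G <- matrix(0, nbf, nbf)
    for (m in seq_len(nbf)) for (n in seq_len(nbf)) {
      G[m, n] <- sum(P * (eri[m, n, , ] - 0.5 * eri[m, , , n]))
    }
    F_ <- Hcore + G
    Fp <- t(X) %*% F_ %*% X
    ef <- eigen(Fp, symmetric = TRUE)
    ord <- order(ef$values)                # ascending orbital energies
    C <- X %*% ef$vectors[, ord, drop = FALSE]
    eps <- ef$values[ord]
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    P_new <- 2 * Cocc %*% t(Cocc)
    E_el <- 0.5 * sum(P_new * (Hcore + F_))
    if (max(abs(P_new - P)) < tol && abs(E_el - E_old) < tol) {
      P <- P_new
      break
    }
    P <- P_new; E_old <- E_el
  }
  # fix a deterministic MO sign: largest-magnitude AO component positive
  for (j in seq_len(ncol(C))) {
    k <- which.max(abs(C[, j]))
    if (C[k, j] < 0) C[, j] <- -C[, j]
  }
  G <- matrix(0, nbf, nbf)
  for (m in seq_len(nbf)) for (n in seq_len(nbf)) {
    G[m, n] <- sum(P * (eri[m, n, , ] - 0.5 * eri[m, , , n]))
  }
  E_el <- 0.5 * sum(P * (2 * Hcore + G))
  list(energy = E_el + e_nuc, C = C, eps = eps)
}

# transform AO integrals to spatial-MO basis
.mo_transform <- function(C, Hcore, eri) {
  h_mo <- t(C) %*% Hcore %*% C
  nbf <- nrow(C)
  tmp <- array(0, rep(nbf, 4))
  # (ij|kl) chemist-notation four-index transform, naive loops (nbf <= 3)
  g1 <- array(0, rep(nbf, 4)); g2 <- g1; g3 <- g1; g4 <- g1
  for (i in seq_len(nbf)) for (b in seq_len(nbf))
    for (c_ in seq_len(nbf)) for (d in seq_len(nbf)) {
      g1[i, b, c_, d] <- sum(C[, i] * eri[, b, c_, d])
    }
  for (i in seq_len(nbf)) for (j in seq_len(nbf))
    for (c_ in seq_len(nbf)) for (d in seq_len(nbf)) {
      g2[i, j, c_, d] <- sum(C[, j] * g1[i, , c_, d])
    }
  for (i in seq_len(nbf)) for (j in seq_len(nbf))
    for (k in seq_len(nbf)) for (d in seq_len(nbf)) {
      g3[i, j, k, d] <- sum(C[, k] * g2[i, j, , d])
    }
  for (i in seq_len(nbf)) for (j in seq_len(nbf))
    for (k in seq_len(nbf)) for (l in seq_len(nbf)) {
      g4[i, j, k, l] <- sum(C[, l] * g3[i, j, k, ])
    }
  list(h = h_mo, eri = g4)
}

# spatial MO integrals -> interleaved spin-orbital integrals.
# Spin-orbital p = 2*(i-1) + spin (spin 0 = alpha, 1 = beta), 1-based
# storage index p+1. two_body holds physicist-notation <pq|rs>.
.spin_orbital_integrals <- function(h_mo, eri_mo) {
  nmo <- nrow(h_mo)
  N <- 2L * nmo
  one <- matrix(0, N, N)
  two <- array(0, rep(N, 4))
  spat <- function(p) (p - 1L) %/% 2L + 1L
  spin <- function(p) (p - 1L) %% 2L
  for (p in seq_len(N)) for (q in seq_len(N)) {
    if (spin(p) == spin(q)) one[p, q] <- h_mo[spat(p), spat(q)]
  }
  for (p in seq_len(N)) for (q in seq_len(N))
    for (r in seq_len(N)) for (s in seq_len(N)) {
      if (spin(p) == spin(r) && spin(q) == spin(s)) {
        two[p, q, r, s] <- eri_mo[spat(p), spat(r), spat(q), spat(s)]
      }
    }
  list(one_body = one, two_body = two)
}

#' Generate molecular spin-orbital integrals for a shipped system
#'
#' Runs the built-in s-orbital restricted Hartree-Fock engine and
#' transforms the integrals to the interleaved spin-orbital basis
#' (alpha, beta, alpha, beta, ... by ascending spatial orbital). The
#' two-body block is stored in physicist notation
#' \eqn{\langle pq|rs\rangle}. H2 uses the STO-3G basis (four
#' spin-orbitals, two electrons); LiH uses a minimal basis with only s
#' functions, i.e. STO-3G with the lithium p functions removed (six
#' spin-orbitals, four electrons, no frozen core).
#'
#' @param molecule `"H2"` or `"LiH"`.
#' @param bond_length internuclear distance in Angstrom.
#' @param mo_reference optional `molecular_integrals` from an adjacent
#'   geometry; when given, molecular-orbital phases are aligned to it via
#'   [fix_mo_phases()] before the integral transform.
#' @return An object of class `molecular_integrals`.
#' @export
molecular_integrals <- function(molecule = c("H2", "LiH"), bond_length,
                                mo_reference = NULL) {
  molecule <- match.arg(molecule)
  atoms <- if (molecule == "H2") c("H", "H") else c("Li", "H")
  coords <- rbind(c(0, 0, 0), c(0, 0, bond_length * .ANGSTROM_TO_BOHR))
  shells <- .contracted_s_basis(atoms, coords)
  ao <- .ao_integrals(shells, atoms, coords)
  e_nuc <- .nuclear_repulsion(atoms, coords)
  Hcore <- ao$T + ao$V
  n_el <- if (molecule == "H2") 2L else 4L
  hf <- .rhf(ao$S, Hcore, ao$eri, n_el, e_nuc)
  C <- hf$C
  if (!is.null(mo_reference)) {
    fixed <- fix_mo_phases(
      list(matrix = mo_reference$mo_coefficients,
           overlap = mo_reference$overlap,
           geometry_id = mo_reference$geometry_id),
      list(matrix = C, overlap = ao$S,
           geometry_id = format(bond_length)))
    C <- fixed$matrix
  }
  mo <- .mo_transform(C, Hcore, ao$eri)
  so <- .spin_orbital_integrals(mo$h, mo$eri)
  structure(list(
    molecule = molecule,
    basis_label = if (molecule == "H2") "STO-3G" else "STO-3G-s-only",
    geometry_id = format(bond_length),
    n_spin_orbitals = 2L * nrow(mo$h),
    n_electrons = n_el,
    e_nuclear = e_nuc,
    hf_energy = hf$energy,
    one_body = so$one_body,
    two_body = so$two_body,
    mo_coefficients = C,
    overlap = ao$S), class = "molecular_integrals")
}

#' @export
print.molecular_integrals <- function(x, ...) {
  cat(sprintf(
    "<molecular_integrals: %s/%s at %s A; N = %d spin-orbitals, n = %d electrons>\n",
    x$molecule, x$basis_label, x$geometry_id, x$n_spin_orbitals,
    x$n_electrons))
  cat(sprintf("  E_nuc = %.8f Ha, E_HF = %.8f Ha\n", x$e_nuclear, x$hf_energy))
  invisible(x)
}
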