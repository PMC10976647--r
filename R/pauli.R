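# Phase-exact Pauli-string algebra.
#
# A Pauli string is a fixed-length word over {I, X, Y, Z}, one letter per
# qubit; qubit 0 is the LEFTMOST letter everywhere in this package (labels,
# bitstrings, Kronecker order: qubit 0 is the most significant factor).
# Single-qubit products carry an exact phase i^k, k in 0..3, tracked as an
# integer so that cancellations in operator products are exact.

.PAULI_LETTERS <- c("I", "X", "Y", "Z")

# i^k phase exponent of the product a.b for codes a, b in 0..3 (I,X,Y,Z):
# X.Y = iZ, Y.Z = iX, Z.X = iY and conjugates.
.PAULI_PHASE_POW <- matrix(c(
  0L, 0L, 0L, 0L,
  0L, 0L, 1L, 3L,
  0L, 3L, 0L, 1L,
  0L, 1L, 3L, 0L), nrow = 4, byrow = TRUE)

.PAULI_MATS <- list(
  I = diag(2) + 0i,
  X = matrix(c(0, 1, 1, 0), 2) + 0i,
  Y = matrix(c(0, 1i, -1i, 0), 2),
  Z = diag(c(1, -1)) + 0i)

.check_label <- function(label) {
  if (!is.character(label) || length(label) != 1L ||
      grepl("[^IXYZ]", label)) {
    stop("invalid Pauli label: ", deparse(label), call. = FALSE)
  }
  invisible(label)
}

.label_codes <- function(labels, n_qubits) {
  if (length(labels) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = n_qubits))
  }
  m <- matrix(match(unlist(strsplit(labels, "", fixed = TRUE)),
                    .PAULI_LETTERS) - 1L,
              nrow = length(labels), ncol = n_qubits, byrow = TRUE)
  m
}

.codes_label <- function(codes) {
  if (nrow(codes) == 0L) return(character(0))
  chars <- matrix(.PAULI_LETTERS[codes + 1L], nrow = nrow(codes))
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

#' Construct a Pauli-string operator sum
#'
#' A `pauli_sum` stores a sparse operator \eqn{\sum_i o_i \hat P_i} as a
#' mapping from Pauli-string labels to complex coefficients. Duplicate
#' labels are merged and coefficients with magnitude below `tol` are
#' dropped. A Hermitian operator has all coefficients real, since Pauli
#' strings form a Hermitian basis.
#'
#' @param labels character vector of Pauli labels over `{I,X,Y,Z}`, one
#'   letter per qubit; qubit 0 is the leftmost letter.
#' @param coeffs numeric or complex coefficients, recycled to `labels`.
#' @param n_qubits number of qubits; defaults to the label width.
#' @param tol magnitude below which a merged coefficient is pruned.
#' @return An object of class `pauli_sum` with fields `labels`, `coeffs`
#'   and `n_qubits`, labels sorted lexicographically.
#' @examples
#' pauli_sum(c("XX", "YY", "XX"), c(1, 2, 0.5))
#' @export
pauli_sum <- function(labels, coeffs = 1, n_qubits = NULL, tol = 1e-12) {
  if (length(labels) == 0L) {
    if (is.null(n_qubits)) stop("n_qubits required for an empty sum")
    return(structure(list(labels = character(0), coeffs = complex(0),
                          n_qubits = as.integer(n_qubits)),
                     class = "pauli_sum"))
  }
  labels <- as.character(labels)
  lapply(labels, .check_label)
  widths <- nchar(labels)
  if (length(unique(widths)) != 1L) stop("labels differ in length")
  if (is.null(n_qubits)) n_qubits <- widths[[1L]]
  if (widths[[1L]] != n_qubits) stop("label length does not match n_qubits")
  coeffs <- rep_len(as.complex(coeffs), length(labels))
  .ps_build(labels, coeffs, as.integer(n_qubits), tol)
}

# merge duplicates, prune, sort; no validation
.ps_build <- function(labels, coeffs, n_qubits, tol = 1e-12) {
  if (length(labels)) {
    merged <- tapply(coeffs, labels, sum)
    labels <- names(merged)
    coeffs <- as.complex(merged)
    keep <- Mod(coeffs) >= tol
    labels <- labels[keep]
    coeffs <- coeffs[keep]
    ord <- order(labels, method = "radix")
    labels <- labels[ord]
    coeffs <- coeffs[ord]
  }
  structure(list(labels = unname(labels), coeffs = unname(coeffs),
                 n_qubits = as.integer(n_qubits)),
            class = "pauli_sum")
}

#' @export
print.pauli_sum <- function(x, max_terms = 20L, ...) {
  cat(sprintf("<pauli_sum: %d term(s) on %d qubit(s)>\n",
              length(x$labels), x$n_qubits))
  k <- min(length(x$labels), max_terms)
  if (k > 0) {
    for (i in seq_len(k)) {
      co <- x$coeffs[[i]]
      if (abs(Im(co)) < 1e-14) {
        cat(sprintf("  %s  %+.10g\n", x$labels[[i]], Re(co)))
      } else {
        cat(sprintf("  %s  %+.10g%+.10gi\n", x$labels[[i]], Re(co), Im(co)))
      }
    }
    if (length(x$labels) > k) cat("  ...\n")
  }
  invisible(x)
}

#' @export
length.pauli_sum <- function(x) length(x$labels)

#' Number of terms in a Pauli sum
#' @param s a `pauli_sum`.
#' @return integer count of stored Pauli strings (identity included).
#' @export
n_terms <- function(s) length(s$labels)

.check_same_n <- function(a, b) {
  if (a$n_qubits != b$n_qubits) {
    stop("operands act on different numbers of qubits", call. = FALSE)
  }
}

#' Multiply two Pauli strings
#'
#' Computes the matrix product of two Pauli strings as `phase * r` where
#' `phase` is one of `1, -1, 1i, -1i` and `r` is again a Pauli string.
#' Single-qubit phases multiply across positions.
#'
#' @param p,q Pauli labels of equal length.
#' @return list with components `phase` (complex) and `label`.
#' @examples
#' pauli_product("X", "Y")  # +i Z
#' @export
pauli_product <- function(p, q) {
  .check_label(p); .check_label(q)
  if (nchar(p) != nchar(q)) stop("Pauli labels differ in length")
  a <- .label_codes(p, nchar(p))[1L, ]
  b <- .label_codes(q, nchar(q))[1L, ]
  pow <- sum(.PAULI_PHASE_POW[cbind(a + 1L, b + 1L)]) %% 4L
  codes <- bitwXor(a, b)
  list(phase = (0+1i)^pow,
       label = paste0(.PAULI_LETTERS[codes + 1L], collapse = ""))
}

#' Qubit-wise commutativity of two Pauli strings
#'
#' Two strings commute qubit-wise (QWC) when at every position the letters
#' are equal or at least one is the identity.
#'
#' @param p,q Pauli labels of equal length.
#' @return logical.
#' @export
commutes_qwc <- function(p, q) {
  .check_label(p); .check_label(q)
  if (nchar(p) != nchar(q)) stop("Pauli labels differ in length")
  a <- .label_codes(p, nchar(p))[1L, ]
  b <- .label_codes(q, nchar(q))[1L, ]
  all(a == b | a == 0L | b == 0L)
}

#' General commutativity of two Pauli strings
#'
#' Two strings commute in the general sense (GC) when the number of
#' positions carrying distinct non-identity letters is even. QWC is the
#' special case of zero such positions.
#'
#' @param p,q Pauli labels of equal length.
#' @return logical.
#' @export
commutes_gc <- function(p, q) {
  .check_label(p); .check_label(q)
  if (nchar(p) != nchar(q)) stop("Pauli labels differ in length")
  a <- .label_codes(p, nchar(p))[1L, ]
  b <- .label_codes(q, nchar(q))[1L, ]
  sum(a != b & a != 0L & b != 0L) %% 2L == 0L
}

#' Add two Pauli sums
#'
#' Termwise coefficient addition with merging of duplicate labels;
#' coefficients below `tol` in magnitude are dropped.
#'
#' @param a,b `pauli_sum` objects on the same number of qubits.
#' @param tol pruning tolerance.
#' @return a `pauli_sum`.
#' @export
ps_add <- function(a, b, tol = 1e-12) {
  .check_same_n(a, b)
  .ps_build(c(a$labels, b$labels), c(a$coeffs, b$coeffs), a$n_qubits, tol)
}

#' Scale a Pauli sum by a scalar
#' @param a a `pauli_sum`.
#' @param s numeric or complex scalar.
#' @return a `pauli_sum`.
#' @export
ps_scale <- function(a, s) {
  .ps_build(a$labels, a$coeffs * as.complex(s), a$n_qubits, 0)
}

#' Multiply two Pauli sums
#'
#' Distributes the single-string product over all term pairs with exact
#' integer phase tracking, merges duplicate labels and prunes
#' coefficients below `tol`. For a Hermitian operator squared, cross
#' terms generated by anticommuting string pairs cancel exactly because
#' the phases are exact powers of i.
#'
#' @param a,b `pauli_sum` objects on the same number of qubits.
#' @param tol pruning tolerance.
#' @return a `pauli_sum`.
#' @export
ps_multiply <- function(a, b, tol = 1e-12) {
  .check_same_n(a, b)
  na <- length(a$labels); nb <- length(b$labels)
  n <- a$n_qubits
  if (na == 0L || nb == 0L) return(pauli_sum(character(0), n_qubits = n))
  A <- .label_codes(a$labels, n)
  B <- .label_codes(b$labels, n)
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  Ae <- A[ia, , drop = FALSE]
  Be <- B[ib, , drop = FALSE]
  pow <- matrix(.PAULI_PHASE_POW[cbind(as.vector(Ae) + 1L,
                                       as.vector(Be) + 1L)],
                nrow = length(ia))
  pow <- rowSums(pow) %% 4L
  codes <- matrix(bitwXor(as.vector(Ae), as.vector(Be)), nrow = length(ia))
  coeffs <- a$coeffs[ia] * b$coeffs[ib] * (0+1i)^pow
  .ps_build(.codes_label(codes), coeffs, n, tol)
}

#' Build the folded-spectrum operator (H - omega)^2
#'
#' Forms \eqn{(\hat H - \omega I)^2} by phase-tracked Pauli
#' multiplication of the shifted operator with itself, so that the
#' surviving term count is independent of `omega` as long as the merging
#' is exact. The folded operator shares the eigenvectors of `h`; its
#' eigenvalues are \eqn{(E_i-\omega)^2}, so its minimum selects the
#' eigenstate of `h` nearest the target energy `omega`.
#'
#' @param h Hermitian `pauli_sum` (all coefficients real).
#' @param omega real target energy, Hartree.
#' @param tol pruning tolerance for the reduced product.
#' @return An object of class `folded_operator`: list with fields `base`
#'   (`h`), `omega` and `folded` (the reduced `pauli_sum`).
#' @export
fold_spectrum <- function(h, omega, tol = 1e-12) {
  stopifnot(inherits(h, "pauli_sum"), is.numeric(omega), length(omega) == 1L)
  if (any(abs(Im(h$coeffs)) > 1e-10)) {
    stop("fold_spectrum requires a Hermitian operator (real coefficients)")
  }
  idl <- strrep("I", h$n_qubits)
  shifted <- ps_add(h, pauli_sum(idl, -omega, h$n_qubits), tol = 0)
  folded <- ps_multiply(shifted, shifted, tol = tol)
  # phase bookkeeping guarantees real coefficients; drop numerical dust
  folded$coeffs <- as.complex(Re(folded$coeffs))
  structure(list(base = h, omega = omega, folded = folded),
            class = "folded_operator")
}

#' @export
print.folded_operator <- function(x, ...) {
  cat(sprintf(
    "<folded_operator: omega = %.8f Ha; %d -> %d Pauli strings>\n",
    x$omega, length(x$base$labels), length(x$folded$labels)))
  invisible(x)
}

#' Dense matrix realization of a Pauli sum
#'
#' Kronecker-product expansion with qubit 0 as the most significant
#' (leftmost) factor. Guarded at 12 qubits.
#'
#' @param s a `pauli_sum` (or single Pauli label with `n_qubits` implied).
#' @return complex matrix of dimension `2^n x 2^n`.
#' @export
pauli_to_matrix <- function(s) {
  if (is.character(s)) s <- pauli_sum(s, 1)
  n <- s$n_qubits
  if (n > 12L) stop("matrix realization guarded at 12 qubits")
  dim <- 2L^n
  m <- matrix(0+0i, dim, dim)
  for (i in seq_along(s$labels)) {
    letters_i <- strsplit(s$labels[[i]], "")[[1L]]
    term <- Reduce(kronecker, .PAULI_MATS[letters_i])
    m <- m + s$coeffs[[i]] * term
  }
  m
}

#' Decompose a matrix onto the Pauli-string basis
#'
#' Recovers coefficients by the trace inner product
#' \eqn{o_P = \mathrm{tr}(P M)/2^n}. Intended for small cross-checks.
#'
#' @param m complex matrix of dimension `2^n x 2^n`, `n <= 6`.
#' @param tol coefficients below this magnitude are dropped.
#' @return a `pauli_sum`.
#' @export
matrix_to_pauli <- function(m, tol = 1e-10) {
  n <- as.integer(round(log2(nrow(m))))
  if (2L^n != nrow(m) || n > 6L) stop("expected a 2^n x 2^n matrix, n <= 6")
  combos <- expand.grid(rep(list(.PAULI_LETTERS), n),
                        stringsAsFactors = FALSE)[, n:1, drop = FALSE]
  labels <- do.call(paste0, combos)
  coeffs <- vapply(labels, function(lab) {
    p <- Reduce(kronecker, .PAULI_MATS[strsplit(lab, "")[[1L]]])
    sum(diag(p %*% m)) / nrow(m)
  }, complex(1))
  .ps_build(labels, coeffs, n, tol)
}

#' Apply a Pauli string to a statevector
#'
#' Pauli strings act as signed (complex-phase) permutations of the
#' computational basis; this applies one in O(2^n) time.
#'
#' @param label Pauli label.
#' @param psi complex amplitude vector of length `2^nchar(label)`;
#'   basis index bit of qubit 0 is the most significant.
#' @return complex vector `P psi`.
#' @export
pauli_apply <- function(label, psi) {
  n <- nchar(label)
  if (length(psi) != 2L^n) stop("statevector length mismatch")
  codes <- .label_codes(label, n)[1L, ]
  idx <- 0:(2L^n - 1L)
  flip_mask <- 0L
  phase <- rep(1+0i, length(psi))
  for (q in seq_len(n)) {
    bitpos <- n - q          # qubit q-1 occupies bit (n - q) counting from 0
    bit <- bitwAnd(bitwShiftR(idx, bitpos), 1L)
    code <- codes[[q]]
    if (code == 1L) {                       # X: flip
      flip_mask <- bitwOr(flip_mask, bitwShiftL(1L, bitpos))
    } else if (code == 2L) {                # Y: flip with phase +/- i
      flip_mask <- bitwOr(flip_mask, bitwShiftL(1L, bitpos))
      phase <- phase * ifelse(bit == 0L, 1i, -1i)
    } else if (code == 3L) {                # Z: sign on |1>
      phase <- phase * ifelse(bit == 0L, 1, -1)
    }
  }
  out <- complex(length(psi))
  out[bitwXor(idx, flip_mask) + 1L] <- psi * phase
  out
}

#' Exact expectation of a Pauli sum in a statevector
#'
#' Computes \eqn{\langle\psi|\hat O|\psi\rangle} term by term via signed
#' basis permutations; exact up to floating point.
#'
#' @param s a `pauli_sum`.
#' @param psi complex amplitude vector.
#' @return real expectation value.
#' @export
ps_expectation <- function(s, psi) {
  val <- 0+0i
  for (i in seq_along(s$labels)) {
    val <- val + s$coeffs[[i]] * sum(Conj(psi) * pauli_apply(s$labels[[i]], psi))
  }
  Re(val)
}

#' Write a Pauli sum to a plain-text operator file
#'
#' Format: a header line `n_qubits <n>`, then one term per line,
#' `LABEL real_coeff [imag_coeff]`. The reader/writer pair round-trips
#' exactly (coefficients serialized at full precision).
#'
#' @param s a `pauli_sum`.
#' @param path output file path.
#' @export
write_pauli_sum <- function(s, path) {
  lines <- c(sprintf("n_qubits %d", s$n_qubits),
             vapply(seq_along(s$labels), function(i) {
               co <- s$coeffs[[i]]
               if (Im(co) == 0) {
                 sprintf("%s %.17g", s$labels[[i]], Re(co))
               } else {
                 sprintf("%s %.17g %.17g", s$labels[[i]], Re(co), Im(co))
               }
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pauli sum from a plain-text operator file
#' @param path file written by [write_pauli_sum()].
#' @return a `pauli_sum`.
#' @export
read_pauli_sum <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  head_parts <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (head_parts[[1L]] != "n_qubits") stop("missing n_qubits header")
  n <- as.integer(head_parts[[2L]])
  body <- lines[-1L]
  labels <- character(0); coeffs <- complex(0)
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    labels <- c(labels, parts[[1L]])
    re <- as.numeric(parts[[2L]])
    im <- if (length(parts) >= 3L) as.numeric(parts[[3L]]) else 0
    coeffs <- c(coeffs, complex(real = re, imaginary = im))
  }
  pauli_sum(labels, coeffs, n, tol = 0)
}
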