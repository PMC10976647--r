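# Jordan-Wigner qubit Hamiltonians from spin-orbital integral fixtures.
#
# Spin-orbital ordering is interleaved (alpha, beta, alpha, beta, ...) by
# ascending spatial orbital, and is used consistently for the JW mapping,
# excitation enumeration and reference states. Qubit j hosts spin-orbital
# j; |1> means occupied. The JW Z string sits on qubits with index lower
# than j, and the sign convention of the qubit ladder operators maps the
# vacuum to |0...0>.

#' Jordan-Wigner image of a fermionic ladder operator
#'
#' Maps the creation (`dagger = TRUE`) or annihilation operator on
#' spin-orbital `j` to \eqn{(X_j \mp i Y_j)/2} dressed with Z on all
#' qubits of index below `j`. The images satisfy the canonical
#' anticommutation relations.
#'
#' @param j spin-orbital (= qubit) index, 0-based.
#' @param dagger logical; `TRUE` for the creation operator.
#' @param n total number of qubits.
#' @return a `pauli_sum` with two terms.
#' @export
jw_ladder <- function(j, dagger, n) {
  if (j < 0 || j >= n) stop("orbital index out of range")
  zs <- strrep("Z", j)
  pad <- strrep("I", n - j - 1L)
  labels <- c(paste0(zs, "X", pad), paste0(zs, "Y", pad))
  ycoef <- if (dagger) -0.5i else 0.5i
  pauli_sum(labels, c(0.5 + 0i, ycoef), n, tol = 0)
}

#' Build the JW-mapped qubit Hamiltonian from molecular integrals
#'
#' Assembles \eqn{\hat H = \sum_{pq} h_{pq} a^\dagger_p a_q +
#' \tfrac12 \sum_{pqrs} \langle pq|rs\rangle a^\dagger_p a^\dagger_q a_s
#' a_r + E_{nuc}} and maps it to Pauli strings under the Jordan-Wigner
#' transformation. One-body terms with p = q and two-body terms pairing
#' identical spin-orbital indices land on diagonal (I/Z-only) strings.
#'
#' @param mi a `molecular_integrals` object.
#' @param tol coefficient pruning tolerance.
#' @return a Hermitian `pauli_sum` on `mi$n_spin_orbitals` qubits.
#' @export
build_hamiltonian <- function(mi, tol = 1e-12) {
  stopifnot(inherits(mi, "molecular_integrals"))
  N <- mi$n_spin_orbitals
  cre <- lapply(seq_len(N) - 1L, jw_ladder, dagger = TRUE, n = N)
  ann <- lapply(seq_len(N) - 1L, jw_ladder, dagger = FALSE, n = N)
  h <- pauli_sum(strrep("I", N), mi$e_nuclear, N, tol = 0)
  for (p in seq_len(N)) for (q in seq_len(N)) {
    c_pq <- mi$one_body[p, q]
    if (abs(c_pq) < 1e-14) next
    term <- ps_scale(ps_multiply(cre[[p]], ann[[q]], tol = 0), c_pq)
    h <- ps_add(h, term, tol = 0)
  }
  two <- mi$two_body
  for (p in seq_len(N)) for (q in seq_len(N)) {
    if (p == q) next
    pq <- ps_multiply(cre[[p]], cre[[q]], tol = 0)
    for (s in seq_len(N)) for (r in seq_len(N)) {
      if (s == r) next
      g <- two[p, q, r, s]
      if (abs(g) < 1e-14) next
      sr <- ps_multiply(ann[[s]], ann[[r]], tol = 0)
      h <- ps_add(h, ps_scale(ps_multiply(pq, sr, tol = 0), 0.5 * g), tol = 0)
    }
  }
  h <- .ps_build(h$labels, h$coeffs, N, tol)
  h$coeffs <- as.complex(Re(h$coeffs))   # Hermitian by construction
  .ps_build(h$labels, h$coeffs, N, tol)
}

#' Hartree-Fock determinant bitstring
#'
#' In the interleaved spin-orbital ordering the closed-shell HF
#' determinant occupies the first `n_electrons` qubits.
#'
#' @param mi a `molecular_integrals` object.
#' @return occupation bitstring, leftmost character = qubit 0.
#' @export
hf_determinant <- function(mi) {
  paste0(strrep("1", mi$n_electrons),
         strrep("0", mi$n_spin_orbitals - mi$n_electrons))
}

#' Align molecular-orbital phases between adjacent geometries
#'
#' Computes \eqn{P = C_k^T S_k C_{k+1}}. Diagonal entries near -1 signal
#' a phase jump of the corresponding orbital between the two geometries;
#' those columns of `C_{k+1}` are negated so that the returned
#' coefficients give diagonal entries near +1. Diagonal entries far from
#' unit magnitude indicate an orbital-character swap and raise a warning
#' rather than a silent correction.
#'
#' @param prev,nxt lists with fields `matrix` (AO x MO coefficients),
#'   `overlap` (AO overlap at the earlier geometry) and `geometry_id`.
#' @param swap_tol warn when `abs(abs(diag(P)) - 1)` exceeds this.
#' @return `nxt` with phase-corrected `matrix`.
#' @export
fix_mo_phases <- function(prev, nxt, swap_tol = 0.5) {
  if (!all(dim(prev$matrix) == dim(nxt$matrix))) {
    stop("MO coefficient dimensions differ between geometries")
  }
  P <- t(prev$matrix) %*% prev$overlap %*% nxt$matrix
  d <- diag(P)
  if (any(abs(abs(d) - 1) > swap_tol)) {
    warning(sprintf(
      "possible orbital-character swap between geometries %s and %s: |diag(P)| = %s",
      prev$geometry_id, nxt$geometry_id,
      paste(sprintf("%.3f", abs(d)), collapse = ", ")))
  }
  flip <- which(d < 0)
  if (length(flip)) nxt$matrix[, flip] <- -nxt$matrix[, flip]
  nxt
}

.fmt_block <- function(x) {
  v <- sprintf("%.17g", as.vector(x))
  lines <- character(0)
  for (i in seq(1, length(v), by = 6)) {
    lines <- c(lines, paste(v[i:min(i + 5, length(v))], collapse = " "))
  }
  lines
}

#' Write molecular integrals to a plain-text fixture file
#'
#' Human-readable key/value header followed by dense arrays. The
#' two-body block is stored in physicist notation with the last index
#' fastest (R column-major vectorization of the `[p,q,r,s]` array).
#'
#' @param mi a `molecular_integrals` object.
#' @param path output path.
#' @export
write_integrals <- function(mi, path) {
  N <- mi$n_spin_orbitals
  nao <- nrow(mi$mo_coefficients)
  lines <- c(
    "# fsvqe molecular integral fixture v1",
    paste("molecule", mi$molecule),
    paste("basis_label", mi$basis_label),
    paste("geometry_id", mi$geometry_id),
    paste("n_spin_orbitals", N),
    paste("n_electrons", mi$n_electrons),
    sprintf("e_nuclear %.17g", mi$e_nuclear),
    sprintf("hf_energy %.17g", mi$hf_energy),
    sprintf("one_body %d %d", N, N), .fmt_block(mi$one_body),
    sprintf("two_body %d %d %d %d", N, N, N, N), .fmt_block(mi$two_body),
    sprintf("mo_coefficients %d %d", nao, ncol(mi$mo_coefficients)),
    .fmt_block(mi$mo_coefficients),
    sprintf("overlap %d %d", nao, nao), .fmt_block(mi$overlap))
  writeLines(lines, path)
  invisible(path)
}

.parse_scalar <- function(kv, key, numeric = TRUE) {
  if (!key %in% names(kv)) stop("fixture is missing field '", key, "'")
  v <- kv[[key]]
  if (numeric) {
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v)) stop("fixture field '", key, "' is not numeric")
  }
  v
}

#' Read molecular integrals from a fixture file
#'
#' Parses and validates a file written by [write_integrals()]: one-body
#' symmetry, the permutational symmetries of real-orbital two-electron
#' integrals in physicist notation, and electron count not exceeding the
#' spin-orbital count. Malformed files raise an error naming the
#' offending field.
#'
#' @param path fixture path.
#' @return a `molecular_integrals` object.
#' @export
read_integrals <- function(path) {
  if (!file.exists(path)) stop("fixture file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- list()
  arrays <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    key <- parts[[1L]]
    if (key %in% c("one_body", "two_body", "mo_coefficients", "overlap")) {
      dims <- as.integer(parts[-1L])
      if (anyNA(dims)) stop("fixture field '", key, "' has malformed dimensions")
      total <- prod(dims)
      vals <- numeric(0)
      i <- i + 1L
      while (length(vals) < total) {
        if (i > length(lines)) {
          stop("fixture field '", key, "' is truncated (expected ",
               total, " values, got ", length(vals), ")")
        }
        vals <- c(vals,
                  suppressWarnings(as.numeric(
                    strsplit(trimws(lines[[i]]), "\\s+")[[1L]])))
        i <- i + 1L
      }
      if (anyNA(vals)) stop("fixture field '", key, "' contains non-numeric values")
      arrays[[key]] <- array(vals, dims)
    } else {
      kv[[key]] <- paste(parts[-1L], collapse = " ")
      i <- i + 1L
    }
  }
  for (key in c("one_body", "two_body")) {
    if (is.null(arrays[[key]])) stop("fixture is missing field '", key, "'")
  }
  N <- as.integer(.parse_scalar(kv, "n_spin_orbitals"))
  n_el <- as.integer(.parse_scalar(kv, "n_electrons"))
  if (n_el > N) stop("fixture field 'n_electrons' exceeds n_spin_orbitals")
  one <- matrix(arrays$one_body, N, N)
  two <- arrays$two_body
  if (max(abs(one - t(one))) > 1e-8) {
    stop("fixture field 'one_body' is not symmetric")
  }
  sym_err <- max(abs(two - aperm(two, c(2, 1, 4, 3))),
                 abs(two - aperm(two, c(3, 2, 1, 4))),
                 abs(two - aperm(two, c(1, 4, 3, 2))))
  if (sym_err > 1e-8) {
    stop("fixture field 'two_body' violates real-orbital permutational symmetry")
  }
  structure(list(
    molecule = if (is.null(kv$molecule)) "unknown" else kv$molecule,
    basis_label = if (is.null(kv$basis_label)) "unknown" else kv$basis_label,
    geometry_id = if (is.null(kv$geometry_id)) "unknown" else kv$geometry_id,
    n_spin_orbitals = N,
    n_electrons = n_el,
    e_nuclear = .parse_scalar(kv, "e_nuclear"),
    hf_energy = .parse_scalar(kv, "hf_energy"),
    one_body = one,
    two_body = two,
    mo_coefficients = if (is.null(arrays$mo_coefficients)) NULL else arrays$mo_coefficients,
    overlap = if (is.null(arrays$overlap)) NULL else arrays$overlap),
    class = "molecular_integrals")
}

#' Path to a packaged integral fixture
#'
#' @param molecule `"H2"` or `"LiH"`.
#' @param bond_length bond length in Angstrom matching a shipped fixture.
#' @return file path inside the installed package.
#' @export
fixture_path <- function(molecule, bond_length) {
  fname <- sprintf("%s_%s.dat", tolower(molecule),
                   formatC(bond_length, format = "f", digits = 2))
  p <- system.file("extdata", fname, package = "fsvqe")
  if (!nzchar(p)) stop("no packaged fixture for ", molecule, " at ",
                       bond_length, " Angstrom")
  p
}

#' Bond lengths of the packaged fixtures
#' @param molecule `"H2"` or `"LiH"`.
#' @return numeric vector of bond lengths in Angstrom.
#' @export
fixture_grid <- function(molecule = c("H2", "LiH")) {
  molecule <- match.arg(molecule)
  files <- list.files(system.file("extdata", package = "fsvqe"),
                      pattern = paste0("^", tolower(molecule), "_.*\\.dat$"))
  sort(as.numeric(sub("^[a-z0-9]+_([0-9.]+)\\.dat$", "\\1", files)))
}
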