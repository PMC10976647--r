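# Partitioning of Pauli sums into simultaneously measurable groups and
# recovery of expectation values from measured counts.
#
# Bitstring convention matches Pauli labels: the leftmost character of a
# histogram key is qubit 0.

#' Pairwise commutation adjacency of a Pauli sum
#'
#' Builds the graph whose vertices are the Pauli-string labels of `s`
#' and whose edges join pairs that commute under the chosen mode
#' (qubit-wise or general commutativity).
#'
#' @param s a nonempty `pauli_sum`.
#' @param mode `"qwc"` or `"gc"`.
#' @return symmetric logical adjacency matrix with label dimnames
#'   (diagonal `TRUE`).
#' @export
commutation_graph <- function(s, mode = c("qwc", "gc")) {
  mode <- match.arg(mode)
  if (length(s$labels) == 0L) stop("empty Pauli sum")
  codes <- .label_codes(s$labels, s$n_qubits)
  m <- nrow(codes)
  clash_count <- matrix(0L, m, m)
  any_clash <- matrix(FALSE, m, m)
  for (q in seq_len(s$n_qubits)) {
    cq <- codes[, q]
    neq <- outer(cq, cq, "!=") & outer(cq != 0L, cq != 0L, "&")
    any_clash <- any_clash | neq
    clash_count <- clash_count + neq
  }
  adj <- if (mode == "qwc") !any_clash else clash_count %% 2L == 0L
  dimnames(adj) <- list(s$labels, s$labels)
  adj
}

#' Greedy clique cover of a commutation graph
#'
#' Partitions the labels into cliques (groups of mutually commuting
#' strings) by greedy sequential coloring of the complement graph with
#' largest-degree-first vertex order and lexicographic tie-breaking.
#' Deterministic; minimum clique cover is NP-hard, so optimality is not
#' claimed, but the heuristic is exact on the shipped systems.
#'
#' @param adj adjacency matrix from [commutation_graph()].
#' @param mode commutativity mode recorded on each group.
#' @return list of `measurement_group` objects (fields `members`,
#'   `mode`, `n_qubits`); groups ordered by first assigned color.
#' @export
clique_cover <- function(adj, mode = c("qwc", "gc")) {
  mode <- match.arg(mode)
  labels <- rownames(adj)
  m <- length(labels)
  comp <- !adj
  diag(comp) <- FALSE
  deg <- rowSums(comp)
  ord <- order(-deg, labels, method = "radix")
  color <- integer(m)
  for (v in ord) {
    used <- unique(color[comp[v, ] & color > 0L])
    col <- 1L
    while (col %in% used) col <- col + 1L
    color[v] <- col
  }
  n_q <- nchar(labels[[1L]])
  lapply(seq_len(max(color)), function(cl) {
    structure(list(members = labels[color == cl], mode = mode,
                   n_qubits = n_q, post_rotation = NULL),
              class = "measurement_group")
  })
}

#' Partition a Pauli sum into simultaneously measurable groups
#'
#' Convenience wrapper: commutation graph plus greedy clique cover, with
#' post-rotations assigned for QWC groups.
#'
#' @param s a `pauli_sum`.
#' @param mode `"qwc"` or `"gc"`.
#' @return list of `measurement_group`s covering every label of `s`.
#' @export
pauli_groups <- function(s, mode = c("qwc", "gc")) {
  mode <- match.arg(mode)
  groups <- clique_cover(commutation_graph(s, mode), mode)
  if (mode == "qwc") groups <- lapply(groups, assign_post_rotation)
  groups
}

#' @export
print.measurement_group <- function(x, ...) {
  cat(sprintf("<measurement_group (%s): %d member(s)>\n",
              toupper(x$mode), length(x$members)))
  cat(" ", paste(x$members, collapse = " "), "\n")
  if (!is.null(x$post_rotation)) {
    cat("  post-rotation:", paste(x$post_rotation, collapse = " "), "\n")
  }
  invisible(x)
}

#' Assign the shared post-rotation of a QWC group
#'
#' Per qubit: X-basis (Hadamard) where any member carries X, Y-basis
#' (S-adjoint then Hadamard) where any member carries Y, none elsewhere.
#' Qubit-wise commutativity guarantees these assignments never clash,
#' and rotating every member yields an I/Z-only string.
#'
#' @param g a QWC `measurement_group`.
#' @return `g` with `post_rotation` filled (per-qubit tags
#'   `"none"`, `"X"`, `"Y"`).
#' @export
assign_post_rotation <- function(g) {
  if (g$mode != "qwc") {
    stop("post-rotation assignment supports QWC groups only; ",
         "simultaneous-measurement synthesis for GC groups is unsupported")
  }
  codes <- .label_codes(g$members, g$n_qubits)
  tags <- vapply(seq_len(g$n_qubits), function(q) {
    letters_q <- codes[, q]
    if (any(letters_q == 1L)) "X" else if (any(letters_q == 2L)) "Y" else "none"
  }, character(1))
  g$post_rotation <- tags
  g
}

#' Post-rotation gate layer for a QWC group
#'
#' @param g a `measurement_group` with post-rotations assigned.
#' @return a `quantum_circuit` diagonalizing every member of `g`.
#' @export
rotation_circuit <- function(g) {
  if (is.null(g$post_rotation)) g <- assign_post_rotation(g)
  qc <- empty_circuit(g$n_qubits)
  for (q in seq_len(g$n_qubits)) {
    tag <- g$post_rotation[[q]]
    if (tag == "X") {
      qc <- qc_gate(qc, "H", q - 1L)
    } else if (tag == "Y") {
      qc <- qc_gate(qc, "SDG", q - 1L)
      qc <- qc_gate(qc, "H", q - 1L)
    }
  }
  qc
}

#' Diagonal image of group members under their measurement rotation
#'
#' Conjugates each member through the group's rotation layer with exact
#' Clifford sign tracking, asserting that every image is I/Z-only.
#'
#' @param g a `measurement_group` (QWC, or carrying a custom `rotation`
#'   circuit attached as `g$rotation`).
#' @return data.frame with columns `label`, `diagonal`, `sign`.
#' @export
rotated_members <- function(g) {
  circ <- if (!is.null(g$rotation)) g$rotation else rotation_circuit(g)
  out <- lapply(g$members, function(lab) {
    cc <- clifford_conjugate(lab, circ)
    list(label = lab, diagonal = cc$label, sign = cc$sign)
  })
  df <- data.frame(label = vapply(out, `[[`, "", "label"),
                   diagonal = vapply(out, `[[`, "", "diagonal"),
                   sign = vapply(out, `[[`, 0, "sign"),
                   stringsAsFactors = FALSE)
  bad <- grepl("[XY]", df$diagonal)
  if (any(bad)) {
    stop("rotation fails to diagonalize member(s): ",
         paste(df$label[bad], collapse = ", "))
  }
  df
}

#' General-commutativity measurement groups for a folded H2-type operator
#'
#' The folded operator of a two-orbital system splits into two commuting
#' groups: the diagonal (I/Z-only) strings, measured directly, and the
#' weight-n X/Y strings with an even number of Y letters, which are
#' simultaneously diagonalized by one entangling layer — a CNOT fan from
#' qubit 0 followed by a Hadamard on qubit 0 (the layer maps X...X to
#' Z on qubit 0 and preserves diagonality of Z strings). The returned
#' groups carry that rotation; [rotated_members()] asserts the
#' diagonalization with exact Clifford sign tracking.
#'
#' @param s a `pauli_sum` whose non-diagonal strings are all-X/Y words
#'   of even Y parity (the structure of a folded two-level-per-spin
#'   Hamiltonian).
#' @return list of two `measurement_group`s (mode `"gc"`) with attached
#'   `rotation` circuits.
#' @export
fs_gc_groups <- function(s) {
  n <- s$n_qubits
  is_diag <- !grepl("[XY]", s$labels)
  offdiag <- s$labels[!is_diag]
  ok <- !grepl("I|Z", offdiag) &
    vapply(offdiag, function(l) {
      sum(strsplit(l, "")[[1L]] == "Y") %% 2L == 0L
    }, logical(1))
  if (!all(ok)) {
    stop("operator's non-diagonal strings are not even-Y all-X/Y words; ",
         "no shared entangling rotation is provided")
  }
  rot <- empty_circuit(n)
  for (t in seq_len(n - 1L)) rot <- qc_gate(rot, "CNOT", 0L, q2 = t)
  rot <- qc_gate(rot, "H", 0L)
  ga <- structure(list(members = s$labels[is_diag], mode = "gc",
                       n_qubits = n, post_rotation = NULL,
                       rotation = empty_circuit(n)),
                  class = "measurement_group")
  gb <- structure(list(members = offdiag, mode = "gc", n_qubits = n,
                       post_rotation = NULL, rotation = rot),
                  class = "measurement_group")
  groups <- list(ga, gb)
  for (g in groups) rotated_members(g)   # assert diagonalization
  groups
}

# lazily built Clifford conjugation tables ---------------------------------

.clifford_env <- new.env(parent = emptyenv())

.clifford_1q_table <- function() {
  if (!is.null(.clifford_env$t1)) return(.clifford_env$t1)
  gates <- list(
    H = .PAULI_MATS$I, S = .PAULI_MATS$I, SDG = .PAULI_MATS$I,
    X = .PAULI_MATS$X, Z = .PAULI_MATS$Z)
  gates$H <- matrix(c(1, 1, 1, -1), 2) / sqrt(2) + 0i
  gates$S <- diag(c(1, 1i))
  gates$SDG <- diag(c(1, -1i))
  t1 <- list()
  for (gname in names(gates)) {
    U <- gates[[gname]]
    tab <- list()
    for (p in .PAULI_LETTERS) {
      M <- U %*% .PAULI_MATS[[p]] %*% Conj(t(U))
      hit <- NULL
      for (r in .PAULI_LETTERS) for (sgn in c(1, -1)) {
        if (max(Mod(M - sgn * .PAULI_MATS[[r]])) < 1e-12) {
          hit <- list(letter = r, sign = sgn)
        }
      }
      tab[[p]] <- hit
    }
    t1[[gname]] <- tab
  }
  .clifford_env$t1 <- t1
  t1
}

.clifford_cnot_table <- function() {
  if (!is.null(.clifford_env$t2)) return(.clifford_env$t2)
  U <- matrix(0+0i, 4, 4)       # control = first (most significant) qubit
  U[1, 1] <- U[2, 2] <- 1
  U[3, 4] <- U[4, 3] <- 1
  t2 <- list()
  for (pc in .PAULI_LETTERS) for (pt in .PAULI_LETTERS) {
    M <- U %*% kronecker(.PAULI_MATS[[pc]], .PAULI_MATS[[pt]]) %*% Conj(t(U))
    hit <- NULL
    for (rc in .PAULI_LETTERS) for (rt in .PAULI_LETTERS) for (sgn in c(1, -1)) {
      if (max(Mod(M - sgn * kronecker(.PAULI_MATS[[rc]], .PAULI_MATS[[rt]]))) < 1e-12) {
        hit <- list(c_letter = rc, t_letter = rt, sign = sgn)
      }
    }
    t2[[paste0(pc, pt)]] <- hit
  }
  .clifford_env$t2 <- t2
  t2
}

#' Conjugate a Pauli string through a Clifford gate sequence
#'
#' Returns the Pauli string `U P U^dagger` (with its +/-1 sign) for a
#' circuit `U` composed of H, S, S-adjoint, X, Z, and CNOT gates, the
#' gates taken in application order. Rz gates are rejected.
#'
#' @param label Pauli label.
#' @param circuit a `quantum_circuit` of Clifford gates.
#' @return list with `sign` (+1 or -1) and `label`.
#' @export
clifford_conjugate <- function(label, circuit) {
  letters_v <- strsplit(label, "")[[1L]]
  sign <- 1
  t1 <- .clifford_1q_table()
  for (g in circuit$gates) {
    if (g$type == "CNOT") {
      t2 <- .clifford_cnot_table()
      key <- paste0(letters_v[[g$q + 1L]], letters_v[[g$q2 + 1L]])
      hit <- t2[[key]]
      letters_v[[g$q + 1L]] <- hit$c_letter
      letters_v[[g$q2 + 1L]] <- hit$t_letter
      sign <- sign * hit$sign
    } else if (g$type %in% c("H", "S", "SDG", "X", "Z")) {
      hit <- t1[[g$type]][[letters_v[[g$q + 1L]]]]
      letters_v[[g$q + 1L]] <- hit$letter
      sign <- sign * hit$sign
    } else {
      stop("non-Clifford gate in conjugation: ", g$type)
    }
  }
  list(sign = sign, label = paste0(letters_v, collapse = ""))
}

# counts ------------------------------------------------------------------

#' Construct a measurement-counts histogram
#'
#' @param histogram named nonnegative vector; names are bitstrings with
#'   the leftmost character corresponding to qubit 0. Fractional values
#'   are allowed for exact-population backends.
#' @param shots total number of shots (must equal `sum(histogram)`).
#' @return object of class `counts`.
#' @export
counts <- function(histogram, shots = sum(histogram)) {
  if (is.null(names(histogram)) || any(!nzchar(names(histogram)))) {
    stop("histogram must be named by bitstrings")
  }
  if (abs(sum(histogram) - shots) > 1e-9 * max(1, shots)) {
    stop("histogram total does not equal shots")
  }
  structure(list(histogram = histogram, shots = shots), class = "counts")
}

#' @export
print.counts <- function(x, ...) {
  cat(sprintf("<counts: %s shots over %d outcome(s)>\n",
              format(x$shots), length(x$histogram)))
  invisible(x)
}

#' Expectation of a diagonal Pauli string from counts
#'
#' \eqn{\sum_i \lambda_i \, c_i / s} with eigenvalue
#' \eqn{\lambda_i = (-1)^{\mathrm{popcount}}} over the measured 1-bits at
#' the label's Z positions. The label must be I/Z-only; non-diagonal
#' strings must be rotated before sampling.
#'
#' @param c a `counts` object.
#' @param label diagonal Pauli label.
#' @return real value in `[-1, 1]`.
#' @export
expectation_from_counts <- function(c, label) {
  .check_label(label)
  if (grepl("[XY]", label)) {
    stop("label is not diagonal; apply the post-rotation before sampling")
  }
  zpos <- which(strsplit(label, "")[[1L]] == "Z")
  bits <- names(c$histogram)
  if (length(zpos) == 0L) return(1)
  lam <- vapply(bits, function(b) {
    ones <- sum(strsplit(b, "")[[1L]][zpos] == "1")
    if (ones %% 2L == 0L) 1 else -1
  }, numeric(1))
  sum(lam * c$histogram) / c$shots
}

#' Estimate an operator expectation from grouped counts
#'
#' \eqn{\sum_i o_i \langle \hat P_i \rangle} with each string's
#' expectation read from the counts of the group containing it, after
#' rotation bookkeeping (diagonal image and Clifford sign).
#'
#' @param s the `pauli_sum` being estimated.
#' @param groups list of `measurement_group`s covering every label of `s`.
#' @param counts_list one `counts` per group, measured after the group's
#'   post-rotation.
#' @return real estimate (Hartree for molecular operators).
#' @export
estimate_operator <- function(s, groups, counts_list) {
  if (length(groups) != length(counts_list)) {
    stop("need exactly one counts object per group")
  }
  covered <- unlist(lapply(groups, `[[`, "members"))
  missing <- setdiff(s$labels, covered)
  if (length(missing)) {
    stop("groups do not cover label(s): ", paste(missing, collapse = ", "))
  }
  coef <- stats::setNames(s$coeffs, s$labels)
  total <- 0
  for (k in seq_along(groups)) {
    rot <- rotated_members(groups[[k]])
    for (j in seq_len(nrow(rot))) {
      lab <- rot$label[[j]]
      if (!lab %in% s$labels) next
      ev <- rot$sign[[j]] *
        expectation_from_counts(counts_list[[k]], rot$diagonal[[j]])
      total <- total + Re(coef[[lab]]) * ev
    }
  }
  total
}
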