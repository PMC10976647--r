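# The FS-VQE optimization loop: folded-spectrum cost with measurement
# grouping, SPSA with an increasing shot schedule, post-optimization
# refinement (parabola vertex + angle rounding), state tracking along a
# potential-energy surface, and exact-diagonalization references.

HARTREE_TO_KCAL <- 627.5094740631

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# ansatz bundle

#' Build the ordered Trotterized UCCSD ansatz for a system
#'
#' Enumerates spin-conserving single and double excitations from the
#' Hartree-Fock determinant in the fixed occupied-index ordering and
#' compiles them to a Pauli-gadget circuit. The same circuit serves
#' ground and excited states; only the prepared reference changes.
#'
#' @param ref_det Hartree-Fock occupation bitstring.
#' @param n_qubits register size.
#' @param c_scale parameter scaling constant: optimizer variables range
#'   over (-c pi, c pi], physical angles over (-pi, pi].
#' @return object of class `uccsd_ansatz` (excitations, compiled
#'   circuit, per-excitation Trotter factors).
#' @export
uccsd_ansatz <- function(ref_det, n_qubits, c_scale = 2) {
  excs <- enumerate_excitations(ref_det, n_qubits)
  structure(list(
    excitations = excs,
    circuit = compile_ucc(excs, n_qubits, c_scale),
    # application order matches the compiled circuit: reverse enumeration
    terms = rev(.ucc_terms(excs, n_qubits)),
    c_scale = c_scale,
    n_qubits = as.integer(n_qubits),
    n_parameters = length(excs)), class = "uccsd_ansatz")
}

#' @export
print.uccsd_ansatz <- function(x, ...) {
  cat(sprintf("<uccsd_ansatz: %d excitation(s) on %d qubit(s); %d gate(s)>\n",
              x$n_parameters, x$n_qubits, length(x$circuit$gates)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# measurement plan: precomputed eigenvalue tables per QWC group

.popcount_parity <- function(idx, mask) {
  p <- integer(length(idx))
  x <- bitwAnd(idx, mask)
  while (any(x > 0L)) {
    p <- p + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  p %% 2L
}

.measurement_plan <- function(op, mode = "qwc", groups = NULL) {
  groups <- groups %||% pauli_groups(op, mode)
  n <- op$n_qubits
  idx <- 0:(2L^n - 1L)
  coef <- stats::setNames(Re(op$coeffs), op$labels)
  plans <- lapply(groups, function(g) {
    rot <- rotated_members(g)
    zmask <- vapply(rot$diagonal, function(d) {
      bits <- strsplit(d, "")[[1L]] == "Z"
      sum(bitwShiftL(1L, (n - which(bits))))
    }, numeric(1))
    lam <- t(vapply(seq_len(nrow(rot)), function(j) {
      if (zmask[[j]] == 0) rep(1, length(idx))
      else 1 - 2 * .popcount_parity(idx, as.integer(zmask[[j]]))
    }, numeric(length(idx))))
    list(group = g,
         rotation = if (!is.null(g$rotation)) g$rotation
                    else rotation_circuit(g),
         weights = as.numeric(coef[rot$label]) * rot$sign,
         lambda = lam)
  })
  structure(list(groups = plans, n_qubits = n, operator = op, mode = mode),
            class = "measurement_plan")
}

# expectation of the plan's operator from a statevector, exactly or sampled
.plan_estimate <- function(plan, psi, shots = NULL) {
  total <- 0
  for (pl in plan$groups) {
    phi <- simulate_statevector(pl$rotation, psi0 = psi)
    p <- Mod(phi)^2
    freq <- if (is.null(shots)) p else {
      stats::rmultinom(1, shots, p)[, 1L] / shots
    }
    total <- total + sum(pl$weights * as.numeric(pl$lambda %*% freq))
  }
  total
}

# expectation from a counts histogram (noisy backend), one group
.plan_group_from_counts <- function(pl, cts, n) {
  freq <- numeric(2L^n)
  freq[.det_index(names(cts$histogram)) + 1L] <- cts$histogram
  freq <- freq / cts$shots
  sum(pl$weights * as.numeric(pl$lambda %*% freq))
}

# ---------------------------------------------------------------------------
# cost specification

#' Specify an FS-VQE cost function
#'
#' The cost is \eqn{\langle\Psi(\theta)|\hat O|\Psi(\theta)\rangle}
#' for `operator` (the Hamiltonian, or the folded operator
#' \eqn{(\hat H-\omega)^2}), optionally regularized by a continuity
#' penalty \eqn{\eta\,\lVert\theta-\theta_{prev}\rVert^2} used during
#' potential-energy-surface tracking.
#'
#' @param operator a Hermitian `pauli_sum`.
#' @param omega the folding target energy, or `NULL` for a plain
#'   Hamiltonian cost (recorded for bookkeeping only).
#' @param eta continuity weight, >= 0; positive values require
#'   `theta_prev`.
#' @param theta_prev previous physical parameter vector.
#' @return object of class `cost_spec`.
#' @export
cost_spec <- function(operator, omega = NULL, eta = 0, theta_prev = NULL) {
  if (eta < 0) stop("eta must be nonnegative")
  if (eta > 0 && is.null(theta_prev)) {
    stop("a positive continuity weight requires theta_prev")
  }
  structure(list(operator = operator, omega = omega, eta = eta,
                 theta_prev = theta_prev), class = "cost_spec")
}

# closure evaluating the cost; all randomness flows from the caller's RNG
.make_cost <- function(spec, ansatz, reference, backend,
                       noise = NULL, grouping = "qwc") {
  plan <- .measurement_plan(spec$operator, grouping)
  n <- ansatz$n_qubits
  prep <- prepare_reference(reference, n)
  psi0 <- simulate_statevector(prep)
  cs <- ansatz$c_scale
  full_circ <- if (backend == "noisy") {
    qc_append(prep, ansatz$circuit)
  } else NULL
  n_evals <- 0L
  penalty <- function(x) {
    if (spec$eta > 0) {
      spec$eta * sum((x / cs - spec$theta_prev)^2)
    } else 0
  }
  dense <- if (backend == "statevector") pauli_to_matrix(spec$operator) else NULL
  fn <- function(x, shots = NULL) {
    n_evals <<- n_evals + 1L
    if (backend == "statevector") {
      # exact backend: dense quadratic form; equals the grouped
      # exact-population estimate (asserted by the regrouping tests)
      psi <- .ucc_apply(psi0, ansatz$terms, x / cs)
      val <- Re(sum(Conj(psi) * (dense %*% psi)))
    } else if (backend == "sampled") {
      psi <- .ucc_apply(psi0, ansatz$terms, x / cs)
      val <- .plan_estimate(plan, psi, shots = shots)
    } else {
      val <- 0
      for (pl in plan$groups) {
        circ <- qc_append(full_circ, pl$rotation)
        cts <- simulate_noisy(circ, x, noise, shots = shots)
        val <- val + .plan_group_from_counts(pl, cts, n)
      }
    }
    if (is.na(val)) {
      cond <- structure(
        class = c("fsvqe_divergence", "error", "condition"),
        list(message = "cost evaluation returned NaN", call = sys.call()))
      stop(cond)
    }
    val + penalty(x)
  }
  attr(fn, "evals") <- function() n_evals
  attr(fn, "plan") <- plan
  fn
}

#' Evaluate an FS-VQE cost at given parameters
#'
#' @param spec a `cost_spec`.
#' @param theta physical parameter vector (radians).
#' @param ansatz a `uccsd_ansatz`.
#' @param reference a `reference_state`.
#' @param backend `"statevector"`, `"sampled"`, or `"noisy"`.
#' @param shots shots per group circuit (sampled/noisy backends).
#' @param noise `noise_params` for the noisy backend.
#' @param seed optional RNG seed for the sampling step.
#' @return real cost value (Hartree, or Hartree^2 for a folded operator).
#' @export
evaluate_cost <- function(spec, theta, ansatz, reference,
                          backend = c("statevector", "sampled", "noisy"),
                          shots = 10000, noise = NULL, seed = NULL) {
  backend <- match.arg(backend)
  if (!is.null(seed)) set.seed(seed)
  fn <- .make_cost(spec, ansatz, reference, backend, noise)
  fn(theta * ansatz$c_scale, shots = shots)
}

# ---------------------------------------------------------------------------
# shot scheduler

#' Inverse-exponential shot schedule
#'
#' \eqn{s(t) = \mathrm{round}(s_{max} - (s_{max}-s_{min}) e^{-kt})}: the
#' per-evaluation shot count grows from `s_min` toward `s_max` as the
#' optimization approaches the optimum, where measurement accuracy
#' matters most.
#'
#' @param s_min,s_max shot bounds (defaults 1000 and 10000).
#' @param rate exponential rate k > 0 (default 0.01).
#' @param final_shots shots for the final post-optimization measurement
#'   (default 30000).
#' @return object of class `shot_schedule`.
#' @export
shot_schedule <- function(s_min = 1000, s_max = 10000, rate = 0.01,
                          final_shots = 30000) {
  if (rate <= 0) stop("rate must be positive")
  if (s_min > s_max) stop("s_min must not exceed s_max")
  structure(list(s_min = s_min, s_max = s_max, rate = rate,
                 final_shots = final_shots), class = "shot_schedule")
}

#' Shots at iteration t of a schedule
#' @param sched a `shot_schedule`.
#' @param t iteration index, >= 0.
#' @return integer shot count, nondecreasing in `t`.
#' @export
shots_at <- function(sched, t) {
  as.integer(round(sched$s_max - (sched$s_max - sched$s_min) *
                     exp(-sched$rate * t)))
}

# ---------------------------------------------------------------------------
# SPSA

#' SPSA optimizer configuration
#'
#' Gain sequences follow the standard Spall form
#' \eqn{a_k = a/(k+1+A)^\alpha}, \eqn{c_k = c_0/(k+1)^\gamma}. When `a`
#' is `NULL` it is calibrated from a few probe gradient estimates so the
#' expected first step has magnitude `target_step`.
#'
#' @param a gain numerator; `NULL` for calibration.
#' @param c0 perturbation magnitude (optimizer-variable units).
#' @param A stability constant; defaults to 10% of `maxiter`.
#' @param alpha,gamma gain decay exponents (Spall defaults).
#' @param maxiter maximum iterations.
#' @param grad_tol convergence threshold on the smoothed gradient-estimate
#'   norm (default 1e-9).
#' @param grad_window smoothing window (iterations) for the gradient norm.
#' @param target_step calibrated magnitude of the first update.
#' @param n_calibrate probe evaluations used for calibration.
#' @param max_step per-iteration cap on the update norm (optimizer
#'   units). The calibrated gain reflects the gradient scale at the
#'   start point; when the landscape is much steeper elsewhere the raw
#'   update can overshoot violently, so updates are clipped to this
#'   trust radius.
#' @return object of class `spsa_config`.
#' @export
spsa_config <- function(a = NULL, c0 = 0.2, A = NULL, alpha = 0.602,
                        gamma = 0.101, maxiter = 350, grad_tol = 1e-9,
                        grad_window = 10, target_step = 0.05,
                        n_calibrate = 5, max_step = 0.25) {
  if (grad_tol <= 0) stop("grad_tol must be positive")
  if (!is.null(a) && a <= 0 || c0 <= 0) stop("gains must be positive")
  if (max_step <= 0) stop("max_step must be positive")
  structure(list(a = a, c0 = c0, A = A, alpha = alpha, gamma = gamma,
                 maxiter = maxiter, grad_tol = grad_tol,
                 grad_window = grad_window, target_step = target_step,
                 n_calibrate = n_calibrate, max_step = max_step),
            class = "spsa_config")
}

#' Minimize a cost function with SPSA
#'
#' Each iteration draws one Rademacher perturbation, evaluates the cost
#' at theta +/- c_k Delta (exactly two evaluations), and steps along the
#' simultaneous-perturbation gradient estimate. Stops when the smoothed
#' gradient-estimate norm falls below `cfg$grad_tol` or at
#' `cfg$maxiter`. Fully reproducible for a fixed RNG state.
#'
#' @param fn cost function `fn(x, shots)`.
#' @param theta0 start vector (optimizer scale).
#' @param cfg a `spsa_config`.
#' @param sched a `shot_schedule` supplying per-iteration shots.
#' @return list: `theta`, `trace` (data.frame iter/cost/shots/gnorm),
#'   `converged`, `iterations`, `n_evaluations`.
#' @export
spsa_minimize <- function(fn, theta0, cfg = spsa_config(),
                          sched = shot_schedule()) {
  d <- length(theta0)
  A <- cfg$A %||% ceiling(0.1 * cfg$maxiter)
  a <- cfg$a
  if (is.null(a)) {
    gmag <- numeric(cfg$n_calibrate)
    for (i in seq_len(cfg$n_calibrate)) {
      delta <- sample(c(-1, 1), d, replace = TRUE)
      s0 <- shots_at(sched, 0)
      fp <- fn(theta0 + cfg$c0 * delta, shots = s0)
      fm <- fn(theta0 - cfg$c0 * delta, shots = s0)
      gmag[[i]] <- abs(fp - fm) / (2 * cfg$c0)
    }
    gbar <- max(mean(gmag), 1e-8)
    a <- cfg$target_step * (A + 1)^cfg$alpha / gbar
  }
  x <- theta0
  trace <- data.frame(iter = integer(0), cost = numeric(0),
                      shots = integer(0), gnorm = numeric(0))
  gnorm_hist <- numeric(0)
  converged <- FALSE
  n_eval <- 0L
  iter <- 0L
  for (k in seq_len(cfg$maxiter)) {
    iter <- k
    s_k <- shots_at(sched, k - 1L)
    a_k <- a / (k + A)^cfg$alpha
    c_k <- cfg$c0 / k^cfg$gamma
    delta <- sample(c(-1, 1), d, replace = TRUE)
    fp <- fn(x + c_k * delta, shots = s_k)
    fm <- fn(x - c_k * delta, shots = s_k)
    n_eval <- n_eval + 2L
    ghat <- (fp - fm) / (2 * c_k) * delta
    step <- a_k * ghat
    snorm <- sqrt(sum(step^2))
    if (snorm > cfg$max_step) step <- step * (cfg$max_step / snorm)
    x <- x - step
    gn <- sqrt(sum(ghat^2))
    gnorm_hist <- c(gnorm_hist, gn)
    smooth <- mean(utils::tail(gnorm_hist, cfg$grad_window))
    trace <- rbind(trace, data.frame(iter = k, cost = (fp + fm) / 2,
                                     shots = s_k, gnorm = smooth))
    if (length(gnorm_hist) >= cfg$grad_window && smooth < cfg$grad_tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = x, trace = trace, converged = converged,
       iterations = iter, n_evaluations = n_eval)
}

# ---------------------------------------------------------------------------
# post-optimization processing

#' Refine parameters by local parabola fits
#'
#' Probes `n_probe` points around each parameter (spacing `radius` in
#' physical radians), least-squares fits a parabola, and moves to its
#' vertex when the local curvature is positive and the re-evaluated cost
#' does not increase. Never returns a parameter set with a measured cost
#' above the input's.
#'
#' @param fn cost function `fn(x, shots)` on the optimizer scale.
#' @param x parameter vector (optimizer scale).
#' @param c_scale parameter scaling constant.
#' @param shots evaluation shots (`NULL` for exact backends).
#' @param radius probe spacing, radians (default 0.05).
#' @param n_probe probes per parameter (default 5, centered).
#' @return refined parameter vector.
#' @export
quadratic_refine <- function(fn, x, c_scale = 2, shots = NULL,
                             radius = 0.05, n_probe = 5) {
  best_cost <- fn(x, shots = shots)
  offsets <- (seq_len(n_probe) - (n_probe + 1) / 2) * radius * c_scale
  for (i in seq_along(x)) {
    costs <- vapply(offsets, function(o) {
      xi <- x; xi[[i]] <- xi[[i]] + o
      fn(xi, shots = shots)
    }, numeric(1))
    fit <- stats::lm.fit(cbind(1, offsets, offsets^2), costs)
    curv <- fit$coefficients[[3L]]
    if (!is.finite(curv) || curv <= 0) next     # non-convex local fit
    vertex <- -fit$coefficients[[2L]] / (2 * curv)
    cand <- x; cand[[i]] <- cand[[i]] + vertex
    cand_cost <- fn(cand, shots = shots)
    if (cand_cost <= best_cost) {
      x <- cand
      best_cost <- cand_cost
    }
  }
  x
}

#' Round near-special angles when that does not hurt the cost
#'
#' Parameters whose physical angle lies within `tol` of 0, +/-pi/2 or
#' +/-pi are candidates; each rounding is kept only if the evaluated
#' cost does not increase (symmetric systems frequently have exact
#' optima at those angles).
#'
#' @param fn cost function `fn(x, shots)` on the optimizer scale.
#' @param x parameter vector (optimizer scale).
#' @param c_scale parameter scaling constant.
#' @param shots evaluation shots (`NULL` for exact backends).
#' @param tol rounding capture radius, radians (default 0.02).
#' @return parameter vector with accepted roundings applied.
#' @export
round_parameters <- function(fn, x, c_scale = 2, shots = NULL, tol = 0.02) {
  candidates <- c(0, pi / 2, -pi / 2, pi, -pi)
  best_cost <- fn(x, shots = shots)
  for (i in seq_along(x)) {
    phys <- x[[i]] / c_scale
    hits <- candidates[abs(phys - candidates) < tol]
    if (length(hits) == 0L) next
    cand <- x; cand[[i]] <- hits[[1L]] * c_scale
    cand_cost <- fn(cand, shots = shots)
    if (cand_cost <= best_cost) {
      x <- cand
      best_cost <- cand_cost
    }
  }
  x
}

# ---------------------------------------------------------------------------
# exact diagonalization reference

#' Exact eigenvalues of a qubit Hamiltonian
#'
#' Dense diagonalization of the matrix realization; the full
#' configuration interaction (FCI) reference for all error statements.
#' Optionally restricts to the eigenstates carrying a given particle
#' number (identified through the JW number operator), which is the
#' physical sector for comparisons with molecular states.
#'
#' @param h a Hermitian `pauli_sum` on at most 12 qubits.
#' @param n_electrons when given, keep only eigenvalues whose
#'   eigenvector has this JW particle number.
#' @return ascending numeric eigenvalues (Hartree).
#' @export
fci_energies <- function(h, n_electrons = NULL) {
  if (is.null(n_electrons)) {
    return(sort(Re(eigen(pauli_to_matrix(h), symmetric = TRUE,
                         only.values = TRUE)$values)))
  }
  ev <- eigen(pauli_to_matrix(h), symmetric = TRUE)
  nmat <- pauli_to_matrix(jw_number_operator(h$n_qubits))
  nel <- Re(colSums(Conj(ev$vectors) * (nmat %*% ev$vectors)))
  sort(Re(ev$values[abs(nel - n_electrons) < 1e-6]))
}

#' JW particle-number operator
#' @param n number of qubits.
#' @return a `pauli_sum` equal to \eqn{\sum_j (I - Z_j)/2}.
#' @export
jw_number_operator <- function(n) {
  zlabs <- vapply(seq_len(n) - 1L, function(j) {
    paste0(strrep("I", j), "Z", strrep("I", n - j - 1L))
  }, character(1))
  pauli_sum(c(strrep("I", n), zlabs), c(n / 2, rep(-0.5, n)), n, tol = 0)
}

# ---------------------------------------------------------------------------
# the fitting function

#' Fit an FS-VQE model for one electronic state
#'
#' Runs the (folded-spectrum) variational quantum eigensolver on a
#' molecular system: prepares the reference state, applies the ordered
#' Trotterized UCCSD ansatz, minimizes either the Hamiltonian
#' expectation (`omega = NULL`, ground-state VQE) or the folded cost
#' \eqn{\langle(\hat H-\omega)^2\rangle} (excited states), and measures
#' the final energy \eqn{\langle\hat H\rangle}.
#'
#' @param mi a `molecular_integrals` object.
#' @param reference a `reference_state`; defaults to the Hartree-Fock
#'   determinant.
#' @param omega folding target energy in Hartree, `"auto"` to use the
#'   reference-state expectation of the Hamiltonian, or `NULL` for a
#'   plain ground-state VQE.
#' @param backend `"statevector"` (exact), `"sampled"` (ideal device
#'   with finite shots), or `"noisy"` (density-matrix noise model).
#' @param optimizer `"spsa"` or `"bfgs"`; defaults to BFGS on the exact
#'   backend and SPSA otherwise.
#' @param theta0 start vector of physical angles (default zeros).
#' @param theta_prev,eta continuity regularization for PES tracking:
#'   adds `eta * ||theta - theta_prev||^2` to the cost when `eta > 0`.
#' @param c_scale parameter scaling constant (default 2).
#' @param spsa a `spsa_config`.
#' @param schedule a `shot_schedule`.
#' @param noise `noise_params` for the noisy backend.
#' @param seed integer seed controlling every random draw of the run.
#' @param refine,round_angles toggles for the post-optimization parabola
#'   refinement and special-angle rounding.
#' @param omega_update number of additional passes in which omega is
#'   reset to the measured energy and the optimization is restarted from
#'   the current parameters (0 disables).
#' @param n_restarts number of optimization starts on the exact
#'   backend (the first from `theta0`, the rest from seeded random
#'   points); the lowest-cost solution is kept. Ignored for SPSA.
#' @param hamiltonian optionally a precomputed `pauli_sum` (avoids
#'   rebuilding in scans).
#' @param ansatz optionally a precomputed `uccsd_ansatz`.
#' @return An object of class `fsvqe`. Key fields: `energy` (Hartree),
#'   `theta` (physical angles), `omega`, `cost`, `converged`, `trace`,
#'   `n_evaluations`. Methods: `print`, `summary`, `coef`, `plot`,
#'   `simulate`.
#' @examples
#' \donttest{
#' mi <- read_integrals(fixture_path("H2", 0.74))
#' fit <- fsvqe(mi, backend = "statevector")
#' print(fit)
#' }
#' @export
fsvqe <- function(mi, reference = NULL, omega = NULL,
                  backend = c("statevector", "sampled", "noisy"),
                  optimizer = NULL, theta0 = NULL, theta_prev = NULL,
                  eta = 0, c_scale = 2,
                  spsa = spsa_config(), schedule = shot_schedule(),
                  noise = NULL, seed = 1L,
                  refine = TRUE, round_angles = TRUE, omega_update = 0L,
                  n_restarts = 1L, hamiltonian = NULL, ansatz = NULL) {
  backend <- match.arg(backend)
  if (backend == "noisy" && is.null(noise)) {
    stop("the noisy backend requires noise_params")
  }
  h <- hamiltonian %||% build_hamiltonian(mi)
  n <- h$n_qubits
  ansatz <- ansatz %||% uccsd_ansatz(hf_determinant(mi), n, c_scale)
  reference <- reference %||% reference_state(hf_determinant(mi))
  optimizer <- optimizer %||% if (backend == "statevector") "bfgs" else "spsa"
  set.seed(seed)
  psi_ref <- simulate_statevector(prepare_reference(reference, n))
  if (identical(omega, "auto")) omega <- ps_expectation(h, psi_ref)
  folded <- if (!is.null(omega)) fold_spectrum(h, omega) else NULL
  run_once <- function(omega_k, x_start, eta_k = eta,
                       theta_prev_k = theta_prev) {
    op <- if (!is.null(omega_k)) fold_spectrum(h, omega_k)$folded else h
    spec <- cost_spec(op, omega = omega_k, eta = eta_k,
                      theta_prev = theta_prev_k)
    fn <- .make_cost(spec, ansatz, reference, backend, noise)
    if (optimizer == "spsa") {
      res <- spsa_minimize(fn, x_start, spsa, schedule)
    } else {
      opt <- stats::optim(x_start, function(x) fn(x, shots = NULL),
                          method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-15,
                                         ndeps = rep(1e-6, max(1, length(x_start)))))
      res <- list(theta = opt$par,
                  trace = data.frame(iter = seq_len(opt$counts[[1L]]),
                                     cost = NA_real_, shots = NA_integer_,
                                     gnorm = NA_real_),
                  converged = opt$convergence == 0,
                  iterations = opt$counts[[1L]],
                  n_evaluations = attr(fn, "evals")())
    }
    x <- res$theta
    eval_shots <- if (backend == "statevector") NULL else schedule$final_shots
    if (refine) {
      # two sweeps: the first absorbs most of the optimizer's residual
      # drift, the second polishes cross-parameter couplings
      x <- quadratic_refine(fn, x, c_scale = c_scale, shots = eval_shots)
      x <- quadratic_refine(fn, x, c_scale = c_scale, shots = eval_shots)
    }
    if (round_angles) {
      x <- round_parameters(fn, x, c_scale = c_scale, shots = eval_shots)
    }
    res$theta <- x
    res$cost <- fn(x, shots = eval_shots)
    res$n_evaluations <- attr(fn, "evals")()
    res
  }
  x0 <- (theta0 %||% numeric(ansatz$n_parameters)) * c_scale
  res <- run_once(omega, x0)
  if (optimizer == "bfgs" && n_restarts > 1L) {
    for (r in seq_len(n_restarts - 1L)) {
      alt <- run_once(omega, stats::runif(length(x0), -2, 2) * c_scale / 2)
      if (alt$cost < res$cost) res <- alt
    }
  }
  k <- 0L
  plan_h <- .measurement_plan(h, "qwc")
  measure_energy <- function(x) {
    if (backend == "noisy") {
      prep <- prepare_reference(reference, n)
      circ0 <- qc_append(prep, ansatz$circuit)
      val <- 0
      for (pl in plan_h$groups) {
        cts <- simulate_noisy(qc_append(circ0, pl$rotation), x, noise,
                              shots = schedule$final_shots)
        val <- val + .plan_group_from_counts(pl, cts, n)
      }
      val
    } else {
      psi <- .ucc_apply(psi_ref, ansatz$terms, x / c_scale)
      .plan_estimate(plan_h, psi,
                     shots = if (backend == "statevector") NULL
                             else schedule$final_shots)
    }
  }
  energy <- measure_energy(res$theta)
  while (!is.null(omega) && k < omega_update) {
    # refresh the folding target to the measured energy and re-optimize
    # from (and tethered near) the current parameters: the refreshed
    # detuning is small, so a continuity penalty keeps the pass from
    # hopping to a neighboring state's basin
    k <- k + 1L
    omega <- energy
    res <- run_once(omega, res$theta,
                    eta_k = if (eta > 0) eta else 0.1,
                    theta_prev_k = res$theta / c_scale)
    energy <- measure_energy(res$theta)
  }
  structure(list(
    energy = energy,
    theta = res$theta / c_scale,
    omega = omega,
    cost = res$cost,
    converged = res$converged,
    iterations = res$iterations,
    n_evaluations = res$n_evaluations,
    trace = res$trace,
    backend = backend,
    optimizer = optimizer,
    reference = reference,
    hamiltonian = h,
    ansatz = ansatz,
    noise = noise,
    schedule = schedule,
    seed = seed,
    geometry_id = mi$geometry_id,
    molecule = mi$molecule,
    call = match.call()), class = "fsvqe")
}

#' @export
print.fsvqe <- function(x, ...) {
  kind <- if (is.null(x$omega)) "VQE (ground state)" else "FS-VQE"
  cat(sprintf("%s fit: %s at %s A [%s/%s]\n", kind, x$molecule,
              x$geometry_id, x$backend, x$optimizer))
  if (!is.null(x$omega)) {
    cat(sprintf("  target omega: %.8f Ha\n", x$omega))
  }
  cat(sprintf("  energy <H>:   %.8f Ha\n", x$energy))
  cat(sprintf("  final cost:   %.3e  (%s after %d iteration(s), %d evaluation(s))\n",
              x$cost, if (x$converged) "converged" else "not converged",
              x$iterations, x$n_evaluations))
  invisible(x)
}

#' @export
coef.fsvqe <- function(object, ...) {
  stats::setNames(object$theta,
                  vapply(object$ansatz$excitations, function(e) {
                    sprintf("%s(%s->%s)",
                            if (e$rank == 1L) "s" else "d",
                            paste(e$occ, collapse = ","),
                            paste(e$virt, collapse = ","))
                  }, character(1)))
}

#' @export
summary.fsvqe <- function(object, ...) {
  fci <- if (object$hamiltonian$n_qubits <= 8L) {
    nel <- sum(strsplit(object$reference$determinants[[1L]], "")[[1L]] == "1")
    fci_energies(object$hamiltonian, n_electrons = nel)
  } else NULL
  err <- if (!is.null(fci)) min(abs(object$energy - fci)) else NA_real_
  out <- list(fit = object, coef = coef(object), fci_error = err,
              fci = fci)
  class(out) <- "summary.fsvqe"
  out
}

#' @export
print.summary.fsvqe <- function(x, ...) {
  print(x$fit)
  cat("  parameters (rad):\n")
  for (nm in names(x$coef)) {
    cat(sprintf("    %-14s %+.8f\n", nm, x$coef[[nm]]))
  }
  if (!is.na(x$fci_error)) {
    cat(sprintf("  |E - FCI|: %.3e Ha (%.4f kcal/mol)\n",
                x$fci_error, x$fci_error * HARTREE_TO_KCAL))
  }
  invisible(x)
}

#' @export
plot.fsvqe <- function(x, ...) {
  tr <- x$trace
  if (all(is.na(tr$cost))) {
    warning("no per-iteration trace recorded for this optimizer")
    return(invisible(x))
  }
  graphics::plot(tr$iter, tr$cost, type = "l", xlab = "SPSA iteration",
                 ylab = "cost", main = "FS-VQE optimization trace", ...)
  invisible(x)
}

#' Sample measurement counts from a fitted FS-VQE state
#'
#' @param object a fitted `fsvqe` model.
#' @param nsim number of shots.
#' @param seed optional seed.
#' @param ... unused.
#' @return a `counts` object drawn from the optimized state's
#'   computational-basis populations.
#' @export
simulate.fsvqe <- function(object, nsim = 1000, seed = NULL, ...) {
  n <- object$hamiltonian$n_qubits
  psi0 <- simulate_statevector(prepare_reference(object$reference, n))
  psi <- .ucc_apply(psi0, object$ansatz$terms, object$theta)
  sample_counts(psi, nsim, seed = seed)
}

# ---------------------------------------------------------------------------
# potential-energy-surface scan

#' Scan a potential-energy surface with state tracking
#'
#' Runs FS-VQE along an ascending geometry grid for one or more
#' electronic states. For each state, point k+1 starts from the
#' converged parameters of point k and folds around
#' \eqn{\omega_{k+1} = E_k} (state tracking); the first point uses the
#' reference-state energy as omega. A point whose converged energy jumps
#' by more than `jump_tol` from its omega is flagged and re-optimized
#' once with the continuity penalty (`eta`) engaged.
#'
#' @param molecule `"H2"` or `"LiH"` (packaged fixtures).
#' @param bond_lengths ascending geometries (Angstrom); defaults to the
#'   shipped fixture grid.
#' @param states named list of `reference_state`s (`NULL` entries mean
#'   ground-state VQE); defaults to [h2_reference_states()] for H2.
#' @param backend,optimizer,seed,... forwarded to [fsvqe()].
#' @param eta continuity weight for flagged re-runs (default 0.1).
#' @param jump_tol energy jump (Hartree) that triggers a penalized
#'   re-run (default 0.15).
#' @param track_omega when `TRUE` (default) the folding target follows
#'   the previous geometry's energy, `omega_{k+1} = E_k`; when `FALSE`
#'   every point folds around its own reference-state expectation.
#'   Tracking presumes adjacent geometries close enough that the state's
#'   energy moves less than the local level spacing; on a coarse grid
#'   the per-point reference target is the reliable choice.
#' @return An object of class `fsvqe_pes`: a results data.frame
#'   (`geometry`, `state`, `energy`, `omega`, `fci`, `error_fci`,
#'   `converged`, `flagged`) plus the per-point fits. FCI errors are
#'   measured against the particle-number sector of the molecule.
#' @export
fsvqe_pes <- function(molecule = "H2", bond_lengths = NULL, states = NULL,
                      backend = "sampled", optimizer = NULL, seed = 1L,
                      eta = 0.1, jump_tol = 0.15, track_omega = TRUE, ...) {
  bond_lengths <- bond_lengths %||% fixture_grid(molecule)
  states <- states %||% if (molecule == "H2") h2_reference_states()
                        else lih_reference_states()
  rows <- list()
  fits <- list()
  for (sname in names(states)) {
    theta_prev <- NULL
    omega_prev <- NULL
    for (gi in seq_along(bond_lengths)) {
      L <- bond_lengths[[gi]]
      mi <- read_integrals(fixture_path(molecule, L))
      h <- build_hamiltonian(mi)
      ref <- states[[sname]]
      omega_k <- if (is.null(ref)) NULL
                 else if (is.null(omega_prev) || !track_omega) "auto"
                 else omega_prev
      run_seed <- seed + 1000L * gi + 17L * match(sname, names(states))
      fit <- fsvqe(mi, reference = ref, omega = omega_k, backend = backend,
                   optimizer = optimizer, theta0 = theta_prev,
                   seed = run_seed, hamiltonian = h, ...)
      flagged <- FALSE
      if (!is.null(fit$omega) && !is.null(theta_prev) &&
          abs(fit$energy - fit$omega) > jump_tol) {
        # the folded target captured a neighboring state; re-run once,
        # tracking the previous point's energy and penalizing parameter
        # discontinuity
        flagged <- TRUE
        omega_retry <- if (!is.null(omega_prev)) omega_prev else omega_k
        fit <- fsvqe(mi, reference = ref, omega = omega_retry,
                     backend = backend,
                     optimizer = optimizer, theta0 = theta_prev,
                     theta_prev = theta_prev, eta = eta,
                     seed = run_seed + 1L, hamiltonian = h, ...)
      }
      fci <- fci_energies(h, n_electrons = mi$n_electrons)
      fci_match <- fci[[which.min(abs(fit$energy - fci))]]
      rows[[length(rows) + 1L]] <- data.frame(
        geometry = L, state = sname, energy = fit$energy,
        omega = if (is.null(fit$omega)) NA_real_ else fit$omega,
        fci = fci_match, error_fci = abs(fit$energy - fci_match),
        converged = fit$converged, flagged = flagged,
        stringsAsFactors = FALSE)
      fits[[paste(sname, L)]] <- fit
      theta_prev <- fit$theta
      omega_prev <- fit$energy   # omega_{k+1} = E_k
    }
  }
  structure(list(results = do.call(rbind, rows), fits = fits,
                 molecule = molecule, backend = backend, seed = seed),
            class = "fsvqe_pes")
}

#' @export
print.fsvqe_pes <- function(x, ...) {
  cat(sprintf("<fsvqe_pes: %s, %d point(s) on backend '%s'>\n",
              x$molecule, nrow(x$results), x$backend))
  df <- x$results
  df$error_kcal <- df$error_fci * HARTREE_TO_KCAL
  print(df, row.names = FALSE, digits = 7)
  invisible(x)
}

#' @export
plot.fsvqe_pes <- function(x, ...) {
  df <- x$results
  sts <- unique(df$state)
  cols <- seq_along(sts)
  graphics::plot(range(df$geometry), range(c(df$energy, df$fci)),
                 type = "n", xlab = "bond length (Angstrom)",
                 ylab = "energy (Hartree)",
                 main = paste(x$molecule, "potential energy curves"), ...)
  for (i in seq_along(sts)) {
    d <- df[df$state == sts[[i]], ]
    graphics::lines(d$geometry, d$fci, col = cols[[i]], lty = 2)
    graphics::points(d$geometry, d$energy, col = cols[[i]], pch = 19)
  }
  graphics::legend("topright", legend = sts, col = cols, pch = 19, bty = "n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# reference-state catalogs for the shipped systems

#' Excited-state references for H2/STO-3G
#'
#' Interleaved spin-orbital ordering (sigma_g up, sigma_g down, sigma_u
#' up, sigma_u down). T1 is the Ms = 1 open-shell determinant, S1 the
#' spin-symmetrized open-shell singlet combination, S2 the doubly
#' excited closed-shell determinant. The relative sign inside the
#' singlet combination is fixed by this package's determinant-phase
#' convention (Jordan-Wigner operator ordering): the combination below
#' is the one orthogonal to the Ms = 0 triplet.
#'
#' @return named list of `reference_state`s.
#' @export
h2_reference_states <- function() {
  list(
    T1 = reference_state("1010"),
    S1 = reference_state(c("1001", "0110"), c(1, -1) / sqrt(2)),
    S2 = reference_state("0011"))
}

#' Excited-state references for LiH (s-orbital minimal basis)
#'
#' Three sigma spatial orbitals with interleaved spins; references are
#' single determinants (Ms = 1 for triplets) or spin-symmetrized
#' two-determinant open-shell singlet combinations, built from single
#' and double excitations of the Hartree-Fock determinant `111100`.
#' Singlet signs follow the package's determinant-phase convention
#' (the combination orthogonal to the corresponding Ms = 0 triplet).
#'
#' @return named list of `reference_state`s.
#' @export
lih_reference_states <- function() {
  list(
    T1 = reference_state("111010"),
    S1 = reference_state(c("111001", "110110"), c(1, -1) / sqrt(2)),
    S2 = reference_state("110011"),
    T2 = reference_state("101110"),
    S3 = reference_state(c("101101", "011110"), c(1, -1) / sqrt(2)),
    T3 = reference_state("101011"),
    S4 = reference_state(c("100111", "011011"), c(1, -1) / sqrt(2)),
    S5 = reference_state("001111"))
}
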