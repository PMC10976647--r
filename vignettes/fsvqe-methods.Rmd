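---
title: "Folded-spectrum VQE: model, measurement reduction and error mitigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Folded-spectrum VQE: model, measurement reduction and error mitigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsvqe)
```

# The model

The variational quantum eigensolver (VQE) minimizes
$\langle\Psi(\theta)|\hat H|\Psi(\theta)\rangle$ over the parameters of
a quantum circuit and, by the variational principle, approximates the
ground state of a molecular Hamiltonian. This package implements the
folded-spectrum (FS) extension for excited states: instead of
$\hat H$, the cost is the expectation of the folded operator

$$\hat F_\omega = (\hat H - \omega)^2,$$

where $\omega$ is a target energy in Hartree. $\hat F_\omega$ shares
the eigenvectors of $\hat H$ while its eigenvalues fold to
$(E_i - \omega)^2$, so the minimizer of the folded cost is the
eigenstate whose energy lies closest to $\omega$. Any excited state
can therefore be reached directly, with the same circuit used for the
ground state, by moving a single scalar.

The package is a full simulation stack for this method: second-quantized
Hamiltonians from packaged spin-orbital integrals, Jordan–Wigner (JW)
mapping, phase-exact Pauli algebra for the reduction of
$(\hat H-\omega)^2$, commuting-group measurement, statevector /
finite-shot / density-matrix noise backends, SPSA optimization, and
SPAM + zero-noise-extrapolation error mitigation.

## Hamiltonians and conventions

Spin-orbitals are interleaved by spatial orbital
($\alpha, \beta, \alpha, \beta, \dots$), qubit $j$ hosts spin-orbital
$j$, and $|1\rangle$ means occupied. Pauli labels, bitstrings and the
Kronecker order of matrix realizations all place qubit 0 leftmost (most
significant). The JW image of the creation operator is
$a_j^\dagger \mapsto Z_0\cdots Z_{j-1}\,(X_j - iY_j)/2$, which maps the
vacuum to $|0\cdots0\rangle$. Two-body integrals are stored in
physicist notation $\langle pq|rs\rangle$; the fixture generator
converts from what its Hartree–Fock engine produces.

Under these conventions the H$_2$/STO-3G Hamiltonian (4 spin-orbitals,
2 electrons) maps to exactly 15 Pauli strings at every geometry of the
fixture grid, and the LiH s-orbital-only Hamiltonian (6 spin-orbitals,
4 electrons, no frozen core) to 118 strings at 1.60 Å.

## Folding without term blow-up

$(\hat H - \omega)^2$ naively squares the term count. The package
multiplies Pauli sums with exact integer phase bookkeeping (each
single-qubit product contributes a power of $i$ tracked as an integer),
so cross terms from anticommuting string pairs cancel *exactly* rather
than leaving numerical dust, and duplicate labels merge before pruning
(default tolerance `1e-12`, configurable). The fold is computed as
$(\hat H-\omega I)^2$ directly rather than
$\hat H^2 - 2\omega\hat H + \omega^2$, which keeps the surviving term
count independent of $\omega$. For H$_2$ the folded operator carries
24 strings: the 16 diagonal ($I/Z$-only) strings and 8 weight-4 $X/Y$
strings.

## Measurement groups

Expectations are assembled per Pauli string from measured counts.
Strings that commute qubit-wise (QWC: letters agree or meet an identity
at every position) share a single measurement after a per-qubit basis
rotation (Hadamard for $X$; $S^\dagger$ then Hadamard for $Y$). General
commutativity (GC: an even number of positions with distinct non-identity
letters) admits larger groups but requires entangling measurement
circuits, which this package does not synthesize; GC is used for
partition counting. Partitioning is the minimum clique cover problem and
NP-hard, so the package uses a deterministic greedy heuristic: sequential
coloring of the complement graph, largest degree first, ties broken
lexicographically. On H$_2$ this yields 5 QWC groups for the
Hamiltonian and 2 GC groups for both the Hamiltonian and the folded
operator; optimality is not claimed in general.

## The ansatz

The ansatz is first-order Trotterized unitary coupled cluster with
singles and doubles (UCCSD),
$\prod_e \exp\!\big(\theta_e(\hat T_e - \hat T_e^\dagger)\big)\,|\Phi_0\rangle$,
with spin-conserving excitations enumerated from the Hartree–Fock
determinant by iterating occupied indices $j$ in ascending order and
emitting, per $j$, the not-yet-emitted singles involving $j$ followed by
the doubles involving $j$. This gives 3 excitations for H$_2$ and 8 for
LiH. Each generator string becomes a Pauli gadget (basis changes, CNOT
ladder, central $R_z$, mirrored uncompute), $2(w-1)$ CNOTs for a
weight-$w$ string. The strings within one excitation's generator
mutually commute, so the intra-excitation Trotter split is exact and
only their enumeration order (lexicographic, for determinism) needs
fixing.

Two genuinely open choices are resolved as follows and recorded here:

* **Operator application order.** "Added to the ansatz first" can mean
  the first-enumerated factor acts first or last on the reference. We
  apply the factors in *reverse* enumeration order (the first-enumerated
  excitation is the leftmost factor). The choice was made by a
  representability study on the LiH fixture: against exact
  eigen-subspaces, the reversed product reaches six of the eight
  excited references exactly (infidelity at numerical zero) versus two
  for the forward product; see the limitations section for the two
  states it reaches only approximately.
* **Parameter scaling.** Optimizer variables are scaled physical
  angles, $x = c\,\theta$ with $c = 2$ by default (configurable); the
  mechanism keeps SPSA steps from stalling below the gradient
  resolution at finite shots.

## Reference states

Excited references are single determinants (X gates) or equal-weight
two-determinant superpositions prepared exactly with one Hadamard, a
CNOT fan and X gates, $(|D_1\rangle \pm |D_2\rangle)/\sqrt2$ up to a
global sign. For open-shell singlets the relative sign that selects the
singlet (rather than the $M_s=0$ triplet) depends on the
determinant-phase convention; the catalogs `h2_reference_states()` and
`lih_reference_states()` ship the combination orthogonal to the triplet
under this package's convention. The folding target for a fresh state
defaults to $\omega = \langle\mathrm{ref}|\hat H|\mathrm{ref}\rangle$;
along a geometry scan it is tracked as $\omega_{k+1} = E_k$.

# Optimization

On exact (statevector) backends the default optimizer is BFGS on the
deterministic cost. On sampled or noisy backends the package uses SPSA:
per iteration one Rademacher perturbation and exactly two cost
evaluations, gains in standard Spall form ($\alpha = 0.602$,
$\gamma = 0.101$, $A$ = 10% of the iteration budget, perturbation
magnitude $c_0 = 0.2$ in optimizer units, and the step numerator
calibrated from a few probe gradients so the first update has magnitude
0.05). Each update is additionally clipped to a 0.25 trust radius: the
calibration reflects the gradient scale at the start point, and without
the clip a run started near a stationary point (an eigenstate
reference) takes violently oversized steps once it wanders into steeper
regions. Convergence is declared when the gradient-estimate norm, smoothed
over a 10-iteration window, falls below $10^{-9}$; at finite shots the
iteration cap (default 350) is the practical stop.

Shots per evaluation follow an inverse-exponential schedule
$s(t) = s_{\max} - (s_{\max}-s_{\min})e^{-kt}$ from
$s_{\min} = 1000$ to $s_{\max} = 10000$ (only the endpoints and the
inverse-exponential trend are prescribed; this functional form is the
simplest realization of both, with $k = 0.01$ by default). The final
energy is measured at 30000 shots per group circuit.

Two post-processing steps polish the optimum: a per-parameter parabola
fit through 5 probes spaced 0.05 rad (vertex accepted only when the
local curvature is positive and the re-evaluated cost does not
increase), and rounding of parameters within 0.02 rad of
$\{0, \pm\pi/2, \pm\pi\}$, kept only when the measured cost does not
increase — symmetric systems often have exact optima at those angles.

## State tracking on a potential-energy surface

`fsvqe_pes()` scans ascending geometries, warm-starting
$\theta_{k+1} = \theta_k$ and, when `track_omega = TRUE` (the default),
folding around $\omega_{k+1} = E_k$. Tracking presumes adjacent
geometries close enough that a state's energy moves less than the
local level spacing; on the shipped five-point grid neighboring
energies shift by up to 0.9 Ha, so the packaged experiments set
`track_omega = FALSE` and fold each point around its own
reference-state expectation instead, keeping $\omega$ in the correct
basin.

A detuned target biases the converged energy: writing the trial state
as the target eigenstate plus an admixture of a neighbor at distance
$\Delta E$, the folded cost decreases linearly in the admixture
whenever another eigenvalue lies within twice the detuning
$|\omega - E|$ on the $\omega$ side, so the eigenstate is then a
saddle rather than a minimum. The packaged experiments therefore run
one $\omega$-refresh pass (`omega_update = 1`): after convergence,
$\omega$ is reset to the measured energy — shrinking the detuning by
an order of magnitude — and the optimization restarts from the current
parameters with the continuity penalty engaged so the refreshed pass
cannot hop into the neighboring basin. Molecular-orbital
phase continuity across geometries is enforced at fixture-generation
time: the generator aligns MO phases between adjacent geometries via
$P = C_k^T S_k C_{k+1}$, flipping columns whose diagonal entry is near
$-1$ (`fix_mo_phases()`); diagonal entries far from $\pm1$ indicate an
orbital-character swap and produce a warning instead of a silent fix. A
point whose converged energy jumps more than 0.15 Ha from its target is
flagged and re-optimized once with the continuity penalty
$\eta\,\lVert\theta-\theta_{\mathrm{prev}}\rVert^2$, $\eta = 0.1$.

# Noise model and mitigation

The density-matrix backend applies, after every gate and to the touched
qubits only: a depolarizing channel ($p_1$ one-qubit, $p_2$ two-qubit),
then amplitude damping with rate $1 - e^{-t_g/T_1}$ and pure dephasing
with rate derived from the *total* coherence time convention,
$1/T_\phi = 1/T_2 - 1/(2T_1)$ (the alternative reading of $T_2$ as pure
dephasing time is rejected and documented here). Idle-qubit decoherence
during other gates is not modeled. Readout flips each measured bit
independently with $p_{\mathrm{SPAM}}$. Scaling by
$\lambda \in [0,1]$ interpolates geometrically for $T_1, T_2$
(ideal values 2000 and 1000 µs) and linearly for everything else; at
$\lambda = 0.4$ this gives $T_1 = 924$ µs, $T_2 = 462$ µs,
$t_{g1} = 14$ ns, $t_{g2} = 120$ ns.

Mitigation combines two steps, applied per commuting group:

* **SPAM inversion.** The confusion matrix is extracted from
  $p_{\mathrm{SPAM}}$ (symmetric per-qubit flips), its tensor-product
  inverse applied to the empirical distribution, and the resulting
  quasi-probabilities projected onto the simplex (sort-based Euclidean
  projection — the "nearest probability distribution").
* **Zero-noise extrapolation.** Global unitary folding
  $G \mapsto G(G^\dagger G)^{(\gamma-1)/2}$ amplifies gate noise by odd
  factors $\gamma = 1, 3, 5, 7$; the per-group expectation series is
  fit with an unweighted quadratic $E_\gamma = a + b\gamma + c\gamma^2$
  and the intercept retained. Folding does not amplify SPAM error,
  which is why SPAM inversion precedes the fit. A four-point ZNE run
  consumes four times the shots of the unmitigated measurement; the
  overhead is recorded on the result object.

# Numerical choices and problem sizes

* Coefficient pruning `1e-12`; statevector backend guarded at 12
  qubits, density-matrix backend at 8.
* The exact-backend cost uses the dense matrix realization of the
  operator (identical to the grouped exact-population estimate, which
  the test suite asserts); sampled backends draw multinomial counts per
  group from precomputed eigenvalue tables.
* The shipped H$_2$ grid spans 0.50–2.00 Å in five points, chosen to
  cover equilibrium through near-dissociation; LiH ships at 1.60 Å.
  These are the problem sizes used by the packaged experiments: the
  H$_2$ accuracy study runs 5 geometries × 3 excited states on the
  sampled backend, and the mitigation study one geometry at
  $\lambda = 0.2$ with 20000 shots per circuit evaluation.
* All randomness (SPSA perturbations, multinomial sampling, readout
  flips) flows from one seed per run; equal seeds give bitwise equal
  traces.

# What the simulations do and do not show

The synthetic systems are small enough for exact diagonalization, which
is the reference for every error statement. The noise model emulates
depolarizing, relaxation and readout error with realistic magnitudes
but excludes leakage, crosstalk and idle decoherence, so mitigated
accuracies here are an optimistic bound for hardware. The LiH basis
keeps only s functions for tractability; its energies are not
physically meaningful for the real molecule and serve to exercise the
method on a larger register.

Known limitations:

* The greedy clique cover is deterministic and attains the minimal
  group counts on the shipped systems but is not optimal in general.
* General Clifford synthesis of simultaneous-measurement circuits for
  GC groups is not implemented; GC partitions are used for counting.
  One structured special case is provided: `fs_gc_groups()` measures
  the two commuting groups of a folded two-spatial-orbital operator
  (the diagonal strings, and the even-Y all-X/Y strings diagonalized
  by a CNOT fan plus Hadamard), with the diagonalization verified by
  exact Clifford conjugation.
* With the fixed reversed application order, two LiH reference states
  (S3 and S5) are represented only approximately by the disentangled
  UCCSD manifold (eigen-subspace infidelities of order $10^{-5}$ and
  $10^{-3}$ in a multistart representability study), leaving
  folded-spectrum energy residuals of roughly $5\times10^{-5}$ and
  $7\times10^{-3}$ Hartree for those two states; the other six excited
  states are recovered to $10^{-6}$ Hartree or better. No single
  admissible ordering was exact for all eight in our study (each
  ordering variant trades one subset of states against another), and
  the ordering is a package-level constant, not a per-state tuning
  knob.
* SPSA convergence at finite shots is stochastic; the reported
  energies carry the shot noise of the final 30000-shot measurement.

# A worked call

```{r example, eval = FALSE}
mi <- read_integrals(fixture_path("H2", 0.74))
fit <- fsvqe(mi, reference = h2_reference_states()$S2, omega = "auto",
             backend = "sampled", seed = 1)
summary(fit)

np <- scale_noise(noise_params(), 0.2)
mitigated_energy(fit, np, shots = 20000, gammas = c(1, 3, 5, 7), seed = 1)
```
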