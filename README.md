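# fsvqe — folded-spectrum VQE for molecular excited states

`fsvqe` is an R simulation stack for computing molecular ground **and
excited** electronic states with the variational quantum eigensolver
(VQE). Standard VQE minimizes the energy
$\langle\Psi(\theta)|\hat H|\Psi(\theta)\rangle$ of a parameterized
quantum circuit and can only reach the ground state. The
folded-spectrum (FS) method minimizes instead

$$F_\theta(\omega) \;=\; \big\langle \Psi(\theta)\,\big|\,(\hat H-\omega)^2\,\big|\,\Psi(\theta)\big\rangle ,$$

whose minimizer is the eigenstate of $\hat H$ with energy closest to
the chosen target $\omega$ — any excited state becomes directly
reachable with the same circuit. The price is that $(\hat H-\omega)^2$
naively squares the number of Pauli strings to measure; the package
implements the phase-exact Pauli reduction and commuting-group
(qubit-wise / general commutativity) measurement machinery that makes
the folded operator cheap to evaluate, e.g. H$_2$/STO-3G: 15 strings
in $\hat H$, only 24 (not 225) in $(\hat H-\omega)^2$, measurable in 2
commuting groups.

The package is aimed at quantum-algorithm and quantum-chemistry
researchers who want a fully inspectable, classical-simulation
implementation: packaged spin-orbital integrals (H$_2$/STO-3G at five
bond lengths, LiH in an s-orbital minimal basis), Jordan–Wigner
mapping, an ordered Trotterized UCCSD ansatz compiled to Pauli
gadgets, exact / finite-shot / density-matrix-with-noise backends,
SPSA optimization with an increasing shot schedule, state tracking
along potential-energy curves, and readout (SPAM) plus
zero-noise-extrapolation (ZNE) error mitigation.

## Worked example

Compute the highest singlet (S2) of H$_2$ at 0.74 Å on an ideal
shot-sampled simulator, then re-measure it under hardware-like noise
with mitigation:

```r
library(fsvqe)

mi <- read_integrals(fixture_path("H2", 0.74))
h  <- build_hamiltonian(mi)
print(h, max_terms = 3)
#> <pauli_sum: 15 term(s) on 4 qubit(s)>
#>   IIII  -0.0970662682
#>   IIIZ  -0.2234315369
#>   IIZI  -0.2234315369
#>   ...

length(pauli_groups(h, "qwc"))           # 5 simultaneous measurements
length(pauli_groups(h, "gc"))            # 2 under general commutativity
fold_spectrum(h, -0.5)
#> <folded_operator: omega = -0.50000000 Ha; 15 -> 24 Pauli strings>

fit <- fsvqe(mi, reference = h2_reference_states()$S2, omega = "auto",
             backend = "sampled", hamiltonian = h, seed = 1)
summary(fit)
#> FS-VQE fit: H2 at 0.74 A [sampled/spsa]
#>   target omega: 0.46261815 Ha
#>   energy <H>:   0.48367574 Ha
#>   final cost:   -2.291e-03  (not converged after 350 iteration(s), 752 evaluation(s))
#>   parameters (rad):
#>     s(0->2)        +0.00941801
#>     d(0,1->2,3)    -0.11292133
#>     s(1->3)        +0.00363193
#>   |E - FCI|: 5.331e-04 Ha (0.3345 kcal/mol)
```

The fitted energy sits 0.33 kcal/mol from the exact (full
configuration interaction) S2 eigenvalue 0.48314267 Ha — within
chemical accuracy (1 kcal/mol) — using a 1000→10000-shot schedule
during optimization and a 30000-shot final measurement. ("Not
converged" reports that the $10^{-9}$ gradient threshold is
unreachable at finite shots; the iteration cap stopped the run.)

Under the scaled noise model at $\lambda = 0.2$ (depolarizing +
thermal relaxation + readout error at one fifth of present-hardware
magnitudes), SPAM inversion plus per-group quadratic ZNE over folding
factors 1, 3, 5, 7 recovers:

```r
np  <- scale_noise(noise_params(), 0.2)
mitigated_energy(fit, np, shots = 20000, gammas = c(1, 3, 5, 7), seed = 1)
#> <fsvqe_mitigated: E0 = 0.48112798 Ha (lambda = 0.2)>
#>   5 group(s), gammas 1,3,5,7; 400000 shots total (4x unmitigated)
```

A whole potential-energy curve with warm-started parameters:

```r
scan <- fsvqe_pes("H2", backend = "sampled", seed = 1,
                  track_omega = FALSE, omega_update = 1)
plot(scan)
```

A thin command-line wrapper with subcommands `groups`, `fci`, `run`,
`pes` and `mitigate` lives at `inst/cli/fsvqe.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/fsvqe.R", package="fsvqe"))') fci --molecule H2 --bond 0.74`).

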