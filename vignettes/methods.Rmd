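---
title: "Methods: restricted-state-space NMR simulation, spectral fitting, and conformer statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restricted-state-space NMR simulation, spectral fitting, and conformer statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorspin)
```

# The problem

1,3-difluoroalkanes such as 1,3-difluoropropane, 2,4-difluoropentane and
3,5-difluoroheptane report on how fluorine steers the conformation of an
aliphatic chain. Their vicinal ³J couplings are dihedral-dependent (Karplus
behaviour), so experimentally fitted couplings can be confronted with
computed conformer populations. Two obstacles make this hard:

* the molecules are symmetric, so their spectra are strongly second order
  (chemical-shift differences smaller than or comparable to couplings, two
  fluorines with identical shifts but different coupling partners), and
* the largest systems have 16 coupled spins-1/2, where conventional
  simulation by diagonalisation of the 2^16-dimensional Hamiltonian inside
  an iterative least-squares loop is computationally out of reach.

`fluorspin` implements the full computational stack: a restricted
Liouville-space simulator, a simultaneous two-nucleus least-squares fitting
engine, and the ensemble statistics (Boltzmann populations with uncertainty
propagation, ensemble J-averaging, %antiperiplanar scoring and the J-vs-%app
correlation) used to assign conformational profiles.

# Spin model and conventions

A `SpinSystem` holds isotopes (¹H and ¹⁹F only, both spin-1/2), chemical
shifts in ppm, the symmetric scalar-coupling matrix in Hz, the ¹H Larmor
frequency of the magnet, declared permutation-symmetry groups (e.g. methyl
rotors, S₃ each), and optional molecule-level equivalences. Rotating-frame
offsets combine as `shift_ppm × fieldMHz × γ/γ(¹H)`, with γ(¹⁹F)/γ(¹H) =
0.94094011, so mixed ¹H/¹⁹F systems live on one magnet consistently.

The high-field Hamiltonian is

$$H = \sum_i \omega_i I_z^{(i)} + 2\pi \sum_{i<j} J_{ij}\,
      \mathbf{I}^{(i)}\!\cdot\!\mathbf{I}^{(j)}
      \quad\text{(same isotope)}$$

with heteronuclear couplings truncated to the secular
$2\pi J_{ij} I_z^{(i)} I_z^{(j)}$ form. Homonuclear couplings must be kept
in full: the two fluorines share a chemical shift and are strongly coupled,
which is precisely what produces the mirror-asymmetric ¹⁹F multiplets.

# Restricted Liouville state space

Liouville space for n spins-1/2 has dimension 4ⁿ (4.3 × 10⁹ at n = 16)
versus 2ⁿ for Hilbert space, but it truncates much better. The basis is the
orthonormal product basis of single-spin irreducible spherical tensors
{E/√2, T₁₋₁, T₁₀, T₁₊₁}; a product state's *correlation order* is the
number of non-identity factors. The reduction cascade is:

1. **Correlation-order cap** (default 8): high orders of spin correlation
   remain essentially unpopulated in liquid-state pulse-acquire
   experiments. `correlationOrderTrajectory()` lets you verify this
   directly: per-order amplitudes fall by orders of magnitude, and
   truncating above the knee leaves the spectrum unchanged to better than
   one part in 10³.
2. **Connectivity screening** (optional): only states whose non-identity
   spins form a connected cluster of the J-coupling graph (|J| above a
   0.01 Hz cutoff) are generated. This is a documented approximation on
   top of the order cap — the exact screening rules used by large-scale
   simulation codes are more elaborate, and we make no attempt to
   reproduce any particular intermediate dimension; the cascade is
   reported per run by `reductionReport()`.
3. **Conservation-law filters.** The per-isotope total projection quantum
   number is conserved, so the detected isotope is restricted to its
   m = +1 coherence subspace (quadrature detection of L₊). Undetected
   spins whose only couplings into the evolving system are secular IzIz
   terms stay longitudinal exactly and are restricted to {E, T₁₀}. Mode
   `"auto"` applies the longitudinal filter only where it is exact and the
   m = 0 coherence filter otherwise; `"strict"` applies the longitudinal
   filter to all undetected spins — the aggressive screening appropriate
   for very large systems, where the discarded zero-quantum pathways are
   negligible; `"off"` uses coherence filters only.
4. **Symmetry adaptation.** Declared permutation groups (direct products
   of full symmetric groups, e.g. S₃ × S₃ with 36 elements for two methyl
   rotors) act by permuting product states. Only the fully symmetric
   irreducible representation is needed for liquid-state observables; its
   projector is the orthonormal orbit-average map, and the reduced
   dimension is the orbit count (e.g. 64 → 20 for one rotor).

All filters are set-selections, so dimensions are non-increasing along the
cascade and the stages commute.

# Liouvillian assembly and propagation

The commutation superoperator is assembled directly in the restricted
basis: for each Hamiltonian term, left- and right-multiplication factorise
into per-site 4 × 4 matrices, and matrix elements are accumulated per
basis state, with states outside the basis projected out (a Galerkin
restriction). In this basis the superoperator is real symmetric and
sparse; no 2ⁿ × 2ⁿ matrix is ever formed.

Time propagation is diagonalisation-free Krylov (Lanczos) evaluation of
`exp(-i L dt) v` with full reorthogonalisation, an adaptive subspace of up
to 30 vectors, a per-step convergence tolerance of 1e-10 (relative
breakdown detection at 1e-12), and automatic step halving if the subspace
cap is hit. One acquired point costs one Krylov exponential, i.e. a few
tens of sparse matrix-vector products.

Spectra are produced by exponential apodization (default 0.5 Hz full width
at half height, matching a well-shimmed magnet), zero filling, FFT, and a
ppm axis centred on the carrier. The phase convention is absorption = real
part with zero zeroth- and first-order phase (ideal pulse, no dead time);
apodization and phase handling for simulated traces are our choices, as
they are not uniquely dictated by any convention.

Two dense Hilbert-space routes exist besides the restricted engine:

* `denseOracleFid()` — a deliberately brute-force time-domain simulator
  (full 2ⁿ eigendecomposition, density matrix stepped explicitly), kept as
  an independent oracle for tests and refused above 12 spins;
* an internal frequency-domain line-list route that exploits the block
  structure of the Hamiltonian over per-isotope projection sectors. All
  blocks are small and real symmetric, transitions connect adjacent
  sectors of the detected isotope, and the spectrum is the exact discrete
  Fourier transform of the apodized, truncated FID (a geometric series per
  line). This is the engine inside the fitting loop; its compiled kernel
  makes one objective evaluation cost a few milliseconds for six spins.

The three routes agree to numerical precision on systems small enough to
compare; the test suite pins this down at 1e-6 relative spectral deviation
(Krylov accumulation over thousands of steps) and 1e-10 for the exactness
of filters and symmetry projection.

# Least-squares extraction of shifts and couplings

A single spectrum, proton or fluorine, does not reliably constrain a large
strongly coupled parameter set: exchanging the coupling vectors of two
fluorines leaves the ¹H spectrum exactly invariant when the fluorines
differ only through their couplings. Both spectra therefore enter one
objective:

$$\chi^2 = \sum_{s \in \{^1\mathrm{H},\,^{19}\mathrm{F}\}}
  \frac{\| a_s m_s(\theta) + b_s - o_s \|^2}{\| o_s \|^2}$$

where θ are the unique shifts and couplings after symmetry tying (the tie
map comes from `validateEquivalence()` and is user-extensible, since
molecule-level equivalence beyond the declared rotors is an assignment
choice) plus one Lorentzian linewidth. Per-spectrum scale $a_s$ and
constant baseline $b_s$ are linear nuisance parameters profiled out in
closed form at every evaluation; the per-spectrum normalisation makes ¹H
and ¹⁹F contribute comparably. Only absorption intensities enter the
objective. Observed and simulated spectra are compared on the observed
grid (linear interpolation when the grids differ).

Minimisation is adaptive Nelder-Mead (Gao-Han coefficients, as implemented
in `pracma::nelder_mead`). Two implementation details matter in practice:

* **Block-cyclic application.** Above ~14 free parameters a single simplex
  crawls; alternating simplex passes over the shift + linewidth block and
  the coupling block converges geometrically while remaining plain
  Nelder-Mead on the joint objective. Cycles stop when a full cycle moves
  shifts by less than 0.5 × 10⁻⁴ ppm and couplings by less than
  0.5 × 10⁻² Hz — i.e. convergence to at least four decimal places in the
  shifts and two in the couplings, which the steep dependence of
  second-order spectra on near-zero energy differences makes necessary.
* **Multi-resolution continuation.** The error surface of a second-order
  fitting problem has many local minima. The fit first runs against a
  4 Hz-broadened version of the data (broadening is exact for absorption
  Lorentzians: extra decay on the model FID, FFT-domain multiplication for
  the observation), which removes most local structure, then refines at
  the native linewidth.
* **Levenberg-Marquardt refinement.** The final approach to the optimum
  follows a narrow curved valley along which any simplex crawls (we
  measured stagnation around 10⁻³ Hz). Once the simplex has located the
  basin, a damped Gauss-Newton step on the full residual vector
  (`minpack.lm`, numerical Jacobian, ~30 iterations) converges to machine
  precision at a cost of a few hundred extra evaluations. Every run —
  the main fit and each stability restart — is refined this way, so
  restart agreement genuinely tests for distinct optima rather than for
  simplex stopping noise.

Stability is verified the way second-order fits should be: restarts from
parameters perturbed uniformly by ±0.2 Hz in J and ±0.005 ppm in shifts
(5 by default) must converge to the same optimum (pairwise max |ΔJ| below
0.01 Hz); disagreement flags the fit unstable. `validateByDecoupling()`
provides the orthogonal accuracy check: spectra simulated from the fitted
parameters with heteronuclear couplings zeroed (ideal adiabatic decoupling
modelled as J-zeroing) must agree with a decoupled observation.

On the seeded noiseless synthetic benchmark (20 strongly coupled mixed
¹H/¹⁹F cases of 3-6 spins, guesses perturbed by up to 0.5 Hz and 0.01 ppm,
two stability restarts) the stack recovers every coupling to well within
0.1 Hz — the precision at which fitted couplings from well-resolved
experimental spectra can be treated as exact. `jRecoveryStudy()`
reproduces this table.

# Conformer-ensemble statistics

Populations follow the Boltzmann distribution
$p_k = g_k e^{-E_k/RT} / Z$, $Z = \sum_n g_n e^{-E_n/RT}$, with explicit
integer degeneracies $g_k$ (symmetric molecules have degenerate conformer
pairs/quadruples; reporting can divide degeneracy back out when single
conformations are compared), R = 8.31446 J/(mol K) and T = 298 K by
default. Populations are invariant under a uniform energy shift; energies
are stored relative to the minimum.

For the uncertainty of computed populations, every energy is treated as
carrying the same independent standard deviation σ_E. Differentiating the
Boltzmann expression gives
$\partial p_k/\partial E_n = p_k p_n / RT$ for $n \ne k$ and
$-p_k(1 - p_k)/RT$ for $n = k$, hence the first-order propagation

$$\sigma_{p_k} = \frac{\sigma_E\,p_k}{RT}
   \sqrt{(1 - p_k)^2 + \textstyle\sum_{n \ne k} p_n^2}
   \;\le\; \sqrt{2}\,\frac{\sigma_E}{RT}\,p_k (1 - p_k),$$

the bound following from $\sum_{n\ne k} p_n^2 \le (1-p_k)^2$; it is the
more convenient form because it involves only the conformer's own
population. The default σ_E = 0.42 kJ/mol reflects cross-method comparison
of computed conformer energy differences for solvated 1,3-difluoroalkanes;
a worst-case estimate from noncovalent-interaction benchmarks is
1.1 kJ/mol. The implementation is verified against a 10⁵-sample
Monte-Carlo perturbation oracle: at σ_E = 0.42 kJ/mol the analytic result
agrees within 5%. At the 1.1 kJ/mol worst case the sigmoid saturation of
the Boltzmann map makes any first-order propagation overestimate σ_p for
near-degenerate pairs by up to ~10%, so the 5% agreement claim is made —
and tested — at 0.42 kJ/mol only.

Ensemble-averaged couplings use the same weights,
$\langle J\rangle = \sum_n g_n J_n e^{-E_n/RT} / Z$, which over a
uniform-random instance set is the unbiased Monte-Carlo estimator of the
thermal integral over dihedral space; `continuousAverageJ()` provides the
systematic grid-scan integration used to check Monte-Carlo convergence.

Conformer bookkeeping: `enumerateStaggered()` generates all 3ⁿ staggered
label strings over {a, g, g⁻} (a = 180° ± 60°, g = +60° ± 60°,
g⁻ = −60° ± 60°; the capital-letter CC–CC versus lowercase CC–CF
distinction travels as part of the label text). For four-dihedral chains
`condenseGrid()` sums the 9 × 9 population grid into the 3 × 3 marginal of
the inner (central CC–CC) or outer dihedral pair. `percentAntiperiplanar()`
sums the populations of the conformers in which a given atom pair is
antiperiplanar — classified as a dihedral within ±30° of 180°, since
computed minima deviate from perfect staggering but stay within their
wells — and `correlateJApp()` fits the ordinary least-squares line through
(%app, ³J) pairs. A strong linear correlation is expected exactly when
both the conformational energy and the Karplus curve are flat near 180°.

# The synthetic-fixture generator

Because electronic-structure energies and real spectrometer data are out
of scope, all test inputs are generated:

* **Rotamer ensembles** (`rotamerModel`, `buildTruthEnsemble`): staggered
  wells at 180°/±60° with harmonic widths (15 kJ/mol/rad², giving
  realistic well widths of ~15°), per-well energies of a few kJ/mol,
  per-conformer couplings from three-term Karplus curves. The default
  coefficient sets (H–H: 9.5/−1.4/1.6 Hz; H–F: 31/−6/3 Hz) are
  configuration, not assertions about any particular parametrisation —
  they reproduce the field's qualitative ordering, amplitudes of ~10 Hz
  (H,H) versus ~35 Hz (H,F) antiperiplanar.
* **Clash-screened dihedral sampling** (`sampleDihedrals`): uniform
  dihedrals on an idealised tetrahedral carbon chain (1.53 Å bonds,
  109.47° angles), rejecting geometries with nonbonded (1,5 and beyond)
  carbon-carbon contacts under 3.0 Å. Real screening acts on full 3-D
  structures; this chain-only rule plays the same statistical role
  (syn-pentane-type rejections) without claiming the same survival rate.
* **Synthetic spin systems** (`makeSyntheticCase`): seeded mixed ¹H/¹⁹F
  systems in the second-order regime — within-isotope shift gaps of 4-22 Hz
  against couplings of 2-14 Hz (H,H), 5-45 Hz (H,F) and 4-14 Hz (F,F) — or
  a weak-coupling control with 300-600 Hz gaps. Spectra are simulated
  noiselessly (optionally with white noise at a stated signal-to-noise
  ratio) on 1024-point grids zero-filled to 2048, spanning each multiplet
  plus a 60 Hz margin at 0.7 Hz linewidth.

What the generator does *not* emulate: baseline roll, phase errors,
temperature drift, solvent signals, relaxation-induced lineshape
differences, or coupling networks with near-degenerate alternative
assignments. Passing the recovery benchmark therefore demonstrates the
correctness and precision of the simulation + minimisation stack on ideal
data, not robustness to instrumental artefacts.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
problem sizes — 3-6-spin fitting cases on 1024-point grids, 256-384-point
acquisitions for oracle comparisons, an 8-spin chain for the
correlation-order decay demonstration, 10⁵ Monte-Carlo samples for the
uncertainty oracle — chosen so the full stack (not a stub of it) runs in
minutes on one CPU. The experimental acquisition defaults (131072 points
zero-filled to 262144 over 14 ppm for ¹H; 262144 to 524288 over 50 ppm for
¹⁹F, at 500/470.5 MHz) are retained as `acquisitionParams()` defaults for
production use.

Other numerical choices: basis states are ordered by correlation order
then lexicographic label (deterministic sparse patterns); degenerate
denominators in the closed-form discrete Fourier transform fall back to
the series limit; line lists drop transitions below 10⁻¹² of the strongest
amplitude; the linewidth parameter is kept positive by absolute value
rather than a hard bound.

# Known limitations

* No relaxation (T₁/T₂), chemical exchange, quadrupolar nuclei, shaped
  pulses, or 2-D experiments; decoupling is ideal J-zeroing.
* The connectivity screening is a heuristic accelerator: with it enabled,
  symmetry projection may legitimately refuse a basis that is not closed
  under the declared group.
* The longitudinal filter in `"strict"` mode is an approximation whenever
  undetected like spins couple to each other; `"auto"` mode is exact but
  keeps a larger basis.
* First-order uncertainty propagation degrades for σ_E approaching RT, as
  quantified above.
* Nelder-Mead with continuation is robust for guesses within ~0.5 Hz of
  the truth (the accuracy expected of ensemble-averaged computed
  couplings); grossly wrong guesses can still converge to a local minimum,
  which the restart-stability flag is designed to expose.
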