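# fluorspin

Quantum-mechanical simulation and least-squares fitting of strongly
coupled ¹H/¹⁹F NMR spectra, with the conformer-ensemble statistics used to
assign conformational profiles of 1,3-difluoroalkanes.

## Who this is for

NMR spectroscopists and computational chemists who need to

* simulate 1-D pulse-acquire spectra of large spin-1/2 systems (up to the
  16 coupled spins of a 3,5-difluoroheptane) without diagonalising a
  2ⁿ-dimensional Hamiltonian,
* extract chemical shifts and scalar couplings from *second-order*
  spectra — the regime where shift differences are comparable to J and
  multiplets must be fitted, not read off, and
* confront fitted ³J couplings with computed conformer populations
  (Boltzmann weights, uncertainty propagation, %antiperiplanar scoring).

## The methods at the core

**Restricted Liouville state space.** The density-operator space of n
spins-1/2 has dimension 4ⁿ, but pulse-acquire experiments populate only a
thin slice of it. The simulator works in the orthonormal basis of
irreducible spherical-tensor product operators and applies a reduction
cascade: a correlation-order cap (default 8), optional coupling-graph
connectivity screening, exact conservation-law filters (detected isotope
in its m = +1 coherence subspace; undetected spins longitudinal where that
is exact), and projection onto the fully symmetric irreducible
representation of declared permutation groups (two methyl rotors form
S₃ × S₃ with 36 elements). The Liouvillian

H = Σᵢ ωᵢ Iz⁽ⁱ⁾ + 2π Σᵢ<ⱼ J'ᵢⱼ (full **Iᵢ·Iⱼ** within an isotope, IzIz across isotopes)

is assembled directly in the restricted basis as a sparse real symmetric
commutation superoperator, and the experiment is propagated by Krylov
(Lanczos) evaluation of exp(−iLt)v — one matrix-vector sequence per
acquired point, never a matrix factorisation.

**Simultaneous two-nucleus fitting.** A single spectrum does not constrain
a large strongly coupled parameter set; the ¹H and ¹⁹F spectra enter one
normalised least-squares objective with per-spectrum scale and baseline
profiled out. Minimisation is adaptive Nelder-Mead, applied block-cyclically
in high dimension, with multi-resolution continuation (fit a 4 Hz-broadened
surface first), a Levenberg-Marquardt refinement of the located optimum,
and stability restarts from perturbed parameters. On seeded noiseless
synthetic benchmarks every coupling is recovered to well within ±0.1 Hz.

**Conformer statistics.** Boltzmann populations p_k = g_k e^(−E_k/RT)/Z
with first-order uncertainty propagation
σ_pk = (σ_E p_k/RT)·sqrt((1−p_k)² + Σ_{n≠k} p_n²) and the convenient bound
σ_pk ≤ √2(σ_E/RT)p_k(1−p_k); degeneracy-aware ensemble J-averaging;
staggered-rotamer enumeration (3ⁿ conformers); 9 × 9 → 3 × 3 dihedral-grid
condensation; %antiperiplanar scoring and the ordinary least-squares
correlation of ³J against %app.

## A worked example

Simulate the ¹H spectrum of a two-spin H–F pair, fit a perturbed guess
back to a synthetic strongly coupled 4-spin system, and average a Karplus
coupling over a rotamer ensemble:

```r
library(fluorspin)

## spin system: H-F pair, 2J(H,F) = 48 Hz
hf <- spinSystem(c("1H", "19F"), c(4.5, -180), 48)
pars <- acquisitionParams("1H", points = 2048, zerofill = 4096,
                          sweepPpm = 0.5, centerPpm = 4.5)
sp <- simulateSpectrum(hf, pars)
attr(sp, "basis")
#>                               stage dimension
#>                full Liouville space        16
#>              correlation order <= 2        16
#>       coherence m = +1 on spins {1}         4
#>  longitudinal filter on spins {2}           2

## parameter recovery on a seeded synthetic 4-spin case
case  <- makeSyntheticCase(4, "strong", seed = 24)
guess <- perturbParameters(case$truth, maxJ = 0.5, maxShift = 0.01, seed = 2)
fit   <- fitSpectra(guess, unname(case$spectra), case$system,
                    restarts = 2, seed = 3)
max(abs(fit@params@j - case$truth@j))
#> [1] 4.263256e-14        # Hz: all couplings recovered far inside 0.1 Hz

## ensemble-averaged coupling of a two-rotor model
model <- rotamerModel(2, wellEnergies = c(0, 2.5, 2.5))
ens   <- buildTruthEnsemble(model,
           curves = list(HH = karplusCurve(9.5, -1.4, 1.6)), pairs = 1L)
ensembleAverageJ(ens, temperature = 298, pair = "HH")
#> [1] 8.609931            # Hz, between the gauche and anti limits

pu <- populationUncertainty(conformerEnsemble(c("aa", "ag", "ga"),
                                              c(0, 0.9, 1.8)),
                            temperature = 298, sigmaE = 0.42)
round(rbind(p = pu@p, sigma = pu@sigmaP), 3)
#>        [,1]  [,2]  [,3]
#> p     0.459 0.319 0.222
#> sigma 0.052 0.046 0.036
```

The numbers above are what the shipped code prints (seeds included).

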