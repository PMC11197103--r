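# Independent oracles and shared fixtures for the test suite. Everything
# here is deliberately written by brute force, independent of the package
# code paths it checks.

# enumeration oracle: all 4^n label tuples as an integer matrix
enumAllLabels <- function(n) {
  as.matrix(expand.grid(rep(list(0:3), n), KEEP.OUT.ATTRS = FALSE))
}

labelM <- c(0L, -1L, 0L, 1L)

# brute-force count of states with correlation order <= k
countByOrder <- function(n, k) {
  sum(vapply(0:k, function(q) choose(n, q) * 3^q, numeric(1)))
}

# dense 2x2 single-spin matrices
E2 <- diag(2) + 0i
Iz2 <- matrix(c(0.5, 0, 0, -0.5), 2, 2) + 0i
Ip2 <- matrix(c(0, 0, 1, 0), 2, 2) + 0i
Im2 <- matrix(c(0, 1, 0, 0), 2, 2) + 0i
Ix2 <- (Ip2 + Im2) / 2
Iy2 <- (Ip2 - Im2) / (2i)

# dense operator for spin i of n
denseOp <- function(n, i, o) {
  m <- 1 + 0i
  for (s in seq_len(n)) m <- kronecker(if (s == i) o else E2, m)
  m
}

# dense high-field Hamiltonian oracle (rad/s), offsets in Hz
denseHOracle <- function(offsets, J, iso) {
  n <- length(offsets)
  H <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n)) H <- H + 2 * pi * offsets[i] * denseOp(n, i, Iz2)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (J[a, b] == 0) next
    t <- denseOp(n, a, Iz2) %*% denseOp(n, b, Iz2)
    if (iso[a] == iso[b])
      t <- t + denseOp(n, a, Ix2) %*% denseOp(n, b, Ix2) +
        denseOp(n, a, Iy2) %*% denseOp(n, b, Iy2)
    H <- H + 2 * pi * J[a, b] * t
  }
  H
}

# normalised tensor basis matrices for labels 0:3
tensor2 <- list(E2 / sqrt(2), Im2, sqrt(2) * Iz2, Ip2)

# dense matrix of one product basis state (row of labels)
denseBasisState <- function(labels) {
  m <- 1 + 0i
  for (s in seq_along(labels)) m <- kronecker(tensor2[[labels[s] + 1]], m)
  m
}

relSpecDev <- function(a, b) max(abs(a - b)) / max(abs(b))

# convenience alias for the package's internal default Karplus sets
.defaultKarplus <- fluorspin:::.defaultKarplus

# Monte-Carlo oracle for population uncertainty: perturb each conformer
# energy independently, recompute populations, take elementwise sd
mcSigmaP <- function(energies, degeneracy, temperature, sigmaE, nSamples,
                     seed) {
  set.seed(seed)
  rt <- 8.314462618e-3 * temperature
  k <- length(energies)
  sims <- matrix(0, nSamples, k)
  for (s in seq_len(nSamples)) {
    e <- energies + rnorm(k, 0, sigmaE)
    w <- degeneracy * exp(-e / rt)
    sims[s, ] <- w / sum(w)
  }
  apply(sims, 2, sd)
}

# deterministic small strongly coupled mixed test system
mixedSystem5 <- function() {
  J <- matrix(0, 5, 5)
  setJ <- function(i, j, v) J[cbind(c(i, j), c(j, i))] <<- v
  setJ(1, 2, 11.5); setJ(1, 3, 6.2); setJ(2, 3, 13.0)
  setJ(1, 4, 24.0); setJ(2, 4, 9.0); setJ(3, 4, 46.5)
  setJ(1, 5, 8.0); setJ(2, 5, 19.5); setJ(3, 5, 12.0)
  spinSystem(c("1H", "1H", "1H", "19F", "19F"),
             c(1.995, 2.013, 2.040, -179.99, -180.01), J)
}

# 8-spin fixture (7 1H + 1 19F) with the coupling topology of a
# CH3-CH2-CH2-CHF fragment: realistic shift spreads, so strong coupling is
# local (geminal pairs, the CHF proton via its fluorine) while remote
# pairs are weakly coupled -- the regime in which high correlation orders
# stay unpopulated
chainSystem8 <- function() {
  J <- matrix(0, 8, 8)
  setJ <- function(i, j, v) J[cbind(c(i, j), c(j, i))] <<- v
  # spins: 1-3 CH3, 4-5 CH2 (diastereotopic), 6-7 CH2, 8... wait
  setJ(1, 2, 12.0); setJ(1, 3, 12.0); setJ(2, 3, 12.0)   # CH3 internal
  for (i in 1:3) { setJ(i, 4, 7.4); setJ(i, 5, 7.4) }    # CH3-CH2
  setJ(4, 5, -13.9)                                      # geminal
  setJ(4, 6, 3.4); setJ(5, 6, 8.8)                       # CH2-CHF
  setJ(6, 7, 9.1)                                        # CHF-CH(F side)
  setJ(6, 8, 48.6)                                       # 2J(H,F)
  setJ(4, 8, 18.0); setJ(5, 8, 27.5)                     # 3J(H,F)
  setJ(7, 8, 21.0)                                       # 3J(H,F)
  shifts <- c(0.96, 0.96, 0.96, 1.62, 1.70, 4.55, 1.86, -184.5)
  spinSystem(c(rep("1H", 7), "19F"), shifts, J)
}

# shared heavy computation: the seeded recovery study, run once per suite
recoveryStudyCached <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- jRecoveryStudy(nCases = 20, seed = 1, restarts = 2)
    cache
  }
})
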