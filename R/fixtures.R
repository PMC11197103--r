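# Synthetic test-input generators: Karplus-governed rotamer ensembles,
# clash-screened Monte-Carlo dihedral sampling on an idealised tetrahedral
# chain, and seeded strongly coupled 1H/19F spin systems with known ground
# truth. Everything is deterministic under a given seed.

#' Karplus curve
#'
#' Three-term Karplus relation J(theta) = A cos^2(theta) + B cos(theta) + C
#' connecting a vicinal coupling to its dihedral angle.
#'
#' @param A,B,C coefficients in Hz.
#' @return object of class \code{KarplusCurve}.
#' @export
karplusCurve <- function(A, B, C) {
  stopifnot(is.finite(A), is.finite(B), is.finite(C))
  structure(list(A = A, B = B, C = C), class = "KarplusCurve")
}

#' Evaluate a Karplus curve
#'
#' @param curve a \code{\link{karplusCurve}}.
#' @param theta dihedral angle(s) in degrees.
#' @return coupling(s) in Hz.
#' @export
karplusJ <- function(curve, theta) {
  ct <- cos(theta * pi / 180)
  curve$A * ct^2 + curve$B * ct + curve$C
}

# Default coefficient sets. The H-F family has a much larger amplitude
# than H-H, reflecting the large antiperiplanar 3J(H,F) of fluoroalkanes.
.defaultKarplus <- list(
  HH = karplusCurve(9.5, -1.4, 1.6),
  HF = karplusCurve(31.0, -6.0, 3.0)
)

#' Rotamer model for a saturated chain
#'
#' Staggered wells at 180 / +60 / -60 degrees with harmonic restoring
#' force, per-well relative energies, and a steric clash rule on an
#' idealised tetrahedral carbon chain (fixed bond length and angle).
#'
#' @param nDihedrals number of rotatable bonds.
#' @param wellEnergies numeric matrix (nDihedrals x 3) of well energies in
#'   kJ/mol for wells (a, g, g-); a vector is recycled across dihedrals.
#' @param force harmonic force constant in kJ/mol/rad^2.
#' @param bondLength C-C bond length in Angstrom.
#' @param clashMin minimum allowed nonbonded (1,5+) carbon-carbon distance
#'   in Angstrom; NA disables clash screening.
#' @return object of class \code{RotamerModel}.
#' @export
rotamerModel <- function(nDihedrals, wellEnergies = c(0, 2.5, 2.5),
                         force = 15, bondLength = 1.53, clashMin = 3.0) {
  if (is.matrix(wellEnergies)) {
    stopifnot(nrow(wellEnergies) == nDihedrals, ncol(wellEnergies) == 3)
  } else {
    wellEnergies <- matrix(wellEnergies, nDihedrals, 3, byrow = TRUE)
  }
  stopifnot(force > 0)
  structure(list(nDihedrals = nDihedrals, wells = c(180, 60, -60),
                 wellEnergies = wellEnergies, force = force,
                 bondLength = bondLength, clashMin = clashMin),
            class = "RotamerModel")
}

# Smooth periodic torsional energy: the lower envelope of the three
# harmonic wells (angle differences wrapped to [-180, 180)).
.dihedralEnergy <- function(model, d, theta) {
  dev <- outer(theta, model$wells, "-")
  dev <- (dev + 180) %% 360 - 180
  e <- sweep(0.5 * model$force * (dev * pi / 180)^2, 2,
             model$wellEnergies[d, ], "+")
  apply(e, 1, min)
}

.chainEnergy <- function(model, theta) {
  # theta: matrix samples x dihedrals
  rowSums(vapply(seq_len(model$nDihedrals), function(d)
    .dihedralEnergy(model, d, theta[, d]), numeric(nrow(theta))))
}

# Idealised chain coordinates from dihedrals (tetrahedral angles, fixed
# bond length): atoms 1..(d+3).
.chainCoords <- function(theta, bondLength) {
  d <- length(theta)
  n <- d + 3
  ang <- 109.47 * pi / 180
  xyz <- matrix(0, n, 3)
  xyz[2, ] <- c(bondLength, 0, 0)
  xyz[3, ] <- xyz[2, ] + bondLength * c(-cos(ang), sin(ang), 0)
  for (k in 4:n) {
    th <- theta[k - 3] * pi / 180
    b1 <- xyz[k - 1, ] - xyz[k - 2, ]
    b0 <- xyz[k - 2, ] - xyz[k - 3, ]
    e1 <- b1 / sqrt(sum(b1^2))
    nrm <- pracma::cross(b0, b1)
    nrm <- nrm / sqrt(sum(nrm^2))
    m <- cbind(e1, pracma::cross(nrm, e1), nrm)
    d2 <- bondLength * c(-cos(ang), sin(ang) * cos(th), sin(ang) * sin(th))
    xyz[k, ] <- xyz[k - 1, ] + as.vector(m %*% d2)
  }
  xyz
}

.hasClash <- function(xyz, clashMin) {
  n <- nrow(xyz)
  for (i in seq_len(n - 4)) for (j in (i + 4):n)
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < clashMin) return(TRUE)
  FALSE
}

#' Monte-Carlo dihedral sampling with clash screening
#'
#' Draws uniform random dihedral sets, builds idealised chain geometries
#' and screens them for steric clashes (nonbonded atoms closer than the
#' model's minimum distance). Reproducible under the given seed.
#'
#' @param model a \code{\link{rotamerModel}}.
#' @param nSamples number of dihedral sets to draw.
#' @param seed integer seed.
#' @return list with \code{theta} (samples x dihedrals, degrees),
#'   \code{survived} (logical mask), \code{energies} (kJ/mol, torsional)
#'   and \code{survival} (fraction passing the screen).
#' @export
sampleDihedrals <- function(model, nSamples, seed) {
  if (nSamples < 1) stop("nSamples must be >= 1")
  set.seed(as.integer(seed))
  theta <- matrix(stats::runif(nSamples * model$nDihedrals, -180, 180),
                  nSamples, model$nDihedrals)
  survived <- if (is.na(model$clashMin)) rep(TRUE, nSamples) else
    !vapply(seq_len(nSamples), function(i)
      .hasClash(.chainCoords(theta[i, ], model$bondLength), model$clashMin),
      logical(1))
  list(theta = theta, survived = survived,
       energies = .chainEnergy(model, theta),
       survival = mean(survived))
}

#' Build a ground-truth rotamer ensemble
#'
#' Enumerates all staggered conformers of the model, assigns energies from
#' the well depths and per-conformer couplings from Karplus curves
#' evaluated at the well centres, and records the Boltzmann-averaged
#' ground-truth couplings for recovery tests.
#'
#' @param model a \code{\link{rotamerModel}}.
#' @param curves named list of \code{\link{karplusCurve}} objects; each
#'   name becomes a J-table column. Each curve is attached to a dihedral
#'   via \code{pairs}.
#' @param pairs integer vector (same length as \code{curves}): which
#'   dihedral each coupling reports on.
#' @param temperature temperature in K for the recorded averages.
#' @return a \linkS4class{ConformerEnsemble}; attribute
#'   \code{"truthAverages"} holds the ground-truth ensemble-averaged J's.
#' @export
buildTruthEnsemble <- function(model, curves = .defaultKarplus["HH"],
                               pairs = 1L, temperature = 298) {
  stopifnot(length(curves) == length(pairs))
  ens <- enumerateStaggered(model$nDihedrals)
  tok <- lapply(ens@labels, .tokenizeLabel)
  wellIdx <- vapply(tok, function(t)
    match(tolower(t), c("a", "g", "g-")), integer(model$nDihedrals))
  wellIdx <- matrix(wellIdx, nrow = model$nDihedrals)
  energies <- vapply(seq_along(ens@labels), function(i)
    sum(model$wellEnergies[cbind(seq_len(model$nDihedrals), wellIdx[, i])]),
    numeric(1))
  jTable <- vapply(seq_along(curves), function(k)
    karplusJ(curves[[k]], model$wells[wellIdx[pairs[k], ]]),
    numeric(length(ens@labels)))
  colnames(jTable) <- names(curves)
  out <- conformerEnsemble(ens@labels, energies, jTable = jTable)
  attr(out, "truthAverages") <- vapply(names(curves), function(nm)
    ensembleAverageJ(out, temperature, nm), numeric(1))
  out
}

#' Thermal average of a Karplus coupling over one dihedral
#'
#' Computes <J> = integral J(theta) exp(-E(theta)/RT) dtheta / Z for a
#' single dihedral of the rotamer model, either by systematic grid
#' integration or by the uniform Monte-Carlo estimator
#' sum J_n exp(-E_n/RT) / sum exp(-E_n/RT). The grid scan serves as the
#' accuracy and convergence check of the Monte-Carlo procedure.
#'
#' @param model a \code{\link{rotamerModel}}.
#' @param curve a \code{\link{karplusCurve}}.
#' @param dihedral which dihedral (default 1).
#' @param temperature temperature in K.
#' @param method "grid" or "mc".
#' @param n grid points or Monte-Carlo samples.
#' @param seed seed for the Monte-Carlo method.
#' @return for "grid": the average (Hz); for "mc": list with \code{mean}
#'   and its standard error \code{se}.
#' @export
continuousAverageJ <- function(model, curve, dihedral = 1,
                               temperature = 298,
                               method = c("grid", "mc"), n = 10000,
                               seed = 1) {
  method <- match.arg(method)
  rt <- .RGAS * temperature
  if (method == "grid") {
    theta <- seq(-180, 180, length.out = n + 1)[-(n + 1)]
    w <- exp(-.dihedralEnergy(model, dihedral, theta) / rt)
    return(sum(w * karplusJ(curve, theta)) / sum(w))
  }
  set.seed(as.integer(seed))
  theta <- stats::runif(n, -180, 180)
  w <- exp(-.dihedralEnergy(model, dihedral, theta) / rt)
  jv <- karplusJ(curve, theta)
  mu <- sum(w * jv) / sum(w)
  # delta-method standard error of the ratio estimator
  se <- stats::sd(w * (jv - mu)) / (mean(w) * sqrt(n))
  list(mean = mu, se = se)
}

# ---- synthetic spin systems for fitting tests ------------------------------

#' Generate a synthetic strongly coupled test case
#'
#' Builds a seeded mixed 1H/19F spin system in the second-order regime
#' (chemical-shift differences comparable to the couplings), simulates its
#' noiseless 1H and 19F spectra exactly, and returns them together with
#' the generating truth. Optionally adds white noise at a stated
#' signal-to-noise ratio.
#'
#' @param nSpins total number of spins (2 to 12); systems with five or
#'   more spins carry two 19F nuclei, smaller ones a single 19F.
#' @param regime "strong" (second-order, shift differences of a few Hz to
#'   a few tens of Hz) or "weak" (first-order control).
#' @param seed integer seed; identical seeds give identical cases.
#' @param snr signal-to-noise ratio of the noisy spectra (peak signal over
#'   noise standard deviation); Inf for noiseless only.
#' @param points acquired points per spectrum (zero-filled to twice that).
#' @return list with \code{system}, \code{spectra} (noiseless, one per
#'   detected isotope), \code{noisy} (NULL when snr = Inf), \code{truth}
#'   (\linkS4class{FitParameters}) and \code{seed}.
#' @export
makeSyntheticCase <- function(nSpins, regime = c("strong", "weak"), seed,
                              snr = Inf, points = 1024L) {
  regime <- match.arg(regime)
  stopifnot(nSpins >= 2, nSpins <= 12)
  set.seed(as.integer(seed))
  nF <- if (nSpins >= 5) 2L else 1L
  nH <- nSpins - nF
  iso <- c(rep("1H", nH), rep("19F", nF))
  field <- 500
  gapH <- if (regime == "strong") stats::runif(nH - 1, 4, 22) else
    stats::runif(nH - 1, 300, 600)
  offH <- c(0, cumsum(gapH))
  offH <- offH - mean(offH)
  gapF <- if (nF == 2) {
    if (regime == "strong") stats::runif(1, 2, 10) else stats::runif(1, 300, 600)
  } else numeric(0)
  offF <- if (nF == 2) c(-gapF / 2, gapF / 2) else 0
  shifts <- c(1.8 + offH / (field * .gammaRatio("1H")),
              -180 + offF / (field * .gammaRatio("19F")))
  J <- matrix(0, nSpins, nSpins)
  for (a in seq_len(nSpins - 1)) for (b in (a + 1):nSpins) {
    J[a, b] <- J[b, a] <-
      if (iso[a] == "1H" && iso[b] == "1H") stats::runif(1, 2, 14)
      else if (iso[a] == "19F" && iso[b] == "19F") stats::runif(1, 4, 14)
      else stats::runif(1, 5, 45)
  }
  system <- spinSystem(iso, shifts, J, fieldMHz = field)

  lw <- 0.7
  spectra <- list()
  noisy <- if (is.finite(snr)) list() else NULL
  for (det in unique(iso)) {
    carrier <- mean(shifts[iso == det])
    obs <- field * .gammaRatio(det)
    lines <- .lineList(system, det, stats::setNames(
      lapply(unique(iso), function(z) mean(shifts[iso == z])), unique(iso)))
    span <- 2 * max(abs(lines$freqHz)) + 60
    pars <- acquisitionParams(det, points = points, zerofill = 2L * points,
                              sweepPpm = span / obs, centerPpm = carrier,
                              lineBroadening = lw)
    sp <- .spectrumFromLines(lines, pars)
    spectra[[det]] <- sp
    if (is.finite(snr)) {
      noisySp <- sp
      noisySp@intensity <- sp@intensity +
        stats::rnorm(length(sp@intensity), 0, max(sp@intensity) / snr)
      noisy[[det]] <- noisySp
    }
  }
  truth <- fitParameters(system, linewidth = lw,
                         tieMap = validateEquivalence(system))
  list(system = system, spectra = spectra, noisy = noisy, truth = truth,
       seed = seed)
}

#' Perturb fit parameters for an initial guess
#'
#' Adds independent uniform perturbations to every unique coupling and
#' shift, emulating the accuracy of an initial guess obtained from
#' ensemble-averaged calculations.
#'
#' @param params a \linkS4class{FitParameters} set (the truth).
#' @param maxJ half-width of the uniform J perturbation in Hz.
#' @param maxShift half-width of the uniform shift perturbation in ppm.
#' @param seed integer seed.
#' @return perturbed \linkS4class{FitParameters}.
#' @export
perturbParameters <- function(params, maxJ = 0.5, maxShift = 0.01, seed) {
  set.seed(as.integer(seed))
  vec <- .packFit(params)
  ns <- length(params@shiftClasses)
  nj <- length(params@jClasses)
  vec[seq_len(ns)] <- vec[seq_len(ns)] + stats::runif(ns, -maxShift, maxShift)
  vec[ns + seq_len(nj)] <- vec[ns + seq_len(nj)] +
    stats::runif(nj, -maxJ, maxJ)
  .unpackFit(params, vec)
}

#' Shipped example spin systems
#'
#' Deterministic template systems used in examples and tests: a two-spin
#' H-F pair, 1,3-difluoropropane (8 spins) and 3,5-difluoroheptane
#' (16 spins: 14 1H + 2 19F with two methyl S3 rotors and the molecular
#' C2 equivalences).
#'
#' @param name "HF", "difluoropropane" or "difluoroheptane".
#' @return a \linkS4class{SpinSystem}.
#' @export
exampleSystem <- function(name = c("HF", "difluoropropane",
                                   "difluoroheptane")) {
  name <- match.arg(name)
  if (name == "HF")
    return(spinSystem(c("1H", "19F"), c(4.5, -180), 48))
  if (name == "difluoropropane") {
    # FCH2-CH2-CH2F: spins H1 H2 (C1), H3 H4 (C2), H5 H6 (C3), F7 F8
    iso <- c(rep("1H", 6), rep("19F", 2))
    shifts <- c(4.52, 4.52, 1.95, 1.95, 4.52, 4.52, -221, -221)
    J <- matrix(0, 8, 8)
    setJ <- function(i, j, v) J[cbind(c(i, j), c(j, i))] <<- v
    setJ(1, 2, -10.1); setJ(5, 6, -10.1); setJ(3, 4, -14.5)
    for (i in 1:2) for (j in 3:4) setJ(i, j, 5.9)
    for (i in 5:6) for (j in 3:4) setJ(i, j, 5.9)
    setJ(1, 7, 47.2); setJ(2, 7, 47.2); setJ(5, 8, 47.2); setJ(6, 8, 47.2)
    setJ(3, 7, 23.5); setJ(4, 7, 23.5); setJ(3, 8, 23.5); setJ(4, 8, 23.5)
    setJ(7, 8, 2.8)
    return(spinSystem(iso, shifts, J,
                      equivalences = list(c(1, 2, 5, 6), c(3, 4), c(7, 8))))
  }
  # 3,5-difluoroheptane: CH3 CH2 CHF CH2 CHF CH2 CH3
  # spins: 1-3 CH3(C1), 4-5 CH2(C2), 6 CHF-H(C3), 7-8 CH2(C4), 9 CHF-H(C5),
  #        10-11 CH2(C6), 12-14 CH3(C7), 15 F(C3), 16 F(C5)
  iso <- c(rep("1H", 14), rep("19F", 2))
  shifts <- c(rep(0.96, 3), 1.62, 1.70, 4.55, 1.78, 1.86, 4.55, 1.62, 1.70,
              rep(0.96, 3), -184.5, -184.5)
  J <- matrix(0, 16, 16)
  setJ <- function(i, j, v) J[cbind(c(i, j), c(j, i))] <<- v
  for (i in 1:2) for (j in (i + 1):3) setJ(i, j, 12.0)      # rotor 1
  for (i in 12:13) for (j in (i + 1):14) setJ(i, j, 12.0)   # rotor 2
  for (i in 1:3) { setJ(i, 4, 7.4); setJ(i, 5, 7.4) }       # CH3-CH2
  for (i in 12:14) { setJ(i, 10, 7.4); setJ(i, 11, 7.4) }
  setJ(4, 5, -13.9); setJ(10, 11, -13.9); setJ(7, 8, -14.8) # geminal
  setJ(4, 6, 3.4); setJ(5, 6, 8.8)                          # CH2-CHF
  setJ(10, 9, 3.4); setJ(11, 9, 8.8)
  setJ(6, 7, 9.1); setJ(6, 8, 2.9); setJ(9, 8, 9.1); setJ(9, 7, 2.9)
  setJ(6, 15, 48.6); setJ(9, 16, 48.6)                      # 2J HF
  setJ(4, 15, 18.0); setJ(5, 15, 27.5)                      # 3J HF
  setJ(10, 16, 18.0); setJ(11, 16, 27.5)
  setJ(7, 15, 21.0); setJ(8, 15, 12.5)
  setJ(8, 16, 21.0); setJ(7, 16, 12.5)
  setJ(6, 16, 2.0); setJ(9, 15, 2.0)                        # 4J HF
  setJ(15, 16, 3.1)                                         # 4J FF
  spinSystem(iso, shifts, J,
             symmetryGroups = list(list(spins = 1:3, label = "S3"),
                                   list(spins = 12:14, label = "S3")),
             equivalences = list(c(1, 2, 3, 12, 13, 14), c(4, 11), c(5, 10),
                                 c(6, 9), c(15, 16), c(7, 8)))
}

#' Write the complete fixture set
#'
#' Emits example spin-system files, a synthetic strongly coupled test case
#' (system, noiseless spectra, truth parameters), a rotamer conformer
#' table, and a manifest, all as plain text.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed controlling all randomness.
#' @return invisibly, the manifest as a list.
#' @export
makeFixtures <- function(outDir, seed = 1) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outDir, ...)
  for (nm in c("HF", "difluoropropane", "difluoroheptane"))
    writeSpinSystem(exampleSystem(nm), p(paste0(nm, ".yaml")))
  case <- makeSyntheticCase(4, "strong", seed = seed, points = 1024L)
  writeSpinSystem(case$system, p("synthetic-case.yaml"))
  for (det in names(case$spectra))
    writeSpectrumText(case$spectra[[det]],
                      p(sprintf("synthetic-%s.tsv", sub("^\\d+", "", det))))
  model <- rotamerModel(2, wellEnergies = c(0, 2.5, 2.5))
  ens <- buildTruthEnsemble(model, .defaultKarplus, pairs = c(1L, 2L))
  writeConformerTable(ens, p("rotamer-table.tsv"))
  manifest <- list(seed = seed,
                   files = list.files(outDir),
                   truth_j = case$truth@j[upper.tri(case$truth@j)],
                   truth_shifts = case$truth@shifts)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(manifest)
}
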