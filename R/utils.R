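# Internal numerical helpers: isotope registry, single-spin operator algebra
# in the normalised spherical-tensor basis, key encoding for product states,
# and small generic utilities.

# Spin-1/2 only; gamma given as the IUPAC frequency ratio relative to 1H.
.isotopeRegistry <- list(
  "1H"  = list(spin = 0.5, gamma = 1.0),
  "19F" = list(spin = 0.5, gamma = 0.94094011)
)

.knownIsotopes <- function() names(.isotopeRegistry)

.gammaRatio <- function(isotope) {
  entry <- .isotopeRegistry[[isotope]]
  if (is.null(entry)) stop("unsupported isotope: ", isotope)
  entry$gamma
}

# Per-spin m quantum number of each operator label 0:3 (E, I-, Iz, I+).
.labelM <- c(0L, -1L, 0L, 1L)

# 2x2 single-spin operators.
.op2 <- local({
  E  <- diag(2) + 0i
  Iz <- matrix(c(0.5, 0, 0, -0.5), 2, 2) + 0i
  Ip <- matrix(c(0, 0, 1, 0), 2, 2) + 0i   # column-major: Ip[1,2] = 1
  Im <- matrix(c(0, 1, 0, 0), 2, 2) + 0i
  list(E = E, Iz = Iz, Ip = Ip, Im = Im)
})

# Orthonormal single-spin Liouville basis, indexed 1:4 for labels 0:3.
.tensorBasis <- list(
  .op2$E / sqrt(2),       # label 0
  .op2$Im,                # label 1, T(1,-1)
  sqrt(2) * .op2$Iz,      # label 2, T(1,0)
  .op2$Ip                 # label 3, T(1,+1)
)

.frobInner <- function(a, b) sum(Conj(a) * b)

# 4x4 matrices of left/right multiplication by a single-spin operator in the
# orthonormal tensor basis: L[a, b] = <B_a, O B_b>, R[a, b] = <B_a, B_b O>.
# For the operators used here (Iz, I+, I-) all entries are real.
.multMat <- function(op, side = c("left", "right")) {
  side <- match.arg(side)
  m <- matrix(0, 4, 4)
  for (b in 1:4) {
    prod <- if (side == "left") op %*% .tensorBasis[[b]] else
      .tensorBasis[[b]] %*% op
    for (a in 1:4) {
      v <- .frobInner(.tensorBasis[[a]], prod)
      if (abs(Im(v)) > 1e-14)
        stop("complex superoperator entry; basis convention violated")
      m[a, b] <- Re(v)
    }
  }
  m
}

.multMats <- local({
  ops <- list(Iz = .op2$Iz, Ip = .op2$Ip, Im = .op2$Im)
  list(
    left  = lapply(ops, .multMat, side = "left"),
    right = lapply(ops, .multMat, side = "right")
  )
})

# Base-4 encoding of label rows (numeric keys are exact up to 2^53).
.encodeLabels <- function(labels) {
  pow <- 4^(seq_len(ncol(labels)) - 1)
  as.numeric(labels %*% pow)
}

# Sparse real matrix times complex vector.
.cmv <- function(m, v) {
  as.vector(m %*% Re(v)) + 1i * as.vector(m %*% Im(v))
}

.fftshift <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1):n], x[1:floor(n / 2)])
}

# Rotating-frame offsets in Hz for every spin given the carrier (in ppm) of
# each isotope. Undetected-isotope carriers default to the isotope's mean
# shift; their exact value does not affect the detected spectrum because
# heteronuclear couplings are truncated to IzIz.
.spinOffsetsHz <- function(system, carriers) {
  iso <- system@isotopes
  vapply(seq_along(iso), function(i) {
    carrier <- carriers[[iso[i]]]
    (system@shifts[i] - carrier) * system@fieldMHz * .gammaRatio(iso[i])
  }, numeric(1))
}

.defaultCarriers <- function(system, params) {
  iso <- unique(system@isotopes)
  carriers <- lapply(iso, function(z) mean(system@shifts[system@isotopes == z]))
  names(carriers) <- iso
  center <- params@centerPpm
  if (!is.na(center)) carriers[[params@detect]] <- center
  carriers
}

# Observation frequency (MHz) of an isotope on this magnet.
.obsFreqMHz <- function(system, isotope) system@fieldMHz * .gammaRatio(isotope)

`%||%` <- function(a, b) if (is.null(a)) b else a
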