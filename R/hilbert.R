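# Dense Hilbert-space machinery. Two distinct routes live here:
#
#  * denseOracleFid: a deliberately straightforward time-domain simulator
#    (full 2^n Hamiltonian, one eigendecomposition, density matrix stepped
#    through U rho U^H). It exists as an independent oracle for the
#    restricted Liouville-space engine and refuses systems above 12 spins.
#
#  * .lineList / .spectrumFromLines: a fast frequency-domain route that
#    exploits the conservation of the per-isotope total projection quantum
#    number: the Hamiltonian is block-diagonal over (m_1H, m_19F) sectors,
#    so eigenvalues come from small real-symmetric blocks and the spectrum
#    is an explicit sum of discrete-Fourier-transformed decaying
#    exponentials. This is the engine behind the least-squares fitting.

.DENSE_CAP <- 12L

# Full 2^n rotating-frame Hamiltonian (rad/s) as a dense complex matrix.
# Spin i's state is bit i of the basis index (0 = alpha/up, 1 = beta/down).
.denseHamiltonian <- function(system, carriers = NULL, detect = "1H") {
  n <- nSpins(system)
  if (n > .DENSE_CAP)
    stop("dense simulation refused above ", .DENSE_CAP, " spins")
  if (is.null(carriers))
    carriers <- .defaultCarriers(system,
      acquisitionParams(detect = detect, centerPpm = NA_real_))
  offsets <- .spinOffsetsHz(system, carriers)
  ops <- function(i, o) {
    m <- 1 + 0i
    for (s in seq_len(n)) {
      m <- kronecker(if (s == i) o else .op2$E, m)
    }
    m
  }
  H <- matrix(0i, 2^n, 2^n)
  for (i in seq_len(n))
    H <- H + 2 * pi * offsets[i] * ops(i, .op2$Iz)
  J <- system@couplings
  iso <- system@isotopes
  Ix <- (.op2$Ip + .op2$Im) / 2
  Iy <- (.op2$Ip - .op2$Im) / (2i)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (J[a, b] == 0) next
    term <- ops(a, .op2$Iz) %*% ops(b, .op2$Iz)
    if (iso[a] == iso[b])
      term <- term + ops(a, Ix) %*% ops(b, Ix) + ops(a, Iy) %*% ops(b, Iy)
    H <- H + 2 * pi * J[a, b] * term
  }
  H
}

.denseDetectionOp <- function(system, isotope) {
  n <- nSpins(system)
  O <- matrix(0i, 2^n, 2^n)
  for (i in which(system@isotopes == isotope)) {
    m <- 1 + 0i
    for (s in seq_len(n)) m <- kronecker(if (s == i) .op2$Ip else .op2$E, m)
    O <- O + m
  }
  O
}

#' Dense Hilbert-space oracle simulation
#'
#' Brute-force pulse-acquire simulation: the full 2^n Hamiltonian is
#' diagonalised once, the one-step propagator formed, and the density
#' matrix stepped explicitly. Intended as an independent reference for the
#' restricted Liouville-space engine on small systems; refuses more than 12
#' spins, where the cubic factorisation cost becomes prohibitive.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param params an \linkS4class{AcquisitionParams}.
#' @param carriers optional named list of carrier ppm per isotope.
#' @return a \linkS4class{Fid}.
#' @export
denseOracleFid <- function(system, params, carriers = NULL) {
  if (is.null(carriers)) carriers <- .defaultCarriers(system, params)
  H <- .denseHamiltonian(system, carriers, params@detect)
  obs <- .obsFreqMHz(system, params@detect)
  dwell <- 1 / (params@sweepPpm * obs)
  eg <- eigen(H, symmetric = TRUE)
  U <- eg$vectors %*% (exp(-1i * dwell * eg$values) * Conj(t(eg$vectors)))
  O <- .denseDetectionOp(system, params@detect)
  rho <- O
  coilC <- Conj(O)
  samples <- complex(params@points)
  for (k in seq_len(params@points)) {
    samples[k] <- sum(coilC * rho)                  # Tr(O^H rho)
    if (k < params@points) rho <- U %*% rho %*% Conj(t(U))
  }
  # unit-amplitude convention: fid(0) = number of detected spins, matching
  # the normalised Liouville-space detection states
  samples <- samples / 2^(nSpins(system) - 1)
  new("Fid", samples = samples, dwell = dwell, detect = params@detect,
      obsMHz = obs, centerPpm = carriers[[params@detect]])
}

# ---- blocked line-list route ------------------------------------------------

# Transition table (frequency in Hz, real amplitude) of the pulse-acquire
# experiment, computed per (m_isotope) sector from small real-symmetric
# blocks. fid(t) = sum_l A_l exp(-2i pi nu_l t).
.lineList <- function(system, detect, carriers = NULL,
                      amplitudeCut = 1e-12) {
  n <- nSpins(system)
  if (n > .DENSE_CAP)
    stop("dense simulation refused above ", .DENSE_CAP, " spins")
  if (is.null(carriers))
    carriers <- .defaultCarriers(system,
      acquisitionParams(detect = detect, centerPpm = NA_real_))
  offsets <- .spinOffsetsHz(system, carriers)
  iso <- system@isotopes
  J <- system@couplings
  states <- 0:(2^n - 1)
  bits <- vapply(seq_len(n), function(i) bitwAnd(states, bitwShiftL(1L, i - 1L)) > 0,
                 logical(length(states)))       # TRUE = beta (down)
  mspin <- ifelse(bits, -0.5, 0.5)              # states x spins
  # sector key: total m per isotope
  isoLevels <- unique(iso)
  mIso <- vapply(isoLevels, function(z)
    rowSums(mspin[, iso == z, drop = FALSE]), numeric(length(states)))
  key <- apply(mIso, 1, paste, collapse = "/")
  sectors <- split(seq_along(states), key)

  # diagonal and homonuclear flip-flop elements, block by block
  diagH <- as.vector(mspin %*% (2 * pi * offsets))
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (J[a, b] != 0)
      diagH <- diagH + 2 * pi * J[a, b] * mspin[, a] * mspin[, b]

  eigBlock <- function(idx) {
    k <- length(idx)
    Hb <- diag(diagH[idx], k, k)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      if (J[a, b] == 0 || iso[a] != iso[b]) next
      flip <- which(bits[idx, a] != bits[idx, b])
      if (!length(flip)) next
      partner <- match(bitwXor(states[idx[flip]],
                               bitwShiftL(1L, a - 1L) + bitwShiftL(1L, b - 1L)) ,
                       states[idx])
      Hb[cbind(flip, partner)] <- Hb[cbind(flip, partner)] + pi * J[a, b]
    }
    eigen(Hb, symmetric = TRUE)
  }
  eigs <- lapply(sectors, eigBlock)

  detSpins <- which(iso == detect)
  detCol <- match(detect, isoLevels)
  freqs <- numeric(0)
  amps <- numeric(0)
  secM <- do.call(rbind, lapply(sectors, function(idx) mIso[idx[1], ]))
  for (s1 in seq_along(sectors)) {
    target <- secM[s1, ]
    target[detCol] <- target[detCol] + 1
    s2 <- which(apply(secM, 1, function(r) all(abs(r - target) < 1e-9)))
    if (!length(s2)) next
    idx1 <- sectors[[s1]]; idx2 <- sectors[[s2]]
    # detection operator block <idx2 | sum I+ | idx1>
    Ob <- matrix(0, length(idx2), length(idx1))
    for (i in detSpins) {
      src <- which(bits[idx1, i])               # spin i down in source
      if (!length(src)) next
      dst <- match(states[idx1[src]] - bitwShiftL(1L, i - 1L), states[idx2])
      ok <- which(!is.na(dst))
      if (length(ok)) Ob[cbind(dst[ok], src[ok])] <- 1
    }
    Ot <- crossprod(eigs[[s2]]$vectors, Ob %*% eigs[[s1]]$vectors)
    A <- Ot^2
    nu <- outer(eigs[[s2]]$values, eigs[[s1]]$values, "-") / (2 * pi)
    if (!length(A) || max(A) == 0) next
    keep <- which(A > amplitudeCut * max(A))
    freqs <- c(freqs, nu[keep])
    amps <- c(amps, A[keep])
  }
  list(freqHz = freqs, amplitude = amps / 2^(n - 1),
       obsMHz = .obsFreqMHz(system, detect),
       centerPpm = carriers[[detect]], detect = detect)
}

# Exact sampled FID of a line list (sum of complex exponentials).
.fidFromLines <- function(lines, dwell, nPoints) {
  samples <- cpp_fid_lines(lines$amplitude, lines$freqHz, 0, dwell,
                           as.integer(nPoints))
  new("Fid", samples = samples, dwell = dwell, detect = lines$detect,
      obsMHz = lines$obsMHz, centerPpm = lines$centerPpm)
}

# Closed-form spectrum of a line list: the exact discrete Fourier transform
# of the apodized, truncated, zero-filled FID (geometric series per line),
# evaluated on the standard fft grid. Identical (to rounding) to
# fidToSpectrum(.fidFromLines(...)).
.spectrumFromLines <- function(lines, params, obsMHz = lines$obsMHz) {
  dwell <- 1 / (params@sweepPpm * obsMHz)
  n <- params@points
  nz <- params@zerofill
  lb <- params@lineBroadening
  a <- exp((-2i * pi * lines$freqHz - pi * lb) * dwell)
  grid <- seq_len(nz) - 1 - floor(nz / 2)            # shifted fft bins
  b <- exp(2i * pi * grid / nz)
  aN <- a^n
  bN <- b^(n %% nz)
  Z <- outer(a, b)
  num <- 1 - outer(aN, bN)
  den <- 1 - Z
  small <- abs(den) < 1e-12
  G <- num / den
  if (any(small)) G[small] <- n                      # limit of the sum
  S <- as.vector((lines$amplitude + 0i) %*% G)
  freqHz <- grid / (nz * dwell)
  axis <- lines$centerPpm + freqHz / obsMHz
  new("NMRSpectrum", axisPpm = axis, intensity = Re(S),
      complexIntensity = S, params = params)
}
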