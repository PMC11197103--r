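# Cached line-list evaluation for iterative fitting. The sector structure
# of the Hamiltonian (per-isotope total projection), the flip-flop sparsity
# patterns and the detection-operator blocks depend only on the coupling
# topology, so they are built once per system; each objective evaluation
# only refills the numeric entries and rediagonalises the small
# real-symmetric blocks.

.lineListContext <- function(system, detect, carriers) {
  n <- nSpins(system)
  if (n > .DENSE_CAP)
    stop("dense simulation refused above ", .DENSE_CAP, " spins")
  iso <- system@isotopes
  states <- 0:(2^n - 1)
  bits <- vapply(seq_len(n), function(i)
    bitwAnd(states, bitwShiftL(1L, i - 1L)) > 0, logical(length(states)))
  mspin <- ifelse(bits, -0.5, 0.5)
  isoLevels <- unique(iso)
  mIso <- vapply(isoLevels, function(z)
    rowSums(mspin[, iso == z, drop = FALSE]), numeric(length(states)))
  key <- apply(mIso, 1, paste, collapse = "/")
  sectors <- split(seq_along(states), key)
  secM <- do.call(rbind, lapply(sectors, function(idx) mIso[idx[1], ]))

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  homo <- iso[pairs[, 1]] == iso[pairs[, 2]]

  secInfo <- lapply(sectors, function(idx) {
    k <- length(idx)
    msec <- mspin[idx, , drop = FALSE]
    mprod <- msec[, pairs[, 1], drop = FALSE] *
      msec[, pairs[, 2], drop = FALSE]
    flips <- list()
    for (pid in which(homo)) {
      a <- pairs[pid, 1]; b <- pairs[pid, 2]
      src <- which(bits[idx, a] != bits[idx, b])
      if (!length(src)) next
      partner <- match(bitwXor(states[idx[src]],
                               bitwShiftL(1L, a - 1L) + bitwShiftL(1L, b - 1L)),
                       states[idx])
      flips[[length(flips) + 1]] <- list(at = cbind(src, partner), pid = pid)
    }
    list(idx = idx, k = k, msec = msec, mprod = mprod, flips = flips)
  })

  detSpins <- which(iso == detect)
  detCol <- match(detect, isoLevels)
  links <- list()
  for (s1 in seq_along(sectors)) {
    target <- secM[s1, ]
    target[detCol] <- target[detCol] + 1
    s2 <- which(apply(secM, 1, function(r) all(abs(r - target) < 1e-9)))
    if (!length(s2)) next
    idx1 <- sectors[[s1]]; idx2 <- sectors[[s2]]
    Ob <- matrix(0, length(idx2), length(idx1))
    for (i in detSpins) {
      src <- which(bits[idx1, i])
      if (!length(src)) next
      dst <- match(states[idx1[src]] - bitwShiftL(1L, i - 1L), states[idx2])
      ok <- which(!is.na(dst))
      if (length(ok)) Ob[cbind(dst[ok], src[ok])] <- 1
    }
    links[[length(links) + 1]] <- list(s1 = s1, s2 = s2, Ob = Ob)
  }
  list(n = n, iso = iso, pairs = pairs, secInfo = secInfo, links = links,
       detect = detect, obsMHz = .obsFreqMHz(system, detect),
       centerPpm = carriers[[detect]], carriers = carriers,
       ampNorm = 2^(n - 1))
}

# offsets: rotating-frame offsets in Hz per spin; J: full coupling matrix.
.lineListEval <- function(ctx, offsets, J, amplitudeCut = 1e-12) {
  jvec <- 2 * pi * J[ctx$pairs]
  off <- 2 * pi * offsets
  eigs <- vector("list", length(ctx$secInfo))
  for (s in seq_along(ctx$secInfo)) {
    si <- ctx$secInfo[[s]]
    diagv <- as.vector(si$msec %*% off) + as.vector(si$mprod %*% jvec)
    if (si$k == 1) {
      eigs[[s]] <- list(values = diagv, vectors = matrix(1, 1, 1))
      next
    }
    Hb <- diag(diagv, si$k, si$k)
    for (fl in si$flips)
      Hb[fl$at] <- Hb[fl$at] + 0.5 * jvec[fl$pid]
    eigs[[s]] <- eigen(Hb, symmetric = TRUE)
  }
  freqs <- vector("list", length(ctx$links))
  amps <- vector("list", length(ctx$links))
  for (li in seq_along(ctx$links)) {
    lk <- ctx$links[[li]]
    Ot <- crossprod(eigs[[lk$s2]]$vectors, lk$Ob %*% eigs[[lk$s1]]$vectors)
    nu <- outer(eigs[[lk$s2]]$values, eigs[[lk$s1]]$values, "-") / (2 * pi)
    freqs[[li]] <- as.vector(nu)
    amps[[li]] <- as.vector(Ot * Ot)
  }
  amplitude <- unlist(amps)
  freqHz <- unlist(freqs)
  keep <- amplitude > amplitudeCut * max(amplitude)
  list(freqHz = freqHz[keep], amplitude = amplitude[keep] / ctx$ampNorm,
       obsMHz = ctx$obsMHz, centerPpm = ctx$centerPpm, detect = ctx$detect)
}

# model absorption intensity on the grid of `pars` from a cached context;
# the eigenproblem, line assembly and FID accumulation run compiled
.modelIntensityCtx <- function(ctx, offsets, J, linewidth, pars) {
  dwell <- 1 / (pars@sweepPpm * ctx$obsMHz)
  fid <- cpp_ctx_fid(ctx$secInfo, ctx$links, offsets, J[ctx$pairs],
                     ctx$ampNorm, pi * linewidth, dwell, pars@points)
  xz <- c(fid, complex(pars@zerofill - pars@points))
  Re(.fftshift(stats::fft(xz, inverse = TRUE)))
}
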