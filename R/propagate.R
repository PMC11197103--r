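# Diagonalization-free time propagation: Krylov (Lanczos) approximation of
# exp(-i L t) v using only sparse matrix-vector products. L is real
# symmetric in the orthonormal tensor product basis, so the Lanczos
# recurrence applies with complex vectors and real recurrence coefficients.

# One Krylov exponential step: returns exp(-1i * t * L) %*% v.
.expmv <- function(L, v, t, tol = 1e-10, mMax = 30L) {
  nrmv <- sqrt(Re(sum(Conj(v) * v)))
  if (nrmv == 0 || t == 0) return(v)
  m <- min(mMax, nrow(L))
  V <- matrix(0i, length(v), m)
  alpha <- numeric(m)
  beta <- numeric(m)          # beta[k] couples vector k and k+1
  V[, 1] <- v / nrmv
  w <- .cmv(L, V[, 1])
  alpha[1] <- Re(sum(Conj(V[, 1]) * w))
  w <- w - alpha[1] * V[, 1]
  k <- 1L
  happy <- FALSE
  while (k < m) {
    beta[k] <- sqrt(Re(sum(Conj(w) * w)))
    scale <- max(abs(alpha[1:k]), beta[1:k], 1)
    if (beta[k] < 1e-12 * scale) { happy <- TRUE; break }
    V[, k + 1] <- w / beta[k]
    # full reorthogonalization (cheap at these subspace sizes)
    h <- crossprod(Conj(V[, 1:k, drop = FALSE]), V[, k + 1])
    V[, k + 1] <- V[, k + 1] - V[, 1:k, drop = FALSE] %*% h
    renrm <- sqrt(Re(sum(Conj(V[, k + 1]) * V[, k + 1])))
    if (renrm < 1e-6) { happy <- TRUE; break }   # subspace exhausted
    V[, k + 1] <- V[, k + 1] / renrm
    k <- k + 1L
    w <- .cmv(L, V[, k])
    alpha[k] <- Re(sum(Conj(V[, k]) * w))
    w <- w - alpha[k] * V[, k] - beta[k - 1] * V[, k - 1]
    # error estimate: weight of the last Krylov direction in the exponential
    if (k >= 4 || k == nrow(L)) {
      eT <- .triEig(alpha[1:k], beta[1:(k - 1)])
      wts <- eT$vectors %*% (exp(-1i * t * eT$values) *
                               Conj(eT$vectors[1, ]))
      bnext <- sqrt(Re(sum(Conj(w) * w)))
      err <- abs(bnext * wts[k]) * abs(t)
      if (err < tol || k == nrow(L)) {
        return(nrmv * (V[, 1:k, drop = FALSE] %*% wts))
      }
    }
  }
  if (happy || k >= nrow(L)) {
    # invariant subspace reached (or the Krylov space spans the operator):
    # the projected exponential is exact
    eT <- .triEig(alpha[1:k], if (k > 1) beta[1:(k - 1)] else numeric(0))
    wts <- eT$vectors %*% (exp(-1i * t * eT$values) * Conj(eT$vectors[1, ]))
    return(nrmv * (V[, 1:k, drop = FALSE] %*% wts))
  }
  # not converged at mMax: halve the step (signals step too large)
  half <- .expmv(L, v, t / 2, tol, mMax)
  .expmv(L, half, t / 2, tol, mMax)
}

.triEig <- function(alpha, beta) {
  k <- length(alpha)
  T <- diag(alpha, k, k)
  if (k > 1) {
    T[cbind(1:(k - 1), 2:k)] <- beta
    T[cbind(2:k, 1:(k - 1))] <- beta
  }
  eigen(T, symmetric = TRUE)
}

#' Propagate a pulse-acquire experiment
#'
#' Computes \code{samples[k] = <coil | exp(-i L (k-1) dwell) | state>} by
#' repeated Krylov exponential action; the Liouvillian is never factorised.
#'
#' @param liouvillian a \linkS4class{Liouvillian}.
#' @param state initial state vector (complex, in the Liouvillian's basis).
#' @param dwell dwell time in seconds (> 0).
#' @param nSteps number of acquired points (>= 1).
#' @param coil detection state vector; defaults to \code{state} (quadrature
#'   detection of the same coherence that was excited).
#' @param tol per-step Krylov convergence tolerance.
#' @param detect isotope label stored in the returned \linkS4class{Fid}.
#' @param obsMHz observation frequency in MHz (axis metadata).
#' @param centerPpm carrier position in ppm (axis metadata).
#' @return a \linkS4class{Fid}.
#' @export
propagate <- function(liouvillian, state, dwell, nSteps, coil = state,
                      tol = 1e-10, detect = liouvillian@detect,
                      obsMHz = NA_real_, centerPpm = NA_real_) {
  if (dwell <= 0) stop("dwell must be positive")
  if (nSteps < 1) stop("nSteps must be >= 1")
  L <- liouvillian@matrix
  v <- state
  cc <- Conj(coil)
  samples <- complex(nSteps)
  for (k in seq_len(nSteps)) {
    samples[k] <- sum(cc * v)
    if (k < nSteps) v <- .expmv(L, v, dwell, tol = tol)
  }
  new("Fid", samples = samples, dwell = dwell, detect = detect,
      obsMHz = obsMHz, centerPpm = centerPpm)
}

# Propagate while recording the Euclidean norm of the state restricted to
# each correlation order. Returns a steps x orders matrix.
.orderTrajectory <- function(liouvillian, state, dwell, nSteps, orders,
                             maxTracked, tol = 1e-10) {
  v <- state
  out <- matrix(0, nSteps, maxTracked)
  for (k in seq_len(nSteps)) {
    amp2 <- Re(Conj(v) * v)
    for (q in seq_len(maxTracked))
      out[k, q] <- sqrt(sum(amp2[orders == q]))
    if (k < nSteps) v <- .expmv(liouvillian@matrix, v, dwell, tol = tol)
  }
  out
}
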