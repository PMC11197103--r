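# End-to-end pulse-acquire simulation: basis build -> reduction cascade ->
# Liouvillian -> Krylov propagation -> Fourier transform; plus the
# correlation-order diagnostic used to justify the state-space truncation.

# Zero couplings between the decoupled isotope and all others (ideal
# adiabatic decoupling modelled as J-zeroing).
.decoupleSystem <- function(system, decouple) {
  if (is.null(decouple)) return(system)
  J <- system@couplings
  sel <- system@isotopes == decouple
  J[sel, !sel] <- 0
  J[!sel, sel] <- 0
  methods::initialize(system, couplings = J)
}

# Which undetected spins may be restricted to longitudinal order exactly:
# those with no homonuclear coupling to another undetected spin (their only
# couplings to the evolving system are then secular IzIz terms).
.longitudinalSafe <- function(system, undetected, cutoff = 1e-9) {
  vapply(undetected, function(i) {
    same <- setdiff(undetected[system@isotopes[undetected] ==
                                 system@isotopes[i]], i)
    !length(same) || all(abs(system@couplings[i, same]) <= cutoff)
  }, logical(1))
}

#' Simulate a 1-D pulse-acquire NMR spectrum
#'
#' Composes the full restricted-state-space pipeline: product basis with a
#' correlation-order cap (optionally connectivity-screened), conservation
#' law filters, fully symmetric permutation adaptation, sparse Liouvillian,
#' Krylov time propagation and Fourier transform. The filters applied are
#' the coherence filter m = +1 on the detected isotope (quadrature
#' detection of L+) and, on undetected spins, the longitudinal spin-order
#' filter where it is exact, with the per-isotope coherence filter m = 0
#' otherwise (mode "auto"); mode "strict" applies the longitudinal filter
#' to every undetected spin (the aggressive screening used for very large
#' systems), and "off" uses only coherence filters.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param params an \linkS4class{AcquisitionParams}.
#' @param maxOrder correlation-order cap (default: all orders up to
#'   min(n, 8); amplitudes above eight-spin correlation are negligible in
#'   liquid-state experiments of this kind).
#' @param connectivity coupling-graph screening cutoff in Hz, TRUE for the
#'   0.01 Hz default, or NULL for none.
#' @param filters logical: apply conservation-law filters.
#' @param longitudinal "auto", "strict" or "off" (see Details).
#' @param symmetry logical: project onto the fully symmetric irreducible
#'   representation of the declared permutation groups.
#' @param decouple isotope label to decouple (zeroes its heteronuclear
#'   couplings; validation mode), or NULL.
#' @param method "liouville" (restricted state space, default) or "hilbert"
#'   (dense frequency-domain reference for small systems).
#' @param krylovTol per-step Krylov tolerance.
#' @return an \linkS4class{NMRSpectrum}; attribute \code{"basis"} carries
#'   the reduction cascade for the liouville method.
#' @export
simulateSpectrum <- function(system, params, maxOrder = NULL,
                             connectivity = NULL, filters = TRUE,
                             longitudinal = c("auto", "strict", "off"),
                             symmetry = TRUE, decouple = NULL,
                             method = c("liouville", "hilbert"),
                             krylovTol = 1e-10) {
  method <- match.arg(method)
  longitudinal <- match.arg(longitudinal)
  system <- .decoupleSystem(system, decouple)
  carriers <- .defaultCarriers(system, params)
  if (method == "hilbert") {
    lines <- .lineList(system, params@detect, carriers)
    return(.spectrumFromLines(lines, params))
  }
  n <- nSpins(system)
  if (is.null(maxOrder)) maxOrder <- min(n, 8L)
  basis <- buildBasis(system, maxOrder, connectivity)
  detSpins <- which(system@isotopes == params@detect)
  if (!length(detSpins)) stop("detected isotope absent from system")
  if (filters) {
    basis <- filterCoherence(basis, +1L, detSpins)
    undet <- setdiff(seq_len(n), detSpins)
    if (length(undet)) {
      if (longitudinal == "strict") {
        basis <- filterLongitudinal(basis, undet)
      } else if (longitudinal == "auto") {
        safe <- undet[.longitudinalSafe(system, undet)]
        if (length(safe)) basis <- filterLongitudinal(basis, safe)
        rest <- setdiff(undet, safe)
        for (z in unique(system@isotopes[rest]))
          basis <- filterCoherence(basis, 0L,
                                   rest[system@isotopes[rest] == z])
      } else {
        for (z in unique(system@isotopes[undet]))
          basis <- filterCoherence(basis, 0L,
                                   undet[system@isotopes[undet] == z])
      }
    }
  }
  useBasis <- basis
  if (symmetry && length(system@symmetryGroups))
    useBasis <- symmetrize(basis, system@symmetryGroups)
  L <- buildLiouvillian(system, useBasis, carriers, detect = params@detect)
  rho0 <- initialState(system, useBasis, params@detect)
  obs <- .obsFreqMHz(system, params@detect)
  dwell <- 1 / (params@sweepPpm * obs)
  fid <- propagate(L, rho0, dwell, params@points, tol = krylovTol,
                   detect = params@detect, obsMHz = obs,
                   centerPpm = carriers[[params@detect]])
  out <- fidToSpectrum(fid, params)
  attr(out, "basis") <- provenance(useBasis)
  out
}

#' Correlation-order content of the evolving state
#'
#' Propagates the pulse-acquire experiment while recording, at every time
#' step, the Euclidean norm of the projection of the state onto each
#' spin-correlation order. High orders staying orders of magnitude below
#' the single-spin amplitude is what justifies the restricted state space.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param params an \linkS4class{AcquisitionParams} (its \code{points}
#'   bounds the number of recorded steps; cap with \code{nSteps}).
#' @param maxTrackedOrder highest correlation order reported.
#' @param maxOrder basis truncation order (default: track everything, i.e.
#'   min(n, 8)).
#' @param nSteps optional cap on the recorded steps.
#' @param krylovTol per-step Krylov tolerance.
#' @return numeric matrix (steps x orders); column q is the norm of the
#'   q-spin correlation content over time.
#' @export
correlationOrderTrajectory <- function(system, params, maxTrackedOrder,
                                       maxOrder = NULL, nSteps = NULL,
                                       krylovTol = 1e-10) {
  n <- nSpins(system)
  if (is.null(maxOrder)) maxOrder <- min(n, 8L)
  maxTrackedOrder <- min(maxTrackedOrder, maxOrder)
  carriers <- .defaultCarriers(system, params)
  basis <- buildBasis(system, maxOrder)
  detSpins <- which(system@isotopes == params@detect)
  basis <- filterCoherence(basis, +1L, detSpins)
  undet <- setdiff(seq_len(n), detSpins)
  if (length(undet)) {
    safe <- undet[.longitudinalSafe(system, undet)]
    if (length(safe)) basis <- filterLongitudinal(basis, safe)
    rest <- setdiff(undet, safe)
    for (z in unique(system@isotopes[rest]))
      basis <- filterCoherence(basis, 0L, rest[system@isotopes[rest] == z])
  }
  L <- buildLiouvillian(system, basis, carriers, detect = params@detect)
  rho0 <- initialState(system, basis, params@detect)
  obs <- .obsFreqMHz(system, params@detect)
  dwell <- 1 / (params@sweepPpm * obs)
  steps <- min(params@points, nSteps %||% params@points)
  orders <- .correlationOrders(basis@labels)
  traj <- .orderTrajectory(L, rho0, dwell, steps, orders, maxTrackedOrder,
                           tol = krylovTol)
  colnames(traj) <- paste0("order", seq_len(maxTrackedOrder))
  traj
}
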