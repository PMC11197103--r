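# Restricted Liouville-space basis construction and the reduction cascade:
# correlation-order truncation (optionally connectivity-screened), exact
# conservation-law filters, and fully-symmetric permutation adaptation.

.MAX_BASIS_STATES <- 2e6

setValidity("ProductBasis", function(object) {
  if (nrow(object@labels) != length(object@keys))
    return("keys/labels length mismatch")
  if (anyDuplicated(object@keys)) return("duplicate states in basis")
  d <- object@provenance$dimension
  if (length(d) && any(diff(d) > 0))
    return("provenance dimensions must be non-increasing along the cascade")
  TRUE
})

setMethod("dimension", "ProductBasis", function(object) nrow(object@labels))

setMethod("nSpins", "ProductBasis", function(object) ncol(object@labels))

setMethod("provenance", "ProductBasis", function(object) object@provenance)

setMethod("show", "ProductBasis", function(object) {
  cat(sprintf("ProductBasis: %d states over %d spins\n", dimension(object),
              nSpins(object)))
  print(object@provenance, row.names = FALSE)
})

setMethod("dimension", "SymmetrizedBasis", function(object)
  nrow(object@projector))

setMethod("nSpins", "SymmetrizedBasis", function(object)
  nSpins(object@basis))

setMethod("provenance", "SymmetrizedBasis", function(object)
  object@provenance)

setMethod("show", "SymmetrizedBasis", function(object) {
  cat(sprintf("SymmetrizedBasis: %d fully symmetric combinations (from %d)\n",
              dimension(object), dimension(object@basis)))
  print(object@provenance, row.names = FALSE)
})

# Correlation order of each basis state (count of non-identity labels).
.correlationOrders <- function(labels) rowSums(labels != 0L)

# Per-state coherence order (sum of single-spin projection indices).
.coherenceOrders <- function(labels, spins = NULL) {
  m <- matrix(.labelM[labels + 1L], nrow(labels), ncol(labels))
  if (!is.null(spins)) m <- m[, spins, drop = FALSE]
  rowSums(m)
}

.appendStage <- function(prov, stage, dim) {
  rbind(prov, data.frame(stage = stage, dimension = dim,
                         stringsAsFactors = FALSE))
}

#' Build the restricted product-operator basis
#'
#' Enumerates all product states with correlation order (number of spins
#' simultaneously involved) up to \code{maxOrder}. With
#' \code{connectivity} set, only states whose non-identity spins form a
#' connected cluster of the J-coupling graph are kept: a documented,
#' togglable screening approximation on top of the order cap.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param maxOrder maximum correlation order retained (>= 1).
#' @param connectivity NULL for the pure combinatorial truncation, or a
#'   coupling cutoff in Hz (default 0.01 when \code{TRUE}): graph edges where
#'   |J| exceeds the cutoff.
#' @return a \linkS4class{ProductBasis}; its provenance records the full
#'   4^n dimension and the restricted dimension.
#' @examples
#' sys <- spinSystem(c("1H", "1H"), c(1, 2), matrix(c(0, 8, 8, 0), 2))
#' dimension(buildBasis(sys, 2))  # 16
#' @export
buildBasis <- function(system, maxOrder, connectivity = NULL) {
  n <- nSpins(system)
  if (n < 1) stop("empty spin system")
  if (maxOrder < 1) stop("maxOrder must be >= 1")
  maxOrder <- min(as.integer(maxOrder), n)

  cutoff <- NULL
  if (isTRUE(connectivity)) cutoff <- 0.01
  else if (is.numeric(connectivity)) cutoff <- connectivity
  if (is.null(cutoff)) {
    est <- 1 + sum(choose(n, seq_len(maxOrder)) * 3^seq_len(maxOrder))
    if (est > .MAX_BASIS_STATES)
      stop("restricted basis would have ", est,
           " states; tighten maxOrder or use connectivity screening")
  }
  subsets <- .correlationSubsets(system, maxOrder, cutoff)

  total <- sum(3^lengths(subsets)) + 1
  if (total > .MAX_BASIS_STATES)
    stop("restricted basis would have ", total,
         " states; tighten maxOrder or connectivity")

  labels <- matrix(0L, total, n)
  row <- 1L
  for (s in subsets) {
    k <- length(s)
    block <- as.matrix(expand.grid(rep(list(1:3), k), KEEP.OUT.ATTRS = FALSE))
    labels[row + seq_len(nrow(block)), s] <- as.integer(block)
    row <- row + nrow(block)
  }

  ord <- order(.correlationOrders(labels), .encodeLabels(labels))
  labels <- labels[ord, , drop = FALSE]
  prov <- data.frame(stage = c("full Liouville space",
                               if (is.null(cutoff))
                                 sprintf("correlation order <= %d", maxOrder)
                               else
                                 sprintf(
                                   "correlation order <= %d, connected (|J| > %g Hz)",
                                   maxOrder, cutoff)),
                     dimension = c(4^n, nrow(labels)),
                     stringsAsFactors = FALSE)
  new("ProductBasis", labels = labels, keys = .encodeLabels(labels),
      isotopes = system@isotopes, provenance = prov)
}

# All spin subsets of size 1..maxOrder, optionally restricted to connected
# subgraphs of the coupling graph.
.correlationSubsets <- function(system, maxOrder, cutoff) {
  n <- nSpins(system)
  subsets <- list()
  if (is.null(cutoff)) {
    for (k in seq_len(maxOrder)) {
      cmb <- utils::combn(n, k)
      for (i in seq_len(ncol(cmb)))
        subsets[[length(subsets) + 1]] <- cmb[, i]
    }
    return(subsets)
  }
  adj <- abs(system@couplings) > cutoff
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  # grow connected subsets breadth-first to avoid enumerating all combn(n, k)
  grown <- lapply(seq_len(n), function(i) i)
  subsets <- grown
  for (k in seq_len(maxOrder - 1)) {
    nxt <- list()
    seen <- character(0)
    for (s in grown) {
      nbrs <- setdiff(which(apply(adj[s, , drop = FALSE], 2, any)), s)
      for (b in nbrs) {
        cand <- sort(c(s, b))
        key <- paste(cand, collapse = ",")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1]] <- cand
        }
      }
    }
    subsets <- c(subsets, nxt)
    grown <- nxt
    if (!length(grown)) break
  }
  subsets
}

.subsetBasis <- function(basis, keep, stage) {
  labels <- basis@labels[keep, , drop = FALSE]
  new("ProductBasis", labels = labels, keys = basis@keys[keep],
      isotopes = basis@isotopes,
      provenance = .appendStage(basis@provenance, stage, nrow(labels)))
}

#' Longitudinal spin-order filter
#'
#' Keeps only states in which every listed spin carries the identity or the
#' T(1,0) (longitudinal) operator. In high-field NMR, spins that are not
#' pulsed and couple to the rest of the system only through IzSz terms stay
#' longitudinal, so this filter is exact for such spins.
#'
#' @param basis a \linkS4class{ProductBasis}.
#' @param spins integer indices of the spins to restrict.
#' @return the filtered \linkS4class{ProductBasis} (provenance appended).
#' @export
filterLongitudinal <- function(basis, spins) {
  spins <- as.integer(spins)
  if (length(spins) == 0) return(basis)
  if (any(spins < 1 | spins > nSpins(basis))) stop("spin index out of range")
  sub <- basis@labels[, spins, drop = FALSE]
  keep <- rowSums(sub == 1L | sub == 3L) == 0
  .subsetBasis(basis, keep, sprintf("longitudinal filter on spins {%s}",
                                    paste(spins, collapse = ",")))
}

#' Coherence-order filter
#'
#' Keeps only states whose summed projection quantum number over the listed
#' spins equals \code{totalM}. The per-isotope total projection is conserved
#' by the high-field Hamiltonian, so restricting to the subspace populated
#' by the initial state is exact. Quadrature detection of L+ magnetization
#' lives in the m = +1 subspace of the detected isotope.
#'
#' @param basis a \linkS4class{ProductBasis}.
#' @param totalM target total projection quantum number.
#' @param spins integer indices of the spins summed over.
#' @return the filtered \linkS4class{ProductBasis} (provenance appended).
#' @export
filterCoherence <- function(basis, totalM, spins) {
  spins <- as.integer(spins)
  if (any(spins < 1 | spins > nSpins(basis))) stop("spin index out of range")
  if (abs(totalM) > length(spins))
    stop("|totalM| cannot exceed the number of listed spins")
  keep <- .coherenceOrders(basis@labels, spins) == totalM
  .subsetBasis(basis, keep, sprintf("coherence m = %+d on spins {%s}",
                                    totalM, paste(spins, collapse = ",")))
}

#' Fully symmetric permutation adaptation
#'
#' Projects the basis onto the fully symmetric irreducible representation of
#' the direct product of the declared permutation groups (the only irrep
#' needed for liquid-state observables). The reduced states are orthonormal
#' orbit averages of product states, so the projector applied twice equals
#' the projector applied once.
#'
#' @param basis a \linkS4class{ProductBasis}, closed under every group
#'   permutation (guaranteed when built without connectivity screening or
#'   with a permutation-invariant coupling graph).
#' @param groups symmetry groups in the format of
#'   \code{SpinSystem@symmetryGroups} (or a \linkS4class{SpinSystem}).
#' @return a \linkS4class{SymmetrizedBasis}.
#' @export
symmetrize <- function(basis, groups) {
  if (is(groups, "SpinSystem")) groups <- groups@symmetryGroups
  n <- nSpins(basis)
  perms <- .permsFromGroups(groups, n)
  if (length(perms) == 1) {
    proj <- Matrix::Diagonal(dimension(basis))
    return(new("SymmetrizedBasis", basis = basis,
               projector = methods::as(proj, "CsparseMatrix"),
               provenance = .appendStage(basis@provenance,
                                         "symmetry (trivial group)",
                                         dimension(basis))))
  }
  keyMat <- vapply(perms, function(p)
    .encodeLabels(basis@labels[, p, drop = FALSE]), numeric(dimension(basis)))
  if (!all(keyMat %in% basis@keys))
    stop("basis is not closed under a symmetry group permutation; ",
         "the truncation is incompatible with the declared symmetry")
  canonical <- apply(keyMat, 1, min)
  orbitId <- match(canonical, sort(unique(canonical)))
  orbitSize <- tabulate(orbitId)
  proj <- Matrix::sparseMatrix(i = orbitId, j = seq_along(orbitId),
                               x = 1 / sqrt(orbitSize[orbitId]),
                               dims = c(max(orbitId), dimension(basis)))
  new("SymmetrizedBasis", basis = basis, projector = proj,
      provenance = .appendStage(basis@provenance,
                                sprintf(
                                  "symmetry (fully symmetric irrep, |G| = %d)",
                                  length(perms)),
                                nrow(proj)))
}

.permsFromGroups <- function(groups, n) {
  elems <- list(seq_len(n))
  for (g in groups) {
    idx <- as.integer(g$spins)
    local <- .allPermutations(length(idx))
    new <- list()
    for (e in elems) for (p in local) {
      q <- e
      q[idx] <- e[idx[p]]
      new[[length(new) + 1]] <- q
    }
    elems <- new
  }
  elems
}

#' State-space reduction report
#'
#' The cascade of reduction stages applied to a basis, as a machine-readable
#' table (printed human-readably by \code{show}).
#'
#' @param basis a \linkS4class{ProductBasis} or \linkS4class{SymmetrizedBasis}.
#' @return data.frame with columns \code{stage} and \code{dimension}.
#' @export
reductionReport <- function(basis) {
  prov <- provenance(basis)
  if (!nrow(prov)) stop("basis has empty provenance")
  prov
}
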