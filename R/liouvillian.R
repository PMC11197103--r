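# Assembly of the high-field Hamiltonian commutation superoperator directly
# in the restricted product basis, without ever forming 2^n x 2^n matrices.
#
# H = sum_i w_i Iz(i) + 2*pi * sum_{i<j} J_ij * (Ii . Ij)   (same isotope)
#                     + 2*pi * sum_{i<j} J_ij * Iz(i) Iz(j) (different isotope)
#
# The commutation superoperator of a product term factorises into per-site
# left- and right-multiplication 4x4 matrices, so its matrix elements in the
# orthonormal spherical-tensor product basis are assembled site by site.
# States generated outside the restricted basis are projected out (Galerkin
# restriction).

setMethod("dimension", "Liouvillian", function(object) nrow(object@matrix))

setMethod("show", "Liouvillian", function(object) {
  cat(sprintf("Liouvillian: %d x %d, %d nonzeros (rad/s)\n",
              nrow(object@matrix), ncol(object@matrix),
              Matrix::nnzero(object@matrix)))
})

#' Build the Liouvillian in a restricted basis
#'
#' Assembles the commutation superoperator of the rotating-frame high-field
#' Hamiltonian over a \linkS4class{ProductBasis} or
#' \linkS4class{SymmetrizedBasis}. Couplings between spins of the same
#' isotope are kept in full (required for strongly coupled spins sharing a
#' chemical shift); heteronuclear couplings are truncated to the secular
#' IzIz form.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param basis a basis built for this system.
#' @param carriers named list of carrier positions (ppm) per isotope;
#'   defaults to the mean shift of each isotope.
#' @param detect isotope whose carrier takes priority (metadata only).
#' @return a \linkS4class{Liouvillian} (sparse real symmetric, rad/s).
#' @export
buildLiouvillian <- function(system, basis, carriers = NULL, detect = "1H") {
  if (is(basis, "SymmetrizedBasis")) {
    inner <- buildLiouvillian(system, basis@basis, carriers, detect)
    V <- basis@projector
    m <- V %*% inner@matrix %*% Matrix::t(V)
    return(new("Liouvillian", matrix = methods::as(m, "CsparseMatrix"),
               basis = basis, detect = detect))
  }
  if (!is(basis, "ProductBasis")) stop("basis must be a ProductBasis")
  n <- nSpins(system)
  if (nSpins(basis) != n || !identical(basis@isotopes, system@isotopes))
    stop("basis/system mismatch")
  if (is.null(carriers)) carriers <- .defaultCarriers(system,
    acquisitionParams(detect = detect, centerPpm = NA_real_))
  offsets <- .spinOffsetsHz(system, carriers)

  trip <- list(i = vector("list", 0), j = vector("list", 0),
               x = vector("list", 0))
  add <- function(i, j, x) {
    k <- length(trip$i) + 1
    trip$i[[k]] <<- i; trip$j[[k]] <<- j; trip$x[[k]] <<- x
  }

  # Zeeman terms
  for (s in seq_len(n))
    if (abs(offsets[s]) > 0)
      .accumulateTerm(basis, sites = s, ops = list("Iz"),
                      coeff = 2 * pi * offsets[s], add = add)

  # Coupling terms
  J <- system@couplings
  iso <- system@isotopes
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (J[a, b] == 0) next
    cf <- 2 * pi * J[a, b]
    .accumulateTerm(basis, c(a, b), list("Iz", "Iz"), cf, add)
    if (iso[a] == iso[b]) {
      .accumulateTerm(basis, c(a, b), list("Ip", "Im"), cf / 2, add)
      .accumulateTerm(basis, c(a, b), list("Im", "Ip"), cf / 2, add)
    }
  }

  d <- dimension(basis)
  if (!length(trip$i)) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(d, d))
  } else {
    m <- Matrix::sparseMatrix(i = unlist(trip$i), j = unlist(trip$j),
                              x = unlist(trip$x), dims = c(d, d))
  }
  new("Liouvillian", matrix = m, basis = basis, detect = detect)
}

# Accumulate sparse triplets of the commutation superoperator of one
# product term  coeff * O(site1) [P(site2)] : C = L(O)L(P) - R(O)R(P).
.accumulateTerm <- function(basis, sites, ops, coeff, add) {
  labels <- basis@labels
  keys <- basis@keys
  nstates <- nrow(labels)
  pw <- 4^(sites - 1)
  b1 <- labels[, sites[1]] + 1L
  Lo <- .multMats$left[[ops[[1]]]]; Ro <- .multMats$right[[ops[[1]]]]
  if (length(sites) == 1) {
    for (a in 1:4) {
      amp <- coeff * (Lo[a, b1] - Ro[a, b1])
      nz <- which(abs(amp) > 1e-14)
      if (!length(nz)) next
      newkey <- keys[nz] + (a - b1[nz]) * pw[1]
      row <- match(newkey, keys)
      ok <- which(!is.na(row))
      if (length(ok)) add(row[ok], nz[ok], amp[nz][ok])
    }
    return(invisible())
  }
  b2 <- labels[, sites[2]] + 1L
  Lp <- .multMats$left[[ops[[2]]]]; Rp <- .multMats$right[[ops[[2]]]]
  for (a1 in 1:4) for (a2 in 1:4) {
    amp <- coeff * (Lo[a1, b1] * Lp[a2, b2] - Ro[a1, b1] * Rp[a2, b2])
    nz <- which(abs(amp) > 1e-14)
    if (!length(nz)) next
    newkey <- keys[nz] + (a1 - b1[nz]) * pw[1] + (a2 - b2[nz]) * pw[2]
    row <- match(newkey, keys)
    ok <- which(!is.na(row))
    if (length(ok)) add(row[ok], nz[ok], amp[nz][ok])
  }
  invisible()
}

#' Initial state after an ideal 90-degree pulse
#'
#' The detection-relevant part of the density operator at the start of
#' quadrature detection: the sum of single-spin T(1,+1) (I+) states over all
#' spins of the detected isotope. Each contributing basis state has unit
#' coefficient, so the vector norm is sqrt(number of detected spins).
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param basis a \linkS4class{ProductBasis} or \linkS4class{SymmetrizedBasis}.
#' @param isotope detected isotope label.
#' @return complex state vector in the given basis.
#' @export
initialState <- function(system, basis, isotope) {
  if (!isotope %in% system@isotopes)
    stop("isotope ", isotope, " absent from the system")
  inner <- if (is(basis, "SymmetrizedBasis")) basis@basis else basis
  orders <- .correlationOrders(inner@labels)
  v <- numeric(dimension(inner))
  sel <- which(orders == 1)
  for (s in sel) {
    spin <- which(inner@labels[s, ] != 0L)
    if (inner@labels[s, spin] == 3L && system@isotopes[spin] == isotope)
      v[s] <- 1
  }
  v <- v + 0i
  if (is(basis, "SymmetrizedBasis")) v <- .cmv(basis@projector, v)
  v
}
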