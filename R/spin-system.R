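#' Construct a spin system
#'
#' Builds and validates a \linkS4class{SpinSystem}. Internal resonance
#' frequencies are computed as \code{shift_ppm * fieldMHz * gammaRatio} Hz,
#' which is how mixed 1H/19F offsets must combine on one magnet. Only
#' spin-1/2 nuclei (1H, 19F) are accepted.
#'
#' @param isotopes character vector of isotope labels ("1H" or "19F").
#' @param shifts numeric vector of chemical shifts in ppm, one per spin.
#' @param couplings symmetric numeric matrix of scalar couplings in Hz with
#'   zero diagonal (a single number is accepted for two spins).
#' @param fieldMHz 1H Larmor frequency of the magnet in MHz.
#' @param symmetryGroups list of \code{list(spins =, label =)}: spin index
#'   sets obeying full permutation groups (e.g. methyl rotors, label "S3").
#' @param equivalences list of integer vectors declaring molecule-level
#'   chemical equivalence (parameter ties for fitting).
#' @return a validated \linkS4class{SpinSystem}.
#' @examples
#' hf <- spinSystem(c("1H", "19F"), c(4.5, -180), couplings = 48)
#' nSpins(hf)
#' @export
spinSystem <- function(isotopes, shifts, couplings, fieldMHz = 500,
                       symmetryGroups = list(), equivalences = list()) {
  n <- length(isotopes)
  if (length(couplings) == 1 && n == 2)
    couplings <- matrix(c(0, couplings, couplings, 0), 2, 2)
  couplings <- as.matrix(couplings)
  storage.mode(couplings) <- "double"
  symmetryGroups <- lapply(symmetryGroups, function(g) {
    if (is.numeric(g)) g <- list(spins = g)
    list(spins = as.integer(g$spins), label = g$label %||% "S")
  })
  equivalences <- lapply(equivalences, as.integer)
  obj <- new("SpinSystem", isotopes = as.character(isotopes),
             shifts = as.numeric(shifts), couplings = couplings,
             fieldMHz = as.numeric(fieldMHz),
             symmetryGroups = symmetryGroups, equivalences = equivalences)
  validObject(obj)
  obj
}

setValidity("SpinSystem", function(object) {
  n <- length(object@isotopes)
  bad <- setdiff(unique(object@isotopes), .knownIsotopes())
  if (length(bad))
    return(sprintf("isotopes: unsupported (non spin-1/2) nucleus '%s'", bad[1]))
  if (length(object@shifts) != n)
    return("shifts_ppm: length does not match the number of spins")
  if (!all(is.finite(object@shifts)))
    return("shifts_ppm: all chemical shifts must be finite")
  J <- object@couplings
  if (!all(dim(J) == c(n, n)))
    return("J_hz: matrix dimensions inconsistent with the spin count")
  if (!all(is.finite(J)))
    return("J_hz: all couplings must be finite")
  if (max(abs(J - t(J))) > 1e-9)
    return("J_hz: coupling matrix is not symmetric")
  if (max(abs(diag(J))) > 1e-12)
    return("J_hz: diagonal must be zero")
  if (length(object@fieldMHz) != 1 || object@fieldMHz <= 0)
    return("base_frequency_mhz: must be a positive scalar")
  members <- unlist(lapply(object@symmetryGroups, `[[`, "spins"))
  if (length(members)) {
    if (any(members < 1 | members > n))
      return("symmetry_groups: spin index out of range")
    if (anyDuplicated(members))
      return("symmetry_groups: groups must be pairwise disjoint")
  }
  for (g in object@symmetryGroups) {
    idx <- g$spins
    if (length(unique(object@isotopes[idx])) > 1)
      return("symmetry_groups: members of one group must share an isotope")
    if (diff(range(object@shifts[idx])) > 1e-9)
      return("symmetry_groups: members of one group must share a chemical shift")
    outside <- setdiff(seq_len(n), idx)
    for (k in outside)
      if (diff(range(J[idx, k])) > 1e-9)
        return(sprintf(
          "symmetry_groups: members couple unequally to spin %d", k))
    if (length(idx) > 2) {
      intra <- J[idx, idx][upper.tri(J[idx, idx])]
      if (diff(range(intra)) > 1e-9)
        return("symmetry_groups: intra-group couplings must be equal")
    }
  }
  for (e in object@equivalences)
    if (any(e < 1 | e > n))
      return("equivalences: spin index out of range")
  TRUE
})

#' @describeIn spinSystem number of spins.
#' @param object a \linkS4class{SpinSystem}.
#' @export
setMethod("nSpins", "SpinSystem", function(object) length(object@isotopes))

#' @rdname spinSystem
#' @export
setMethod("isotopes", "SpinSystem", function(object) object@isotopes)

#' @rdname spinSystem
#' @export
setMethod("chemicalShifts", "SpinSystem", function(object) object@shifts)

#' @rdname spinSystem
#' @export
setMethod("jCouplings", "SpinSystem", function(object) object@couplings)

setMethod("show", "SpinSystem", function(object) {
  n <- nSpins(object)
  tab <- table(object@isotopes)
  cat(sprintf("SpinSystem: %d spins (%s) at %.1f MHz\n", n,
              paste(sprintf("%d x %s", tab, names(tab)), collapse = ", "),
              object@fieldMHz))
  if (length(object@symmetryGroups))
    cat(sprintf("  symmetry: %s\n", paste(vapply(object@symmetryGroups,
      function(g) sprintf("%s{%s}", g$label,
                          paste(g$spins, collapse = ",")), ""),
      collapse = " x ")))
  cat(sprintf("  couplings: %d nonzero\n",
              sum(object@couplings[upper.tri(object@couplings)] != 0)))
})

#' Hilbert- and Liouville-space dimensions
#'
#' For n spin-1/2 nuclei the Hilbert (wavefunction) space has dimension 2^n
#' and the Liouville (density operator) space 4^n.
#'
#' @param system a \linkS4class{SpinSystem} or a spin count.
#' @return numeric scalar (numeric because 4^16 exceeds integer range).
#' @export
hilbertDimension <- function(system) {
  n <- if (is(system, "SpinSystem")) nSpins(system) else as.integer(system)
  2^n
}

#' @rdname hilbertDimension
#' @export
liouvilleDimension <- function(system) {
  n <- if (is(system, "SpinSystem")) nSpins(system) else as.integer(system)
  4^n
}

#' Read a spin system from a structured text file
#'
#' The file is YAML with fields \code{spins}, \code{shifts_ppm}, \code{j_hz}
#' (full matrix, row per spin), \code{base_frequency_mhz}, and optional
#' \code{symmetry} (list of \code{\{spins, group\}}) and \code{equivalences}
#' (list of spin-index lists). Spin order in the file is authoritative;
#' indices are 1-based as in reports.
#'
#' @param path file path.
#' @return a validated \linkS4class{SpinSystem}.
#' @export
readSpinSystem <- function(path) {
  if (!file.exists(path)) stop("spin system file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("parse failure in '", path, "': ",
                                           conditionMessage(e)))
  for (field in c("spins", "shifts_ppm", "j_hz"))
    if (is.null(doc[[field]]))
      stop("spin system file missing field '", field, "'")
  n <- length(doc$spins)
  J <- do.call(rbind, lapply(doc$j_hz, as.numeric))
  if (!all(dim(J) == c(n, n)))
    stop("j_hz: matrix dimensions inconsistent with the ", n, " spins listed")
  groups <- lapply(doc$symmetry %||% list(), function(g)
    list(spins = as.integer(g$spins), label = g$group %||% "S"))
  eqs <- lapply(doc$equivalences %||% list(), as.integer)
  spinSystem(isotopes = doc$spins, shifts = as.numeric(doc$shifts_ppm),
             couplings = J, fieldMHz = doc$base_frequency_mhz %||% 500,
             symmetryGroups = groups, equivalences = eqs)
}

#' Write a spin system to a structured text file
#'
#' Inverse of \code{\link{readSpinSystem}}; the round trip is the identity
#' on all fields.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpinSystem <- function(system, path) {
  doc <- list(
    spins = as.list(system@isotopes),
    shifts_ppm = as.list(system@shifts),
    base_frequency_mhz = system@fieldMHz,
    j_hz = lapply(seq_len(nSpins(system)),
                  function(i) as.list(system@couplings[i, ]))
  )
  if (length(system@symmetryGroups))
    doc$symmetry <- lapply(system@symmetryGroups, function(g)
      list(spins = as.list(g$spins), group = g$label))
  if (length(system@equivalences))
    doc$equivalences <- lapply(system@equivalences, as.list)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Parameter-tying map implied by symmetry
#'
#' Returns the constraint descriptors that reduce the free parameters of a
#' fit: which chemical shifts are forced equal (orbits of the declared
#' permutation groups, merged with molecule-level equivalence declarations)
#' and which couplings are forced equal (orbits of spin pairs under the
#' composite permutation group).
#'
#' @param system a \linkS4class{SpinSystem}.
#' @return list with elements \code{shiftClasses} (list of integer vectors),
#'   \code{jClasses} (list of two-column index matrices, upper triangle),
#'   and \code{descriptors} (human-readable constraint strings).
#' @export
validateEquivalence <- function(system) {
  n <- nSpins(system)
  perms <- symmetryGroupElements(system)

  # Shift classes: union-find over group orbits and declared equivalences.
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (g in system@symmetryGroups)
    for (k in g$spins[-1]) union2(g$spins[1], k)
  for (e in system@equivalences) {
    if (length(unique(system@isotopes[e])) > 1)
      stop("equivalences: inconsistent tie across isotopes (spins ",
           paste(e, collapse = ","), ")")
    for (k in e[-1]) union2(e[1], k)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  shiftClasses <- unname(split(seq_len(n), roots))

  # J classes: orbits of unordered pairs under the composite group, then
  # merged across declared equivalence ties when couplings already agree.
  pairKey <- function(i, j) paste(min(i, j), max(i, j))
  seen <- new.env(hash = TRUE)
  jClasses <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.null(seen[[pairKey(i, j)]])) next
    orbit <- unique(t(vapply(perms, function(p) sort(c(p[i], p[j])),
                             integer(2))))
    jref <- system@couplings[i, j]
    for (r in seq_len(nrow(orbit))) {
      if (abs(system@couplings[orbit[r, 1], orbit[r, 2]] - jref) > 1e-9)
        stop(sprintf(
          "inconsistent declared ties: J[%d,%d] differs from J[%d,%d]",
          i, j, orbit[r, 1], orbit[r, 2]))
      seen[[pairKey(orbit[r, 1], orbit[r, 2])]] <- TRUE
    }
    jClasses[[length(jClasses) + 1]] <- orbit
  }

  descriptors <- c(
    vapply(Filter(function(cl) length(cl) > 1, shiftClasses), function(cl)
      sprintf("shift(%s) tied", paste(cl, collapse = ",")), ""),
    vapply(Filter(function(m) nrow(m) > 1, jClasses), function(m)
      sprintf("J(%s) tied", paste(apply(m, 1, paste, collapse = "-"),
                                  collapse = ",")), "")
  )
  list(shiftClasses = shiftClasses, jClasses = jClasses,
       descriptors = descriptors)
}

#' Elements of the composite permutation group
#'
#' Expands the declared symmetry groups (each a full symmetric group on its
#' spin set) into explicit permutations of all spins: the direct product of
#' the per-group symmetric groups. Two methyl rotors (S3 x S3) give 36
#' elements.
#'
#' @param system a \linkS4class{SpinSystem}.
#' @return list of integer permutation vectors of length \code{nSpins}.
#' @export
symmetryGroupElements <- function(system) {
  n <- nSpins(system)
  elems <- list(seq_len(n))
  for (g in system@symmetryGroups) {
    idx <- g$spins
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

.allPermutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- .allPermutations(k - 1)
    for (r in rest) {
      v <- integer(k)
      v[1] <- i
      v[-1] <- setdiff(seq_len(k), i)[r]
      out[[length(out) + 1]] <- v
    }
  }
  out
}

#' Acquisition parameter constructor
#'
#' Defaults follow routine practice on a 500 MHz instrument: 1H spectra with
#' 131072 points zero-filled to 262144 over a 14 ppm sweep centred at 5 ppm;
#' 19F spectra with 262144 points zero-filled to 524288 over a 50 ppm sweep
#' centred on the 19F signal (centre resolved at simulation time when NA).
#'
#' @param detect detected isotope, "1H" or "19F".
#' @param points time-domain points.
#' @param zerofill padded length (>= points).
#' @param sweepPpm spectral width in ppm.
#' @param centerPpm carrier position in ppm (NA = centre of detected signal).
#' @param lineBroadening exponential apodization, Hz.
#' @return an \linkS4class{AcquisitionParams} object.
#' @export
acquisitionParams <- function(detect = "1H",
                              points = if (detect == "1H") 131072L else 262144L,
                              zerofill = 2L * points,
                              sweepPpm = if (detect == "1H") 14 else 50,
                              centerPpm = if (detect == "1H") 5.0 else NA_real_,
                              lineBroadening = 0.5) {
  obj <- new("AcquisitionParams", detect = detect,
             points = as.integer(points), zerofill = as.integer(zerofill),
             sweepPpm = as.numeric(sweepPpm),
             centerPpm = as.numeric(centerPpm),
             lineBroadening = as.numeric(lineBroadening))
  validObject(obj)
  obj
}

setValidity("AcquisitionParams", function(object) {
  if (object@zerofill < object@points)
    return("zerofill_to must be >= n_points")
  if (object@sweepPpm <= 0) return("sweep_ppm must be positive")
  if (object@points < 1) return("n_points must be positive")
  if (object@lineBroadening < 0) return("line_broadening_hz must be >= 0")
  TRUE
})
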