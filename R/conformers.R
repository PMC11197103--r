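# Conformer-ensemble thermodynamics: Boltzmann populations, first-order
# uncertainty propagation with its analytic upper bound, ensemble
# J-averaging, staggered-rotamer enumeration, dihedral-grid condensation,
# percent-antiperiplanar scoring and the J vs %app linear correlation.

.RGAS <- 8.314462618e-3  # kJ/(mol K)

.tokenizeLabel <- function(label) {
  out <- regmatches(label, gregexpr("(a|g-|g)", label, ignore.case = TRUE))[[1]]
  if (nchar(paste(out, collapse = "")) != nchar(label))
    stop("invalid conformer label: ", label)
  out
}

setValidity("ConformerEnsemble", function(object) {
  n <- length(object@labels)
  if (length(object@energies) != n || length(object@degeneracy) != n)
    return("labels/energies/degeneracy length mismatch")
  if (n == 0) return("ensemble is empty")
  if (abs(min(object@energies)) > 1e-9)
    return("energies must be relative (minimum zero)")
  if (any(object@degeneracy < 1)) return("degeneracies must be >= 1")
  tk <- tryCatch(lapply(object@labels, .tokenizeLabel),
                 error = function(e) conditionMessage(e))
  if (is.character(tk)) return(tk)
  if (length(unique(lengths(tk))) > 1)
    return("labels must all describe the same number of dihedrals")
  if (nrow(object@jTable) && nrow(object@jTable) != n)
    return("jTable rows must match the number of conformers")
  TRUE
})

#' Construct a conformer ensemble
#'
#' @param labels dihedral descriptor strings over the alphabet a / g / g-
#'   (case-insensitive; capital letters for CC-CC dihedrals are carried as-is).
#' @param energies relative free energies in kJ/mol; shifted so the minimum
#'   is zero.
#' @param degeneracy positive integer per conformer (default 1).
#' @param dipole optional dipole moments in Debye.
#' @param jTable optional numeric matrix (conformers x pairs) of
#'   three-bond couplings in Hz, with named columns identifying the pairs.
#' @return a validated \linkS4class{ConformerEnsemble}.
#' @export
conformerEnsemble <- function(labels, energies, degeneracy = 1,
                              dipole = NA_real_, jTable = NULL) {
  n <- length(labels)
  energies <- as.numeric(energies) - min(energies)
  if (is.null(jTable)) jTable <- matrix(numeric(0), n, 0)
  obj <- new("ConformerEnsemble", labels = as.character(labels),
             energies = energies,
             degeneracy = rep_len(as.integer(degeneracy), n),
             dipole = rep_len(as.numeric(dipole), n),
             jTable = as.matrix(jTable))
  validObject(obj)
  obj
}

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf(
    "ConformerEnsemble: %d conformers (%d dihedrals), E range 0 .. %.2f kJ/mol\n",
    length(object@labels), length(.tokenizeLabel(object@labels[1])),
    max(object@energies)))
  if (ncol(object@jTable))
    cat(sprintf("  J table: %s\n",
                paste(colnames(object@jTable), collapse = ", ")))
})

setValidity("PopulationResult", function(object) {
  if (any(object@p < -1e-12)) return("populations must be non-negative")
  if (abs(sum(object@p) - 1) > 1e-12) return("populations must sum to one")
  if (any(object@sigmaP > object@sigmaPBound + 1e-12))
    return("sigmaP must not exceed its upper bound")
  TRUE
})

#' @rdname boltzmannPopulations
#' @param object a \linkS4class{PopulationResult}.
#' @export
setMethod("populations", "PopulationResult", function(object) object@p)

setMethod("show", "PopulationResult", function(object) {
  cat(sprintf(
    "PopulationResult: %d conformers at %.1f K (sigma_E = %.2f kJ/mol)\n",
    length(object@p), object@temperature, object@sigmaE))
  top <- order(object@p, decreasing = TRUE)[seq_len(min(3, length(object@p)))]
  for (i in top)
    cat(sprintf("  p[%d] = %.3f +- %.3f\n", i, object@p[i], object@sigmaP[i]))
})

#' Boltzmann conformer populations
#'
#' p_k is proportional to degeneracy_k * exp(-E_k / RT), normalised by the
#' partition function Z = sum_n g_n exp(-E_n / RT).
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param temperature temperature in K (default 298, room temperature).
#' @return a \linkS4class{PopulationResult} with zero uncertainties.
#' @export
boltzmannPopulations <- function(ensemble, temperature = 298) {
  if (temperature <= 0) stop("temperature must be positive")
  w <- ensemble@degeneracy * exp(-ensemble@energies / (.RGAS * temperature))
  p <- w / sum(w)
  new("PopulationResult", p = p, sigmaP = numeric(length(p)),
      sigmaPBound = numeric(length(p)), temperature = temperature,
      sigmaE = 0)
}

#' First-order uncertainty propagation for Boltzmann populations
#'
#' Treats every conformer energy as carrying the same independent standard
#' deviation sigma_E and propagates to the populations to first order.
#' Differentiating p_k = g_k exp(-E_k/RT) / Z gives
#' dp_k/dE_n = p_k p_n / RT for n != k and -p_k (1 - p_k) / RT for n = k,
#' hence
#'   sigma_p_k^2 = (sigma_E p_k / RT)^2 [ (1 - p_k)^2 + sum_{n != k} p_n^2 ].
#' Bounding the sum of squares by the square of the sum yields the more
#' convenient upper bound
#'   sigma_p_k <= sqrt(2) (sigma_E / RT) p_k (1 - p_k),
#' which involves only the conformer's own population.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param temperature temperature in K.
#' @param sigmaE energy standard deviation in kJ/mol; the default 0.42
#'   reflects cross-method comparison of computed conformer energy
#'   differences in solvated 1,3-difluoroalkanes.
#' @return a \linkS4class{PopulationResult}.
#' @export
populationUncertainty <- function(ensemble, temperature = 298,
                                  sigmaE = 0.42) {
  if (sigmaE < 0) stop("sigmaE must be non-negative")
  pr <- boltzmannPopulations(ensemble, temperature)
  p <- pr@p
  rt <- .RGAS * temperature
  if (length(p) == 1) {
    sp <- 0; bound <- 0
  } else {
    sumsq <- sum(p^2) - p^2
    sp <- (sigmaE / rt) * p * sqrt((1 - p)^2 + sumsq)
    bound <- sqrt(2) * (sigmaE / rt) * p * (1 - p)
  }
  new("PopulationResult", p = p, sigmaP = sp, sigmaPBound = bound,
      temperature = temperature, sigmaE = sigmaE)
}

#' Ensemble-averaged J-coupling
#'
#' Boltzmann-weighted (degeneracy-aware) average of a per-conformer
#' coupling: <J> = sum_n g_n J_n exp(-E_n/RT) / sum_n g_n exp(-E_n/RT).
#' Over a Monte-Carlo instance set this is the unbiased estimator of the
#' thermal integral over dihedral space.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble} with a J table.
#' @param temperature temperature in K.
#' @param pair column name in the J table.
#' @return averaged coupling in Hz.
#' @export
ensembleAverageJ <- function(ensemble, temperature = 298, pair) {
  if (!ncol(ensemble@jTable) || !(pair %in% colnames(ensemble@jTable)))
    stop("no J values stored for pair '", pair, "'")
  j <- ensemble@jTable[, pair]
  if (any(!is.finite(j))) stop("missing J values for pair '", pair, "'")
  p <- boltzmannPopulations(ensemble, temperature)@p
  sum(p * j)
}

#' Enumerate every staggered conformation
#'
#' All 3^n dihedral label strings over {a, g, g-}: 9 conformers for two
#' dihedrals (propane/pentane backbones), 81 for four (heptanes).
#'
#' @param nDihedrals number of rotatable bonds (>= 1).
#' @return a \linkS4class{ConformerEnsemble} skeleton (zero energies, unit
#'   degeneracies).
#' @export
enumerateStaggered <- function(nDihedrals) {
  if (nDihedrals < 1) stop("nDihedrals must be >= 1")
  tok <- c("a", "g", "g-")
  grid <- expand.grid(rep(list(tok), nDihedrals), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # first dihedral varies slowest, reading order of a conformational grid
  labels <- apply(grid[, rev(seq_len(nDihedrals)), drop = FALSE], 1, paste,
                  collapse = "")
  conformerEnsemble(labels, numeric(length(labels)))
}

#' Condense a 4-dihedral population grid
#'
#' For four-dihedral chains the 81 conformer populations form a 9 x 9 grid;
#' each cell of the condensed 3 x 3 grid is the sum of the populations of
#' the nine conformations sharing the selected dihedral pair: the two inner
#' (central CC-CC) dihedrals or the two outer ones.
#'
#' @param populations named numeric vector of 81 populations (names are
#'   4-token conformer labels), or a \linkS4class{PopulationResult} plus
#'   \code{ensemble}.
#' @param axis "inner" (dihedrals 2 and 3) or "outer" (dihedrals 1 and 4).
#' @param ensemble optional \linkS4class{ConformerEnsemble} providing the
#'   labels when \code{populations} is unnamed.
#' @return 3 x 3 numeric matrix with dimnames over {a, g, g-}; its grand
#'   total equals the total input population.
#' @export
condenseGrid <- function(populations, axis = c("inner", "outer"),
                         ensemble = NULL) {
  axis <- match.arg(axis)
  if (is(populations, "PopulationResult")) populations <- populations@p
  labels <- names(populations)
  if (is.null(labels)) {
    if (is.null(ensemble)) stop("populations must be named by conformer label")
    labels <- ensemble@labels
  }
  tok <- lapply(labels, .tokenizeLabel)
  if (any(lengths(tok) != 4))
    stop("grid condensation requires 4-dihedral conformer labels")
  sel <- if (axis == "inner") c(2, 3) else c(1, 4)
  lev <- c("a", "g", "g-")
  out <- matrix(0, 3, 3, dimnames = list(lev, lev))
  for (i in seq_along(labels)) {
    r <- match(tolower(tok[[i]][sel[1]]), lev)
    cc <- match(tolower(tok[[i]][sel[2]]), lev)
    if (is.na(r) || is.na(cc)) stop("malformed grid label: ", labels[i])
    out[r, cc] <- out[r, cc] + populations[i]
  }
  out
}

#' Percent antiperiplanar score
#'
#' Sum of the populations of the conformations in which a given atom pair
#' is antiperiplanar, expressed as a percentage.
#'
#' @param populations numeric population vector (or a
#'   \linkS4class{PopulationResult}).
#' @param app logical vector: is the pair antiperiplanar in each conformer
#'   (must cover every conformer).
#' @return percentage in [0, 100].
#' @export
percentAntiperiplanar <- function(populations, app) {
  if (is(populations, "PopulationResult")) populations <- populations@p
  if (length(app) != length(populations) || any(is.na(app)))
    stop("geometry map must cover all conformers")
  100 * sum(populations[as.logical(app)])
}

#' Correlate couplings with percent antiperiplanar
#'
#' Ordinary least-squares line through (%app, J) pairs and its coefficient
#' of determination. A strong linear relationship is expected when both the
#' conformational energy and the Karplus curve are flat near the
#' 180-degree dihedral.
#'
#' @param j experimental couplings in Hz.
#' @param app calculated percent-antiperiplanar values.
#' @return list with \code{slope} (Hz per percent), \code{intercept} (Hz),
#'   \code{r.squared} and the underlying \code{lm} fit.
#' @export
correlateJApp <- function(j, app) {
  if (length(j) != length(app)) stop("j and app must have equal length")
  if (length(j) < 3) stop("at least 3 points are required")
  if (stats::sd(app) == 0) stop("degenerate (constant) predictor")
  fit <- stats::lm(j ~ app)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r.squared = summary(fit)$r.squared, fit = fit)
}

#' Conformer table I/O
#'
#' Delimited text with header columns \code{label}, \code{energy_kJmol},
#' \code{degeneracy}, \code{dipole_D} and any number of \code{J_<pair>}
#' columns.
#'
#' @param ensemble a \linkS4class{ConformerEnsemble}.
#' @param path file path.
#' @return \code{readConformerTable}: a \linkS4class{ConformerEnsemble};
#'   \code{writeConformerTable}: \code{path}, invisibly.
#' @export
writeConformerTable <- function(ensemble, path) {
  tab <- data.frame(label = ensemble@labels,
                    energy_kJmol = ensemble@energies,
                    degeneracy = ensemble@degeneracy,
                    dipole_D = ensemble@dipole)
  if (ncol(ensemble@jTable)) {
    jt <- as.data.frame(ensemble@jTable)
    names(jt) <- paste0("J_", colnames(ensemble@jTable))
    tab <- cbind(tab, jt)
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeConformerTable
#' @export
readConformerTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  need <- c("label", "energy_kJmol")
  if (!all(need %in% names(tab)))
    stop("conformer table must have columns ", paste(need, collapse = ", "))
  jcols <- grep("^J_", names(tab), value = TRUE)
  jTable <- NULL
  if (length(jcols)) {
    jTable <- as.matrix(tab[, jcols, drop = FALSE])
    colnames(jTable) <- sub("^J_", "", jcols)
  }
  conformerEnsemble(tab$label, tab$energy_kJmol,
                    degeneracy = tab$degeneracy %||% 1,
                    dipole = tab$dipole_D %||% NA_real_,
                    jTable = jTable)
}
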