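# Central S4 classes. Single-spin operator labels used throughout the state
# space code are integers 0:3 meaning, in order:
#   0 = identity (E / sqrt(2)),  1 = T(1,-1) (I-),  2 = T(1,0) (sqrt(2) Iz),
#   3 = T(1,+1) (I+)
# i.e. irreducible spherical tensors normalised to unit Frobenius norm, so
# that direct products of them form an orthonormal basis of Liouville space.

#' Spin system description
#'
#' Holds the nuclei, chemical shifts, scalar coupling network, magnet field
#' and permutation-symmetry declarations of a spin-1/2 system. All simulation
#' and fitting operations consume this object. Spin order is authoritative:
#' matrices are indexed in the order the spins were declared.
#'
#' @slot isotopes character, one of \code{"1H"}, \code{"19F"} per spin.
#' @slot shifts numeric, chemical shift per spin in ppm.
#' @slot couplings symmetric numeric matrix of scalar couplings in Hz with
#'   zero diagonal.
#' @slot fieldMHz numeric(1), the 1H Larmor frequency of the magnet in MHz.
#' @slot symmetryGroups list of \code{list(spins =, label =)} entries, each a
#'   set of spin indices obeying a full permutation group (e.g. a three-fold
#'   methyl rotor is an S3 group of its three protons).
#' @slot equivalences list of integer vectors declaring molecule-level
#'   chemical equivalence of spins (used for parameter tying during fitting).
#'
#' @export
setClass("SpinSystem", representation(
  isotopes = "character",
  shifts = "numeric",
  couplings = "matrix",
  fieldMHz = "numeric",
  symmetryGroups = "list",
  equivalences = "list"
))

#' Acquisition parameters for a pulse-acquire experiment
#'
#' @slot detect isotope label of the detected nucleus.
#' @slot points integer(1), time-domain points acquired.
#' @slot zerofill integer(1), length after zero filling (>= points).
#' @slot sweepPpm numeric(1), spectral width in ppm.
#' @slot centerPpm numeric(1), carrier position in ppm (may be NA, in which
#'   case it is resolved to the mean shift of the detected isotope).
#' @slot lineBroadening numeric(1), exponential apodization rate in Hz (full
#'   width at half height of the resulting Lorentzian).
#'
#' @export
setClass("AcquisitionParams", representation(
  detect = "character",
  points = "integer",
  zerofill = "integer",
  sweepPpm = "numeric",
  centerPpm = "numeric",
  lineBroadening = "numeric"
))

#' Restricted product-operator basis
#'
#' An ordered list of product states over the single-spin operators
#' {identity, T(1,-1), T(1,0), T(1,+1)}, with bookkeeping of every reduction
#' stage that produced it.
#'
#' @slot labels integer matrix (states x spins) with entries 0:3.
#' @slot keys numeric vector of base-4 encodings of the rows of
#'   \code{labels}; used for O(log n) state lookup.
#' @slot isotopes character, per-spin isotope labels of the parent system.
#' @slot provenance data.frame of applied reduction stages and resulting
#'   dimensions (strictly non-increasing).
#'
#' @export
setClass("ProductBasis", representation(
  labels = "matrix",
  keys = "numeric",
  isotopes = "character",
  provenance = "data.frame"
))

#' Symmetry-adapted basis
#'
#' The fully symmetric projection of a \linkS4class{ProductBasis} under the
#' direct product of the declared permutation groups. Rows of the projector
#' are orthonormal orbit averages, so \code{projector \%*\% t(projector)} is
#' the identity on the reduced space.
#'
#' @slot basis the parent \linkS4class{ProductBasis}.
#' @slot projector sparse matrix (reduced x full) mapping product states to
#'   symmetry-adapted combinations.
#' @slot provenance data.frame, cascade bookkeeping including this stage.
#'
#' @export
setClass("SymmetrizedBasis", representation(
  basis = "ProductBasis",
  projector = "Matrix",
  provenance = "data.frame"
))

#' Liouvillian superoperator
#'
#' Sparse matrix representation of the commutation superoperator of the
#' high-field spin Hamiltonian, in rad/s, over a \linkS4class{ProductBasis}
#' or \linkS4class{SymmetrizedBasis}. In the orthonormal spherical-tensor
#' product basis this matrix is real symmetric.
#'
#' @slot matrix sparse real matrix (rad/s).
#' @slot basis the basis the operator acts on.
#' @slot detect isotope whose carrier defines the rotating frame, if any.
#'
#' @export
setClass("Liouvillian", representation(
  matrix = "Matrix",
  basis = "ANY",
  detect = "character"
))

#' Free induction decay
#'
#' @slot samples complex time-domain signal.
#' @slot dwell numeric(1), seconds per point.
#' @slot detect isotope label of the detected nucleus.
#' @slot obsMHz observation frequency in MHz (for the ppm axis).
#' @slot centerPpm carrier position in ppm (for the ppm axis).
#'
#' @export
setClass("Fid", representation(
  samples = "complex",
  dwell = "numeric",
  detect = "character",
  obsMHz = "numeric",
  centerPpm = "numeric"
))

#' Frequency-domain NMR spectrum
#'
#' @slot axisPpm strictly monotone frequency axis in ppm.
#' @slot intensity real absorption-mode intensity.
#' @slot complexIntensity complex spectrum before taking the real part.
#' @slot params the \linkS4class{AcquisitionParams} used.
#'
#' @export
setClass("NMRSpectrum", representation(
  axisPpm = "numeric",
  intensity = "numeric",
  complexIntensity = "complex",
  params = "AcquisitionParams"
))

#' Fit parameter set
#'
#' Chemical shifts, couplings and linewidth together with the tie classes
#' that reduce them to the unique free parameters of a fit.
#'
#' @slot shifts numeric, full-length per-spin shifts in ppm.
#' @slot j full symmetric coupling matrix in Hz.
#' @slot linewidth numeric(1), Lorentzian full width at half height in Hz.
#' @slot shiftClasses list of integer vectors: spins forced to share a shift.
#' @slot jClasses list of two-column index matrices: couplings forced equal.
#' @slot scales per-spectrum intensity scale (nuisance parameters).
#' @slot baselines per-spectrum constant baseline offset.
#'
#' @export
setClass("FitParameters", representation(
  shifts = "numeric",
  j = "matrix",
  linewidth = "numeric",
  shiftClasses = "list",
  jClasses = "list",
  scales = "numeric",
  baselines = "numeric"
))

#' Result of a spectral fit
#'
#' @slot params the best \linkS4class{FitParameters} found.
#' @slot residual numeric(1), final normalised least-squares residual.
#' @slot iterations integer(1), total objective evaluations.
#' @slot restarts data.frame, one row per stability restart (residual and
#'   maximum parameter deviation from the best fit).
#' @slot converged logical flags per declared tolerance.
#' @slot selfConsistency numeric(1), residual recomputed from the reported
#'   parameters (stored so the result is verifiable).
#'
#' @export
setClass("FitResult", representation(
  params = "FitParameters",
  residual = "numeric",
  iterations = "integer",
  restarts = "data.frame",
  converged = "logical",
  selfConsistency = "numeric"
))

#' Conformer ensemble
#'
#' Labels, relative free energies, degeneracies and optional per-conformer
#' properties of a rotamer ensemble. Energies are relative: the minimum is
#' zero by convention.
#'
#' @slot labels character, dihedral descriptor per conformer (alphabet
#'   a / g / g- per position).
#' @slot energies numeric, relative free energies in kJ/mol (min = 0).
#' @slot degeneracy integer, number of degenerate copies per conformer.
#' @slot dipole numeric, dipole moments in Debye (NA when unknown).
#' @slot jTable numeric matrix (conformers x coupling pairs) of three-bond
#'   couplings in Hz; zero columns when absent. Column names identify pairs.
#'
#' @export
setClass("ConformerEnsemble", representation(
  labels = "character",
  energies = "numeric",
  degeneracy = "integer",
  dipole = "numeric",
  jTable = "matrix"
))

#' Boltzmann populations with propagated uncertainty
#'
#' @slot p population per conformer (sums to one).
#' @slot sigmaP propagated standard deviation per conformer.
#' @slot sigmaPBound analytic upper bound on sigmaP per conformer.
#' @slot temperature temperature in K.
#' @slot sigmaE energy standard deviation used, kJ/mol.
#'
#' @export
setClass("PopulationResult", representation(
  p = "numeric",
  sigmaP = "numeric",
  sigmaPBound = "numeric",
  temperature = "numeric",
  sigmaE = "numeric"
))
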