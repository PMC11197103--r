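# Simultaneous least-squares fitting of 1H and 19F spectra. The objective
# simulates both spectra from one parameter set (unique shifts and
# couplings after symmetry tying, one linewidth) and sums normalised
# squared deviations; per-spectrum scale and constant baseline are linear
# nuisance parameters and are profiled out in closed form at every
# evaluation. Minimisation is adaptive Nelder-Mead, with stability
# verified by restarting from perturbed parameter sets.

#' Construct fit parameters from a spin system template
#'
#' @param system a \linkS4class{SpinSystem} providing starting shifts and
#'   couplings (e.g. an initial guess from ensemble-averaged calculations).
#' @param linewidth Lorentzian full width at half height in Hz.
#' @param tieMap parameter-tying map as returned by
#'   \code{\link{validateEquivalence}}; defaults to the map implied by the
#'   system's declared symmetry and equivalences.
#' @param scales per-spectrum intensity scale factors.
#' @param baselines per-spectrum constant baseline offsets.
#' @return a \linkS4class{FitParameters} object.
#' @export
fitParameters <- function(system, linewidth = 0.7,
                          tieMap = validateEquivalence(system),
                          scales = 1, baselines = 0) {
  new("FitParameters", shifts = system@shifts, j = system@couplings,
      linewidth = linewidth, shiftClasses = tieMap$shiftClasses,
      jClasses = tieMap$jClasses, scales = scales, baselines = baselines)
}

setValidity("FitParameters", function(object) {
  if (object@linewidth <= 0) return("linewidth must be positive")
  n <- length(object@shifts)
  if (!all(dim(object@j) == c(n, n))) return("j matrix dimension mismatch")
  if (length(object@shiftClasses) &&
      !setequal(unlist(object@shiftClasses), seq_len(n)))
    return("shiftClasses must partition the spins")
  TRUE
})

setMethod("chemicalShifts", "FitParameters", function(object) object@shifts)
setMethod("jCouplings", "FitParameters", function(object) object@j)

setMethod("show", "FitParameters", function(object) {
  cat(sprintf(
    "FitParameters: %d unique shifts, %d unique couplings, lw %.2f Hz\n",
    length(object@shiftClasses), length(object@jClasses), object@linewidth))
})

# free parameter vector <-> FitParameters
.packFit <- function(fp) {
  c(vapply(fp@shiftClasses, function(cl) fp@shifts[cl[1]], numeric(1)),
    vapply(fp@jClasses, function(m) fp@j[m[1, 1], m[1, 2]], numeric(1)),
    fp@linewidth)
}

.unpackFit <- function(fp, vec) {
  ns <- length(fp@shiftClasses)
  nj <- length(fp@jClasses)
  shifts <- fp@shifts
  for (k in seq_len(ns)) shifts[fp@shiftClasses[[k]]] <- vec[k]
  J <- fp@j
  for (k in seq_len(nj)) {
    m <- fp@jClasses[[k]]
    J[m] <- vec[ns + k]
    J[m[, 2:1, drop = FALSE]] <- vec[ns + k]
  }
  methods::initialize(fp, shifts = shifts, j = J,
                      linewidth = abs(vec[ns + nj + 1]))
}

.fitStep <- function(fp, shiftStep = 0.002, jStep = 0.1, lwStep = 0.05) {
  c(rep(shiftStep, length(fp@shiftClasses)),
    rep(jStep, length(fp@jClasses)), lwStep)
}

# model absorption spectrum for one observed spectrum under fp; the FID
# route (geometric progression per line, then FFT) gives the same numbers
# as the closed-form transform at a fraction of the memory traffic
.modelIntensity <- function(fp, obs, system, carriers) {
  modSys <- methods::initialize(system, shifts = fp@shifts, couplings = fp@j)
  pars <- obs@params
  pars@lineBroadening <- fp@linewidth
  lines <- .lineList(modSys, pars@detect, carriers)
  obsMHz <- .obsFreqMHz(modSys, pars@detect)
  fid <- .fidFromLines(lines, 1 / (pars@sweepPpm * obsMHz), pars@points)
  model <- fidToSpectrum(fid, pars)
  if (length(model@axisPpm) == length(obs@axisPpm) &&
      max(abs(model@axisPpm - obs@axisPpm)) < 1e-9)
    return(model@intensity)
  stats::approx(model@axisPpm, model@intensity, xout = obs@axisPpm,
                rule = 2)$y
}

#' Least-squares residual between simulated and observed spectra
#'
#' Sum over spectra of squared pointwise differences between the scaled
#' simulated absorption spectrum (plus constant baseline) and the observed
#' one, each spectrum normalised by its observed energy so that 1H and 19F
#' contribute comparably.
#'
#' @param params a \linkS4class{FitParameters} set.
#' @param observed a single \linkS4class{NMRSpectrum} or a list of them
#'   (each carrying its acquisition metadata).
#' @param system the \linkS4class{SpinSystem} template (topology, isotopes,
#'   symmetry); its shifts/couplings are overridden by \code{params}.
#' @param carriers named list of carrier positions per isotope; defaults to
#'   the centre positions stored in the observed spectra.
#' @param profile logical: if TRUE, per-spectrum scale and baseline are
#'   replaced by their closed-form least-squares optima; if FALSE the
#'   values stored in \code{params} are used.
#' @return numeric scalar; attribute \code{"perSpectrum"} holds the
#'   normalised residual of each spectrum.
#' @export
spectrumResidual <- function(params, observed, system, carriers = NULL,
                             profile = FALSE) {
  if (is(observed, "NMRSpectrum")) observed <- list(observed)
  if (!length(observed)) stop("at least one observed spectrum is required")
  if (is.null(carriers)) carriers <- .carriersFromObserved(observed, system)
  scales <- rep_len(params@scales, length(observed))
  baselines <- rep_len(params@baselines, length(observed))
  per <- numeric(length(observed))
  for (k in seq_along(observed)) {
    obs <- observed[[k]]
    m <- .modelIntensity(params, obs, system, carriers)
    o <- obs@intensity
    if (profile) {
      sb <- .profileScale(m, o)
      scales[k] <- sb[1]; baselines[k] <- sb[2]
    }
    r <- scales[k] * m + baselines[k] - o
    denom <- sum(o^2)
    per[k] <- if (denom > 0) sum(r^2) / denom else sum(r^2)
  }
  out <- sum(per)
  attr(out, "perSpectrum") <- per
  attr(out, "scales") <- scales
  attr(out, "baselines") <- baselines
  out
}

.profileScale <- function(m, o) {
  n <- length(m)
  sm <- sum(m); so <- sum(o); smm <- sum(m * m); smo <- sum(m * o)
  det <- smm * n - sm * sm
  if (abs(det) < 1e-300) return(c(0, so / n))
  s <- (smo * n - sm * so) / det
  c(s, (so - s * sm) / n)
}

# Extra Lorentzian broadening of an absorption spectrum by FFT-domain
# multiplication with exp(-pi*g*|t|): absorption Lorentzians convolve
# exactly, so this reproduces the spectrum at linewidth lw + g.
.smoothIntensity <- function(intensity, g, hzPerPoint) {
  if (g <= 0) return(intensity)
  m <- length(intensity)
  tIdx <- pmin(0:(m - 1), m - (0:(m - 1))) / (m * hzPerPoint)
  Re(stats::fft(stats::fft(intensity) * exp(-pi * g * tIdx),
                inverse = TRUE)) / m
}

# Fast objective closure over cached line-list contexts. `smooth` adds g Hz
# of Lorentzian broadening to both sides (multi-resolution continuation:
# a broadened error surface has far fewer local minima). Falls back to the
# general (interpolating) residual when an observed axis does not coincide
# with the simulation grid of its own acquisition parameters.
.residualObjective <- function(initial, observed, system, carriers,
                               count = function() NULL, smooth = 0,
                               mode = c("scalar", "vector")) {
  mode <- match.arg(mode)
  carrierPerSpin <- vapply(system@isotopes, function(z)
    carriers[[z]], numeric(1))
  fac <- system@fieldMHz * vapply(system@isotopes, .gammaRatio, numeric(1))
  ctxs <- lapply(observed, function(obs)
    .lineListContext(system, obs@params@detect, carriers))
  gridOk <- vapply(seq_along(observed), function(k) {
    obs <- observed[[k]]
    nz <- obs@params@zerofill
    dwell <- 1 / (obs@params@sweepPpm * ctxs[[k]]$obsMHz)
    axis <- ctxs[[k]]$centerPpm +
      (seq_len(nz) - 1 - floor(nz / 2)) / (nz * dwell) / ctxs[[k]]$obsMHz
    length(axis) == length(obs@axisPpm) &&
      max(abs(axis - obs@axisPpm)) < 1e-9
  }, logical(1))
  if (!all(gridOk)) {
    if (smooth > 0)
      stop("smoothed objective requires spectra on their own simulation grid")
    fall <- function(vec) {
      count()
      as.numeric(spectrumResidual(.unpackFit(initial, vec), observed,
                                  system, carriers, profile = TRUE))
    }
    if (mode == "vector")
      stop("vector residuals require spectra on their own simulation grid")
    return(fall)
  }
  target <- lapply(seq_along(observed), function(k) {
    obs <- observed[[k]]
    hzPerPoint <- obs@params@sweepPpm * ctxs[[k]]$obsMHz / obs@params@zerofill
    .smoothIntensity(obs@intensity, smooth, hzPerPoint)
  })
  oEnergy <- vapply(target, function(o)
    max(sum(o^2), .Machine$double.xmin), numeric(1))
  if (mode == "vector") {
    return(function(vec) {
      count()
      fp <- .unpackFit(initial, vec)
      offsets <- (fp@shifts - carrierPerSpin) * fac
      out <- vector("list", length(observed))
      for (k in seq_along(observed)) {
        obs <- observed[[k]]
        m <- .modelIntensityCtx(ctxs[[k]], offsets, fp@j,
                                fp@linewidth + smooth, obs@params)
        sb <- .profileScale(m, target[[k]])
        out[[k]] <- (sb[1] * m + sb[2] - target[[k]]) / sqrt(oEnergy[k])
      }
      unlist(out)
    })
  }
  function(vec) {
    count()
    fp <- .unpackFit(initial, vec)
    offsets <- (fp@shifts - carrierPerSpin) * fac
    total <- 0
    for (k in seq_along(observed)) {
      obs <- observed[[k]]
      m <- .modelIntensityCtx(ctxs[[k]], offsets, fp@j,
                              fp@linewidth + smooth, obs@params)
      sb <- .profileScale(m, target[[k]])
      r <- sb[1] * m + sb[2] - target[[k]]
      total <- total + sum(r^2) / oEnergy[k]
    }
    total
  }
}

.carriersFromObserved <- function(observed, system) {
  carriers <- .defaultCarriers(system,
    acquisitionParams(detect = observed[[1]]@params@detect,
                      centerPpm = NA_real_))
  for (obs in observed) {
    ctr <- obs@params@centerPpm
    if (!is.na(ctr)) carriers[[obs@params@detect]] <- ctr
  }
  carriers
}

#' Fit chemical shifts and couplings to observed spectra
#'
#' Simultaneous Nelder-Mead least-squares fit of all observed spectra
#' (typically the 1H and the 19F spectrum of one sample: either spectrum
#' alone does not reliably constrain a large strongly coupled parameter
#' set). The minimiser uses adaptive simplex coefficients; convergence is
#' pushed to at least four decimal places in the chemical shifts and two in
#' the couplings, and stability is verified by restarting from randomly
#' perturbed parameter sets and requiring agreement.
#'
#' @param initial \linkS4class{FitParameters} starting point (complete).
#' @param observed list of observed \linkS4class{NMRSpectrum} objects.
#' @param system the \linkS4class{SpinSystem} template.
#' @param restarts number of stability restarts from perturbed parameters.
#' @param perturbJ uniform perturbation half-width for couplings, Hz.
#' @param perturbShift uniform perturbation half-width for shifts, ppm.
#' @param maxEval maximum objective evaluations per minimisation.
#' @param tol relative simplex convergence tolerance.
#' @param seed optional seed making the restart perturbations reproducible.
#' @return a \linkS4class{FitResult}.
#' @export
fitSpectra <- function(initial, observed, system, restarts = 5,
                       perturbJ = 0.2, perturbShift = 0.005,
                       maxEval = 20000, tol = 1e-13, seed = NULL) {
  if (is(observed, "NMRSpectrum")) observed <- list(observed)
  carriers <- .carriersFromObserved(observed, system)
  evals <- 0L
  counter <- function() evals <<- evals + 1L
  obj <- .residualObjective(initial, observed, system, carriers,
                            count = counter)
  objSmooth <- tryCatch(
    .residualObjective(initial, observed, system, carriers,
                       count = counter, smooth = 4),
    error = function(e) NULL)
  objVec <- tryCatch(
    .residualObjective(initial, observed, system, carriers,
                       count = counter, mode = "vector"),
    error = function(e) NULL)
  # Levenberg-Marquardt refinement of a simplex-located optimum: the final
  # approach to the minimum follows a narrow curved valley along which the
  # simplex crawls, while a damped Gauss-Newton step on the full residual
  # vector converges in a handful of iterations
  polish <- function(run) {
    if (is.null(objVec)) return(run)
    lm <- tryCatch(
      minpack.lm::nls.lm(run$xmin, fn = objVec,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 60, ftol = 1e-15, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(lm)) return(run)
    f <- obj(lm$par)
    if (f < run$fmin) list(xmin = lm$par, fmin = f) else run
  }
  step <- .fitStep(initial)
  ns <- length(initial@shiftClasses)
  nj <- length(initial@jClasses)
  d <- ns + nj + 1
  # in high dimension the simplex is applied block-cyclically (shifts +
  # linewidth, then couplings), which converges geometrically where the
  # full-space simplex crawls; each block pass is still plain adaptive
  # Nelder-Mead on the joint least-squares functional
  blocks <- if (d <= 14) list(seq_len(d)) else
    list(c(seq_len(ns), d), ns + seq_len(nj))
  lastMove <- c(shift = Inf, j = Inf)
  minimize <- function(fn, x0, maxCycles, budget, firstStep = 1) {
    x <- x0
    f <- fn(x)
    for (cyc in seq_len(maxCycles)) {
      xprev <- x; fprev <- f
      for (b in blocks) {
        fb <- function(xb) { y <- x; y[b] <- xb; fn(y) }
        r <- pracma::nelder_mead(fb, x[b], tol = tol,
                                 maxfeval = budget,
                                 step = step[b] *
                                   if (cyc > 1) 0.1 else firstStep)
        if (r$fmin < f) { x[b] <- r$xmin; f <- r$fmin }
      }
      move <- abs(x - xprev)
      lastMove <<- c(shift = max(move[seq_len(ns)], 0),
                     j = max(move[ns + seq_len(nj)], 0))
      if ((lastMove["shift"] < 5e-5 && lastMove["j"] < 5e-3 &&
           cyc > 1) || f < 1e-13 || fprev - f < 1e-15)
        break
    }
    list(xmin = x, fmin = f)
  }

  x0 <- .packFit(initial)
  # multi-resolution continuation: locate the basin on a 4 Hz broadened
  # error surface, then refine at the native linewidth
  if (!is.null(objSmooth)) {
    stage <- minimize(objSmooth, x0, maxCycles = 4,
                      budget = min(maxEval, 800), firstStep = 2)
    x0 <- stage$xmin
  }
  best <- polish(minimize(obj, x0, maxCycles = 12,
                          budget = min(maxEval, 1200)))

  runs <- list(best)
  if (restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      xp <- best$xmin
      xp[seq_len(ns)] <- xp[seq_len(ns)] +
        stats::runif(ns, -perturbShift, perturbShift)
      xp[ns + seq_len(nj)] <- xp[ns + seq_len(nj)] +
        stats::runif(nj, -perturbJ, perturbJ)
      runs[[r + 1]] <- polish(minimize(obj, xp, maxCycles = 4,
                                       budget = min(maxEval, 800)))
    }
    fmins <- vapply(runs, `[[`, numeric(1), "fmin")
    best <- runs[[which.min(fmins)]]
  }

  jIdx <- ns + seq_len(nj)
  xs <- do.call(rbind, lapply(runs, `[[`, "xmin"))
  fmins <- vapply(runs, `[[`, numeric(1), "fmin")
  restartTab <- data.frame(
    residual = fmins,
    maxDevJHz = apply(abs(sweep(xs[, jIdx, drop = FALSE], 2,
                                best$xmin[jIdx])), 1, max),
    maxDevShiftPpm = apply(abs(sweep(xs[, seq_len(ns), drop = FALSE], 2,
                                     best$xmin[seq_len(ns)])), 1, max))
  # stability is judged on the runs that actually converged: a restart that
  # merely ran out of budget is not evidence of a second minimum, but an
  # equally good optimum elsewhere in parameter space is
  conv <- fmins <= max(10 * min(fmins), 1e-12)
  maxDevJ <- if (sum(conv) > 1) max(restartTab$maxDevJHz[conv]) else 0

  fp <- .unpackFit(initial, best$xmin)
  final <- spectrumResidual(fp, observed, system, carriers, profile = TRUE)
  fp@scales <- attr(final, "scales")
  fp@baselines <- attr(final, "baselines")
  converged <- c(shifts = unname(lastMove["shift"]) < 1e-4,
                 j = unname(lastMove["j"]) < 1e-2,
                 stable = maxDevJ < 1e-2)
  new("FitResult", params = fp, residual = best$fmin,
      iterations = evals, restarts = restartTab, converged = converged,
      selfConsistency = as.numeric(final))
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult: residual %.3e after %d evaluations (%d restarts)\n",
    object@residual, object@iterations, nrow(object@restarts) - 1))
  cat(sprintf("  stable: %s; max restart deviation %.4f Hz in J\n",
              all(object@converged), max(object@restarts$maxDevJHz)))
})

#' Validate a fit against a decoupled spectrum
#'
#' Simulates the decoupled spectrum implied by the fitted parameters
#' (heteronuclear couplings to the decoupled isotope zeroed) and reports
#' the normalised residual against an observed decoupled spectrum; complete
#' agreement confirms the fitted parameter assignment.
#'
#' @param fit a \linkS4class{FitResult}.
#' @param observed the observed decoupled \linkS4class{NMRSpectrum}.
#' @param system the \linkS4class{SpinSystem} template.
#' @param decouple isotope that was decoupled during acquisition.
#' @param threshold normalised residual above which agreement is rejected.
#' @return list with \code{residual}, \code{agrees} and the simulated
#'   spectrum.
#' @export
validateByDecoupling <- function(fit, observed, system, decouple = "19F",
                                 threshold = 1e-3) {
  if (missing(observed) || is.null(observed))
    stop("decoupled observation is required")
  fp <- fit@params
  modSys <- methods::initialize(system, shifts = fp@shifts, couplings = fp@j)
  modSys <- .decoupleSystem(modSys, decouple)
  carriers <- .carriersFromObserved(list(observed), modSys)
  pars <- observed@params
  pars@lineBroadening <- fp@linewidth
  lines <- .lineList(modSys, pars@detect, carriers)
  model <- .spectrumFromLines(lines, pars)
  m <- if (length(model@axisPpm) == length(observed@axisPpm) &&
           max(abs(model@axisPpm - observed@axisPpm)) < 1e-9)
    model@intensity else stats::approx(model@axisPpm, model@intensity,
                                       xout = observed@axisPpm, rule = 2)$y
  sb <- .profileScale(m, observed@intensity)
  r <- sb[1] * m + sb[2] - observed@intensity
  resid <- sum(r^2) / max(sum(observed@intensity^2), .Machine$double.xmin)
  list(residual = resid, agrees = resid < threshold, simulated = model)
}
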