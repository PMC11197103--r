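test_that("residual is numerically zero at the generating truth", {
  case <- makeSyntheticCase(4, "strong", seed = 21)
  r <- spectrumResidual(case$truth, unname(case$spectra), case$system,
                        profile = TRUE)
  expect_lt(as.numeric(r), 1e-18)
})

test_that("unit-scale residual against a zero spectrum is the model energy", {
  case <- makeSyntheticCase(3, "strong", seed = 22)
  zero <- case$spectra[[1]]
  zero@intensity <- zero@intensity * 0
  r <- spectrumResidual(case$truth, zero, case$system, profile = FALSE)
  m <- fluorspin:::.modelIntensity(
    case$truth, case$spectra[[1]], case$system,
    fluorspin:::.carriersFromObserved(unname(case$spectra), case$system))
  expect_equal(as.numeric(r), sum(m^2), tolerance = 1e-10)
})

test_that("a perturbed initial guess produces a dissimilar spectrum", {
  case <- makeSyntheticCase(4, "strong", seed = 23)
  guess <- perturbParameters(case$truth, 0.5, 0.01, seed = 1)
  r <- spectrumResidual(guess, unname(case$spectra), case$system,
                        profile = TRUE)
  # normalised residual of order one: essentially no overlap with the truth
  expect_gt(as.numeric(r), 0.1)
})

test_that("simultaneous fitting recovers the truth from a perturbed guess", {
  case <- makeSyntheticCase(4, "strong", seed = 24)
  guess <- perturbParameters(case$truth, 0.5, 0.01, seed = 2)
  fit <- fitSpectra(guess, unname(case$spectra), case$system, restarts = 2,
                    seed = 3)
  expect_lt(max(abs(fit@params@j - case$truth@j)), 0.1)
  expect_lt(max(abs(fit@params@shifts - case$truth@shifts)), 1e-3)
  expect_true(all(fit@converged))
  # restart stability: every converged restart agrees with the best fit
  conv <- fit@restarts$residual <= 10 * min(fit@restarts$residual)
  expect_lt(max(fit@restarts$maxDevJHz[conv]), 0.01)
  # stored parameters reproduce the reported residual
  expect_equal(fit@selfConsistency, fit@residual, tolerance = 1e-6)
})

test_that("an exact initial guess is returned unchanged", {
  case <- makeSyntheticCase(3, "strong", seed = 25)
  fit <- fitSpectra(case$truth, unname(case$spectra), case$system,
                    restarts = 1, seed = 4)
  expect_lt(max(abs(fit@params@j - case$truth@j)), 1e-3)
  expect_lt(fit@residual, 1e-13)
  expect_true(unname(fit@converged["stable"]))
})

test_that("one nucleus alone under-determines what both nuclei resolve", {
  # two inequivalent fluorines seen by protons only through secular IzIz
  # couplings: exchanging the full F1/F2 coupling vectors leaves the 1H
  # spectrum unchanged but alters the 19F spectrum, so a proton-only fit
  # cannot distinguish the two assignments
  sys <- mixedSystem5()
  sh <- chemicalShifts(sys); sh[5] <- -180.05
  sys <- spinSystem(isotopes(sys), sh, jCouplings(sys))
  swapped <- jCouplings(sys)
  swapped[1:3, 4:5] <- swapped[1:3, 5:4]
  swapped[4:5, 1:3] <- t(swapped[1:3, 4:5])
  truth <- fitParameters(sys, linewidth = 0.8)
  alt <- truth; alt@j <- swapped
  mkspec <- function(det) {
    carrier <- mean(sh[isotopes(sys) == det])
    pars <- acquisitionParams(det, points = 1024, zerofill = 2048,
                              sweepPpm = 220 / (500 * if (det == "1H") 1 else
                                0.94094011),
                              centerPpm = carrier, lineBroadening = 0.8)
    lines <- fluorspin:::.lineList(sys, det,
                                   list("1H" = mean(sh[1:3]),
                                        "19F" = mean(sh[4:5])))
    fluorspin:::.spectrumFromLines(lines, pars)
  }
  obsH <- mkspec("1H"); obsF <- mkspec("19F")
  rH <- as.numeric(spectrumResidual(alt, obsH, sys, profile = TRUE))
  rBoth <- as.numeric(spectrumResidual(alt, list(obsH, obsF), sys,
                                       profile = TRUE))
  expect_lt(rH, 1e-16)          # degenerate for the proton spectrum alone
  expect_gt(rBoth, 1e-3)        # resolved once 19F joins the objective
})

test_that("decoupled-spectrum validation accepts truth and rejects swaps", {
  case <- makeSyntheticCase(4, "strong", seed = 26)
  sys <- case$system
  dec <- fluorspin:::.decoupleSystem(sys, "19F")
  pars <- case$spectra[["1H"]]@params
  lines <- fluorspin:::.lineList(dec, "1H",
    fluorspin:::.carriersFromObserved(unname(case$spectra), sys))
  obsDec <- fluorspin:::.spectrumFromLines(lines, pars)
  fitTruth <- new("FitResult", params = case$truth, residual = 0,
                  iterations = 0L, restarts = data.frame(),
                  converged = c(shifts = TRUE, j = TRUE, stable = TRUE),
                  selfConsistency = 0)
  rep1 <- validateByDecoupling(fitTruth, obsDec, sys, decouple = "19F")
  expect_lt(rep1$residual, 1e-18)
  expect_true(rep1$agrees)
  # swap two H-H couplings: the decoupled proton spectrum must disagree
  wrong <- case$truth
  jw <- wrong@j
  jw[1, 2] <- case$truth@j[1, 3]; jw[2, 1] <- jw[1, 2]
  jw[1, 3] <- case$truth@j[1, 2]; jw[3, 1] <- jw[1, 3]
  wrong@j <- jw
  fitWrong <- fitTruth; fitWrong@params <- wrong
  rep2 <- validateByDecoupling(fitWrong, obsDec, sys, decouple = "19F")
  expect_false(rep2$agrees)
  expect_error(validateByDecoupling(fitTruth, NULL, sys), "required")
})

test_that("recovery study medians meet the noiseless precision target", {
  st <- recoveryStudyCached()
  expect_equal(nrow(st), 20)
  expect_lt(median(st$maxJErrHz), 0.02)
  expect_lt(max(st$maxJErrHz), 0.1)
})
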