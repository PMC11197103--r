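test_that("Liouvillian action matches the dense Hilbert commutator oracle", {
  sys <- spinSystem(c("1H", "1H", "19F"), c(1.00, 1.02, -180),
                    {J <- matrix(0, 3, 3)
                     J[1, 2] <- J[2, 1] <- 9
                     J[1, 3] <- J[3, 1] <- 46; J[2, 3] <- J[3, 2] <- 14; J})
  carriers <- list("1H" = 1.01, "19F" = -180)
  basis <- buildBasis(sys, 3)
  L <- buildLiouvillian(sys, basis, carriers)
  offsets <- (chemicalShifts(sys) - c(1.01, 1.01, -180)) *
    sys@fieldMHz * c(1, 1, 0.94094011)
  H <- denseHOracle(offsets, jCouplings(sys), isotopes(sys))
  set.seed(7)
  for (rep in 1:3) {
    v <- complex(real = rnorm(dimension(basis)),
                 imaginary = rnorm(dimension(basis)))
    # map v to a dense operator, commute, map back
    M <- Reduce(`+`, lapply(seq_along(v), function(s)
      v[s] * denseBasisState(basis@labels[s, ])))
    C <- H %*% M - M %*% H
    oracle <- vapply(seq_along(v), function(s)
      sum(Conj(denseBasisState(basis@labels[s, ])) * C), complex(1))
    lv <- as.vector(L@matrix %*% Re(v)) + 1i * as.vector(L@matrix %*% Im(v))
    expect_lt(max(abs(lv - oracle)) / max(abs(oracle)), 1e-10)
  }
})

test_that("single uncoupled spin: eigenfrequency and analytic FID", {
  s1 <- spinSystem("1H", 1, matrix(0, 1, 1))
  b1 <- buildBasis(s1, 1)
  L1 <- buildLiouvillian(s1, b1, carriers = list("1H" = 0))
  nu <- 500  # Hz at 1 ppm off a 0-ppm carrier on a 500 MHz magnet
  idx <- which(b1@labels[, 1] == 3L)
  v <- numeric(4); v[idx] <- 1
  expect_equal(as.vector(L1@matrix %*% v)[idx], 2 * pi * nu, tolerance = 1e-12)
  fid <- propagate(L1, initialState(s1, b1, "1H"), dwell = 1e-4, nSteps = 64)
  tg <- (0:63) * 1e-4
  expect_lt(max(abs(fid@samples - exp(-2i * pi * nu * tg))), 1e-9)
})

test_that("zero Liouvillian gives a constant FID and norms are conserved", {
  s1 <- spinSystem("1H", 0, matrix(0, 1, 1))   # on resonance, no coupling
  b1 <- buildBasis(s1, 1)
  L0 <- buildLiouvillian(s1, b1, carriers = list("1H" = 0))
  fid <- propagate(L0, initialState(s1, b1, "1H"), 1e-3, 16)
  expect_equal(unique(round(Re(fid@samples), 12)), 1)
  sys <- mixedSystem5()
  basis <- filterCoherence(buildBasis(sys, 5), 1L, 1:3)
  L <- buildLiouvillian(sys, basis, list("1H" = 2.0, "19F" = -180))
  v <- initialState(sys, basis, "1H")
  v2 <- fluorspin:::.expmv(L@matrix, v, 0.05)
  expect_equal(sqrt(sum(abs(v2)^2)), sqrt(sum(abs(v)^2)), tolerance = 1e-9)
})

test_that("initial state lives on the detected isotope with norm sqrt(count)", {
  sys <- mixedSystem5()
  basis <- buildBasis(sys, 5)
  vH <- initialState(sys, basis, "1H")
  vF <- initialState(sys, basis, "19F")
  expect_equal(sqrt(sum(abs(vH)^2)), sqrt(3))
  expect_equal(sqrt(sum(abs(vF)^2)), sqrt(2))
  onF <- which(abs(vF) > 0)
  spins <- apply(basis@labels[onF, , drop = FALSE] != 0, 1, which)
  expect_true(all(isotopes(sys)[spins] == "19F"))
  expect_error(initialState(sys, basis, "13C"), "absent")
})

test_that("weak-coupling AX pair gives the first-order doublet frequencies", {
  ax <- spinSystem(c("1H", "1H"), c(0.0, 2.0), matrix(c(0, 10, 10, 0), 2))
  lines <- fluorspin:::.lineList(ax, "1H", list("1H" = 1.0))
  expect_equal(sort(lines$freqHz), c(-505, -495, 495, 505), tolerance = 1e-2)
})

test_that("AB pair reproduces the closed-form quartet with roof effect", {
  # 20 Hz shift difference, J = 10 Hz at 500 MHz
  ab <- spinSystem(c("1H", "1H"), c(2.00, 2.04), matrix(c(0, 10, 10, 0), 2))
  lines <- fluorspin:::.lineList(ab, "1H", list("1H" = 2.02))
  o <- order(lines$freqHz)
  expected <- c(-(sqrt(500) + 10) / 2, -(sqrt(500) - 10) / 2,
                (sqrt(500) - 10) / 2, (sqrt(500) + 10) / 2)
  expect_equal(lines$freqHz[o], expected, tolerance = 1e-9)
  a <- lines$amplitude[o]
  expect_gt(a[2], a[1]); expect_gt(a[3], a[4])  # inner lines taller
})

test_that("FID transform: peak position, Parseval, zerofill guard", {
  s1 <- spinSystem("1H", 3.0, matrix(0, 1, 1))
  p1 <- acquisitionParams("1H", points = 1024, zerofill = 2048,
                          sweepPpm = 2, centerPpm = 3.2, lineBroadening = 1)
  sp <- simulateSpectrum(s1, p1, method = "hilbert")
  expect_equal(sp@axisPpm[which.max(sp@intensity)], 3.0,
               tolerance = 2 * 2 / 2048)
  sys <- mixedSystem5()
  pars <- acquisitionParams("1H", points = 256, zerofill = 256,
                            sweepPpm = 0.6, centerPpm = 2.02,
                            lineBroadening = 0)
  fid <- denseOracleFid(sys, pars)
  spp <- fidToSpectrum(fid, pars)
  expect_equal(sum(abs(fid@samples)^2),
               sum(abs(spp@complexIntensity)^2) / 256, tolerance = 1e-10)
  bad <- pars; bad@zerofill <- 128L
  expect_error(fidToSpectrum(fid, bad), "zerofill")
})

test_that("restricted Liouville engine matches the dense oracle FID", {
  sys <- mixedSystem5()
  pars <- acquisitionParams("1H", points = 256, zerofill = 512,
                            sweepPpm = 0.6, centerPpm = 2.02,
                            lineBroadening = 1)
  carriers <- fluorspin:::.defaultCarriers(sys, pars)
  fidD <- denseOracleFid(sys, pars, carriers)
  basis <- buildBasis(sys, 5)
  basis <- filterCoherence(basis, 1L, 1:3)
  basis <- filterLongitudinal(basis, 4:5)
  L <- buildLiouvillian(sys, basis, carriers, "1H")
  fidL <- propagate(L, initialState(sys, basis, "1H"), fidD@dwell, 256,
                    obsMHz = fidD@obsMHz, centerPpm = fidD@centerPpm)
  expect_lt(max(abs(fidD@samples - fidL@samples)), 1e-8)
})

test_that("decoupling collapses heteronuclear splittings to a singlet", {
  hf <- spinSystem(c("1H", "19F"), c(4.5, -180), 48)
  pars <- acquisitionParams("1H", points = 512, zerofill = 1024,
                            sweepPpm = 0.5, centerPpm = 4.5,
                            lineBroadening = 1)
  doublet <- simulateSpectrum(hf, pars, method = "hilbert")
  singlet <- simulateSpectrum(hf, pars, method = "hilbert", decouple = "19F")
  nPeaks <- function(sp) {
    y <- sp@intensity
    sum(y > 0.3 * max(y) & y > c(y[-1], 0) & y >= c(0, y[-length(y)]))
  }
  expect_equal(nPeaks(doublet), 2)
  expect_equal(nPeaks(singlet), 1)
})

test_that("spectra are invariant under relabeling of equivalent spins", {
  sys <- mixedSystem5()
  # swap the two fluorines (equal shifts up to 0.02 ppm -> give them equal
  # shifts and swap their coupling vectors)
  sh <- chemicalShifts(sys); sh[4:5] <- -180
  J <- jCouplings(sys)
  perm <- c(1, 2, 3, 5, 4)
  sysA <- spinSystem(isotopes(sys), sh, J)
  sysB <- spinSystem(isotopes(sys)[perm], sh[perm], J[perm, perm])
  pars <- acquisitionParams("1H", points = 256, zerofill = 512,
                            sweepPpm = 0.6, centerPpm = 2.02,
                            lineBroadening = 1)
  spA <- simulateSpectrum(sysA, pars, method = "liouville", filters = TRUE)
  spB <- simulateSpectrum(sysB, pars, method = "liouville", filters = TRUE)
  expect_lt(relSpecDev(spA@intensity, spB@intensity), 1e-10)
})

test_that("restricted spectra converge monotonically to the dense answer", {
  set.seed(42)
  J <- matrix(0, 4, 4)
  J[upper.tri(J)] <- runif(6, 4, 14); J <- J + t(J)
  sys <- spinSystem(rep("1H", 4), c(1.000, 1.012, 1.026, 1.045), J)
  pars <- acquisitionParams("1H", points = 256, zerofill = 512,
                            sweepPpm = 0.4, centerPpm = 1.02,
                            lineBroadening = 1)
  dense <- simulateSpectrum(sys, pars, method = "hilbert")
  devs <- vapply(2:4, function(k) {
    sp <- simulateSpectrum(sys, pars, maxOrder = k, method = "liouville")
    relSpecDev(sp@intensity, dense@intensity)
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-12))
  expect_lt(devs[3], 1e-6)  # full order: engine-precision agreement
})

test_that("correlation-order trajectory behaves like unitary evolution", {
  s1 <- spinSystem("1H", 1, matrix(0, 1, 1))
  p <- acquisitionParams("1H", points = 32, zerofill = 32, sweepPpm = 2,
                         centerPpm = 0)
  tr <- correlationOrderTrajectory(s1, p, 1)
  expect_equal(unname(tr[, 1]), rep(1, 32), tolerance = 1e-9)
  ax <- spinSystem(c("1H", "1H"), c(0, 2), matrix(c(0, 10, 10, 0), 2))
  p2 <- acquisitionParams("1H", points = 64, zerofill = 64, sweepPpm = 3,
                          centerPpm = 1)
  tr2 <- correlationOrderTrajectory(ax, p2, 2)
  total <- sqrt(rowSums(tr2^2))
  expect_equal(unname(total), rep(total[1], 64), tolerance = 1e-8)
  expect_gt(max(tr2[, 2]), 0.1)   # two-spin order genuinely populated
})

test_that("19F multiplet of the difluoroheptane fixture lacks mirror symmetry", {
  sys <- exampleSystem("difluoroheptane")
  pars <- acquisitionParams("19F", points = 1024, zerofill = 2048,
                            sweepPpm = 0.6, centerPpm = -184.5,
                            lineBroadening = 1)
  sp <- simulateSpectrum(sys, pars, maxOrder = 3, connectivity = TRUE,
                         longitudinal = "strict", symmetry = FALSE)
  y <- sp@intensity / max(sp@intensity)
  centroid <- sum(seq_along(y) * y) / sum(y)
  mirrored <- approx(2 * centroid - seq_along(y), y, xout = seq_along(y),
                     rule = 2)$y
  asym <- sqrt(sum((y - mirrored)^2) / sum(y^2))
  expect_gt(asym, 0.01)
})
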