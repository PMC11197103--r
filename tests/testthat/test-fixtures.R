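test_that("Karplus evaluation follows the three-term cosine form", {
  cv <- karplusCurve(9.5, 0, 1.6)
  expect_equal(karplusJ(cv, 90), 1.6, tolerance = 1e-12)
  cv2 <- karplusCurve(9.5, -1.4, 1.6)
  expect_equal(karplusJ(cv2, 0), 9.5 - 1.4 + 1.6, tolerance = 1e-12)
  th <- seq(-180, 180, 15)
  expect_equal(karplusJ(cv2, th), karplusJ(cv2, -th), tolerance = 1e-12)
  # fixtures use physically sensible sets: J(180) > J(60)
  for (cv in fluorspin:::.defaultKarplus)
    expect_gt(karplusJ(cv, 180), karplusJ(cv, 60))
})

test_that("dihedral sampling is seed-reproducible and screens clashes", {
  off <- rotamerModel(4, clashMin = NA)
  s <- sampleDihedrals(off, 200, seed = 5)
  expect_equal(s$survival, 1)
  impossible <- rotamerModel(4, clashMin = 1e3)
  expect_equal(sampleDihedrals(impossible, 100, seed = 5)$survival, 0)
  model <- rotamerModel(4)
  a <- sampleDihedrals(model, 500, seed = 6)
  b <- sampleDihedrals(model, 500, seed = 6)
  expect_identical(a$theta, b$theta)
  expect_identical(a$survived, b$survived)
  # survival fraction is a stable Monte-Carlo estimate across seeds
  surv <- vapply(1:3, function(sd)
    sampleDihedrals(model, 4000, seed = sd)$survival, numeric(1))
  expect_lt(max(surv) - min(surv), 0.04)
  expect_gt(mean(surv), 0.1); expect_lt(mean(surv), 0.9)
})

test_that("truth ensembles average correctly in the analytic limits", {
  # single accessible well: the average is that well's J
  single <- rotamerModel(1, wellEnergies = c(0, 500, 500))
  ens1 <- buildTruthEnsemble(single, .defaultKarplus["HH"], pairs = 1L)
  hh <- fluorspin:::.defaultKarplus$HH
  expect_equal(unname(attr(ens1, "truthAverages")["HH"]),
               karplusJ(hh, 180), tolerance = 1e-6)
  # symmetric double well at equal energy: mean of the two J values
  double <- rotamerModel(1, wellEnergies = c(500, 0, 0))
  ens2 <- buildTruthEnsemble(double, .defaultKarplus["HH"], pairs = 1L)
  expect_equal(unname(attr(ens2, "truthAverages")["HH"]),
               mean(karplusJ(hh, c(60, -60))), tolerance = 1e-6)
})

test_that("grid and Monte-Carlo thermal averages agree within 3 standard errors", {
  model <- rotamerModel(1, wellEnergies = c(0, 2.0, 3.5))
  hh <- fluorspin:::.defaultKarplus$HH
  grid <- continuousAverageJ(model, hh, method = "grid", n = 20000)
  mc <- continuousAverageJ(model, hh, method = "mc", n = 20000, seed = 8)
  expect_lt(abs(grid - mc$mean), 3 * mc$se)
})

test_that("synthetic cases are deterministic under their seed", {
  a <- makeSyntheticCase(4, "strong", seed = 41)
  b <- makeSyntheticCase(4, "strong", seed = 41)
  expect_identical(a$spectra[["1H"]]@intensity, b$spectra[["1H"]]@intensity)
  expect_identical(jCouplings(a$system), jCouplings(b$system))
  c3 <- makeSyntheticCase(4, "strong", seed = 42)
  expect_false(identical(jCouplings(a$system), jCouplings(c3$system)))
})

test_that("weak-coupling control shows first-order multiplets", {
  weak <- makeSyntheticCase(3, "weak", seed = 43)
  # 2 protons, 1 fluorine: each 1H is a doublet of doublets -> 8 lines of
  # equal intensity (multiplet counting oracle)
  lines <- fluorspin:::.lineList(
    weak$system, "1H",
    fluorspin:::.carriersFromObserved(unname(weak$spectra), weak$system))
  main <- lines$amplitude > 0.01 * max(lines$amplitude)
  expect_equal(sum(main), 8)
  # near-equal intensities (residual roof effect from the weak H-H mixing)
  expect_lt(diff(range(lines$amplitude[main])) / max(lines$amplitude), 0.15)
})

test_that("strong-coupling cases have mirror-asymmetric 19F multiplets", {
  strong <- makeSyntheticCase(6, "strong", seed = 44)
  y <- strong$spectra[["19F"]]@intensity
  y <- y / max(y)
  centroid <- sum(seq_along(y) * y) / sum(y)
  mirrored <- approx(2 * centroid - seq_along(y), y, xout = seq_along(y),
                     rule = 2)$y
  expect_gt(sqrt(sum((y - mirrored)^2) / sum(y^2)), 0.01)
})

test_that("noisy spectra carry the requested signal-to-noise", {
  noisy <- makeSyntheticCase(3, "strong", seed = 45, snr = 50)
  expect_false(is.null(noisy$noisy))
  resid <- noisy$noisy[["1H"]]@intensity - noisy$spectra[["1H"]]@intensity
  expect_equal(sd(resid), max(noisy$spectra[["1H"]]@intensity) / 50,
               tolerance = 0.1)
})

test_that("the fixture writer emits a complete, reloadable set", {
  outDir <- withr::local_tempdir()
  manifest <- makeFixtures(outDir, seed = 3)
  expect_true(file.exists(file.path(outDir, "difluoroheptane.yaml")))
  sys <- readSpinSystem(file.path(outDir, "synthetic-case.yaml"))
  expect_gte(nSpins(sys), 2)
  ens <- readConformerTable(file.path(outDir, "rotamer-table.tsv"))
  expect_equal(length(ens@labels), 9)
  sp <- readSpectrumText(file.path(outDir, "synthetic-H.tsv"))
  expect_gt(max(sp@intensity), 0)
})
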