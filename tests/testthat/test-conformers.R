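RT298 <- 8.314462618e-3 * 298

test_that("Boltzmann populations: limits, degeneracy and gauge invariance", {
  two <- conformerEnsemble(c("a", "g"), c(0, 0))
  expect_equal(populations(boltzmannPopulations(two)), c(0.5, 0.5))
  far <- conformerEnsemble(c("a", "g"), c(0, 500))
  expect_equal(populations(boltzmannPopulations(far)), c(1, 0),
               tolerance = 1e-12)
  # 0.9 kJ/mol gap at 298 K: closed-form ratio exp(-dE/RT)
  gap <- conformerEnsemble(c("a", "g"), c(0, 0.9))
  p <- populations(boltzmannPopulations(gap, 298))
  expect_equal(p[2] / p[1], exp(-0.9 / RT298), tolerance = 1e-12)
  # degeneracy multiplies the weight
  dg <- conformerEnsemble(c("a", "g"), c(0, 0), degeneracy = c(1, 2))
  expect_equal(populations(boltzmannPopulations(dg)), c(1, 2) / 3)
  # uniform energy shift is removed by the relative-energy convention
  shifted <- conformerEnsemble(c("a", "g"), c(5, 5.9))
  expect_equal(populations(boltzmannPopulations(shifted, 298)), p)
  expect_error(boltzmannPopulations(two, -1), "temperature")
})

test_that("population sums and label validation hold", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(2:10, 1)
    ens <- conformerEnsemble(
      replicate(k, paste(sample(c("a", "g", "g-"), 2, TRUE), collapse = "")),
      runif(k, 0, 8), degeneracy = sample(1:4, k, TRUE))
    expect_equal(sum(populations(boltzmannPopulations(ens))), 1,
                 tolerance = 1e-12)
  }
  expect_error(conformerEnsemble("ax", 0), "label")
  expect_error(conformerEnsemble(c("a", "gg"), c(0, 1)), "same number")
})

test_that("analytic sigma_p matches the Monte-Carlo perturbation oracle", {
  expect_equal(populationUncertainty(conformerEnsemble("a", 0))@sigmaP, 0)
  ens0 <- conformerEnsemble(c("a", "g", "g-"), c(0, 1, 2))
  expect_equal(populationUncertainty(ens0, sigmaE = 0)@sigmaP, rep(0, 3))

  pr <- populationUncertainty(ens0, 298, sigmaE = 0.42)
  mc <- mcSigmaP(ens0@energies, ens0@degeneracy, 298, 0.42,
                 nSamples = 1e5, seed = 11)
  expect_lt(max(abs(pr@sigmaP - mc) / mc), 0.05)

  set.seed(32)
  for (rep in 1:4) {
    k <- sample(3:8, 1)
    ens <- conformerEnsemble(
      paste0(sample(c("a", "g", "g-"), k, TRUE),
             sample(c("a", "g", "g-"), k, TRUE)),
      runif(k, 0, 6), degeneracy = sample(1:2, k, TRUE))
    pr <- populationUncertainty(ens, 298, sigmaE = 0.42)
    mc <- mcSigmaP(ens@energies, ens@degeneracy, 298, 0.42,
                   nSamples = 1e5, seed = rep)
    expect_lt(max(abs(pr@sigmaP - mc) / pmax(mc, 1e-6)), 0.05)
    # the convenient bound dominates the full first-order expression
    expect_true(all(pr@sigmaPBound >= pr@sigmaP - 1e-12))
  }
  expect_error(populationUncertainty(ens0, sigmaE = -1), "sigmaE")
})

test_that("ensemble J averaging matches direct summation and is bounded", {
  eq <- conformerEnsemble(c("a", "g"), c(0, 0),
                          jTable = cbind(HH = c(0, 10)))
  expect_equal(ensembleAverageJ(eq, 298, "HH"), 5)
  dom <- conformerEnsemble(c("a", "g"), c(0, 60),
                           jTable = cbind(HH = c(9.8, 1.2)))
  expect_equal(ensembleAverageJ(dom, 298, "HH"), 9.8, tolerance = 1e-6)
  # synthetic rotamer set vs independent weighted sum
  model <- rotamerModel(3, wellEnergies = c(0, 2.5, 3.5))
  ens <- buildTruthEnsemble(model, .defaultKarplus, pairs = c(1L, 2L))
  for (pair in colnames(ens@jTable)) {
    w <- ens@degeneracy * exp(-ens@energies / RT298)
    oracle <- sum(w * ens@jTable[, pair]) / sum(w)
    expect_equal(ensembleAverageJ(ens, 298, pair), oracle, tolerance = 1e-12)
    expect_gte(ensembleAverageJ(ens, 298, pair), min(ens@jTable[, pair]))
    expect_lte(ensembleAverageJ(ens, 298, pair), max(ens@jTable[, pair]))
  }
  expect_error(ensembleAverageJ(eq, 298, "HF"), "no J values")
})

test_that("staggered enumeration gives 3^n conformers", {
  expect_length(enumerateStaggered(1)@labels, 3)
  expect_length(enumerateStaggered(2)@labels, 9)
  expect_length(enumerateStaggered(4)@labels, 81)
  expect_false(anyDuplicated(enumerateStaggered(4)@labels) > 0)
  expect_error(enumerateStaggered(0), "nDihedrals")
})

test_that("grid condensation preserves totals and matches direct sums", {
  ens <- enumerateStaggered(4)
  uniform <- setNames(rep(1 / 81, 81), ens@labels)
  inner <- condenseGrid(uniform, "inner")
  expect_equal(unname(inner), matrix(1 / 9, 3, 3), tolerance = 1e-12)
  onehot <- setNames(numeric(81), ens@labels)
  onehot[["ag-ga"]] <- 1
  outer <- condenseGrid(onehot, "outer")
  expect_equal(sum(outer), 1)
  expect_equal(unname(outer["a", "a"]), 1)   # outer dihedrals are a...a
  inner1 <- condenseGrid(onehot, "inner")
  expect_equal(unname(inner1["g-", "g"]), 1)
  # random populations: marginals agree with a direct summation oracle
  set.seed(33)
  p <- runif(81); p <- p / sum(p); names(p) <- ens@labels
  for (axis in c("inner", "outer")) {
    g <- condenseGrid(p, axis)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    sel <- if (axis == "inner") c(2, 3) else c(1, 4)
    tok <- t(vapply(ens@labels, fluorspin:::.tokenizeLabel, character(4)))
    for (u in c("a", "g", "g-")) for (v in c("a", "g", "g-"))
      expect_equal(unname(g[u, v]),
                   sum(p[tok[, sel[1]] == u & tok[, sel[2]] == v]),
                   tolerance = 1e-12)
  }
})

test_that("percent antiperiplanar sums the right populations", {
  expect_equal(percentAntiperiplanar(c(0.25, 0.75), c(TRUE, TRUE)), 100)
  expect_equal(percentAntiperiplanar(c(0.25, 0.75), c(FALSE, FALSE)), 0)
  expect_equal(percentAntiperiplanar(c(0.7, 0.3), c(TRUE, FALSE)), 70)
  expect_error(percentAntiperiplanar(c(0.5, 0.5), c(TRUE, NA)), "cover")
  expect_error(percentAntiperiplanar(c(0.5, 0.5), TRUE), "cover")
})

test_that("J vs %app correlation behaves like ordinary least squares", {
  app <- c(10, 30, 50, 70, 92)
  j <- 2 + 0.08 * app
  r <- suppressWarnings(correlateJApp(j, app))   # lm warns on a perfect fit
  expect_equal(r$r.squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 0.08, tolerance = 1e-10)
  expect_equal(r$intercept, 2, tolerance = 1e-8)
  set.seed(34)
  jn <- j + rnorm(5, 0, 0.3)
  rn <- correlateJApp(jn, app)
  worst <- max(replicate(50, correlateJApp(sample(jn), app)$r.squared))
  expect_gt(rn$r.squared, 0.9)
  expect_lt(mean(replicate(200, correlateJApp(sample(jn), app)$r.squared)),
            rn$r.squared)
  expect_error(correlateJApp(j[1:2], app[1:2]), "3 points")
  expect_error(correlateJApp(j, rep(50, 5)), "degenerate")
})

test_that("conformer tables round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  model <- rotamerModel(2, wellEnergies = c(0, 2.5, 3.0))
  ens <- buildTruthEnsemble(model, .defaultKarplus, pairs = c(1L, 2L))
  writeConformerTable(ens, path)
  back <- readConformerTable(path)
  expect_equal(back@labels, ens@labels)
  expect_equal(back@energies, ens@energies, tolerance = 1e-9)
  expect_equal(back@jTable, ens@jTable, tolerance = 1e-9)
})
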