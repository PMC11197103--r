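twoSpin <- spinSystem(c("1H", "19F"), c(4.5, -180), 48)

test_that("basis enumeration matches the combinatorial count", {
  s1 <- spinSystem("1H", 1, matrix(0, 1, 1))
  expect_equal(dimension(buildBasis(s1, 1)), 4)
  expect_equal(dimension(buildBasis(twoSpin, 2)), 16)
  s3 <- spinSystem(rep("1H", 3), 1:3,
                   {J <- matrix(5, 3, 3); diag(J) <- 0; J})
  expect_equal(dimension(buildBasis(s3, 2)), countByOrder(3, 2))  # 37
  # full dimension for n <= 5 spins is 4^n
  for (n in 2:5) {
    sys <- spinSystem(rep("1H", n), seq_len(n),
                      {J <- matrix(1, n, n); diag(J) <- 0; J})
    expect_equal(dimension(buildBasis(sys, n)), 4^n)
  }
  expect_error(buildBasis(twoSpin, 0), "maxOrder")
})

test_that("provenance records the full Liouville dimension", {
  b <- buildBasis(twoSpin, 1)
  prov <- reductionReport(b)
  expect_equal(prov$dimension[1], 4^2)
  expect_true(all(diff(prov$dimension) <= 0))
  sys16 <- exampleSystem("difluoroheptane")
  b16 <- buildBasis(sys16, 2, connectivity = TRUE)
  expect_equal(reductionReport(b16)$dimension[1], 4^16)  # ~4.3e9
})

test_that("connectivity screening keeps only coupled clusters", {
  # two uncoupled pairs: no 2-spin states across the gap
  J <- matrix(0, 4, 4); J[1, 2] <- J[2, 1] <- 8; J[3, 4] <- J[4, 3] <- 8
  sys <- spinSystem(rep("1H", 4), 1:4, J)
  b <- buildBasis(sys, 2, connectivity = 0.01)
  expect_equal(dimension(b), 1 + 4 * 3 + 2 * 9)   # singles + two pairs
})

test_that("longitudinal filter matches the enumeration oracle", {
  b <- buildBasis(twoSpin, 2)
  expect_equal(dimension(filterLongitudinal(b, integer(0))), 16)
  s1 <- spinSystem("1H", 1, matrix(0, 1, 1))
  expect_equal(dimension(filterLongitudinal(buildBasis(s1, 1), 1L)), 2)
  f2 <- filterLongitudinal(b, 2L)
  # oracle: spin 2 label must be E (0) or T10 (2)
  all16 <- enumAllLabels(2)
  expect_equal(dimension(f2), sum(all16[, 2] %in% c(0, 2)))  # 8
  expect_error(filterLongitudinal(b, 5L), "out of range")
})

test_that("coherence filter matches the enumeration oracle and is idempotent", {
  s1 <- spinSystem("1H", 1, matrix(0, 1, 1))
  expect_equal(dimension(filterCoherence(buildBasis(s1, 1), 0L, 1L)), 2)
  hh <- spinSystem(rep("1H", 2), c(1, 1.02), matrix(c(0, 8, 8, 0), 2))
  b <- buildBasis(hh, 2)
  f <- filterCoherence(b, 1L, 1:2)
  all16 <- enumAllLabels(2)
  m <- matrix(labelM[all16 + 1], nrow(all16), 2)
  expect_equal(dimension(f), sum(rowSums(m) == 1))  # 4
  f2 <- filterCoherence(f, 1L, 1:2)
  expect_equal(f2@keys, f@keys)
  expect_error(filterCoherence(b, 3L, 1:2), "exceed")
})

test_that("filters commute", {
  b <- buildBasis(twoSpin, 2)
  a1 <- filterCoherence(filterLongitudinal(b, 2L), 1L, 1L)
  a2 <- filterLongitudinal(filterCoherence(b, 1L, 1L), 2L)
  expect_setequal(a1@keys, a2@keys)
})

test_that("symmetrization dimension equals the orbit/Burnside count", {
  sym2 <- spinSystem(rep("1H", 2), c(1, 1), matrix(0, 2, 2),
                     symmetryGroups = list(list(spins = 1:2, label = "S2")))
  sb <- symmetrize(buildBasis(sym2, 2), sym2)
  expect_equal(dimension(sb), 10)   # multisets of 4 labels over 2 slots
  rot <- spinSystem(rep("1H", 3), c(1, 1, 1),
                    {J <- matrix(7, 3, 3); diag(J) <- 0; J},
                    symmetryGroups = list(list(spins = 1:3, label = "S3")))
  sb3 <- symmetrize(buildBasis(rot, 3), rot)
  expect_equal(dimension(sb3), (4^3 + 3 * 4^2 + 2 * 4) / 6)  # Burnside: 20
})

test_that("the symmetrization projector is an orthogonal projection", {
  rot <- spinSystem(rep("1H", 3), c(1, 1, 1),
                    {J <- matrix(7, 3, 3); diag(J) <- 0; J},
                    symmetryGroups = list(list(spins = 1:3, label = "S3")))
  sb <- symmetrize(buildBasis(rot, 3), rot)
  V <- sb@projector
  P <- Matrix::t(V) %*% V
  expect_lt(max(abs(P %*% P - P)), 1e-12)
  expect_lt(max(abs(V %*% Matrix::t(V) - Matrix::Diagonal(nrow(V)))), 1e-12)
})

test_that("trivial group leaves the dimension unchanged", {
  b <- buildBasis(twoSpin, 2)
  sb <- symmetrize(b, list())
  expect_equal(dimension(sb), dimension(b))
})

test_that("a basis not closed under the group is refused", {
  sym2 <- spinSystem(rep("1H", 2), c(1, 1), matrix(0, 2, 2),
                     symmetryGroups = list(list(spins = 1:2, label = "S2")))
  b <- filterLongitudinal(buildBasis(sym2, 2), 1L)  # breaks the swap symmetry
  expect_error(symmetrize(b, sym2), "not closed")
})

test_that("reduction report requires provenance and stays monotone", {
  sys16 <- exampleSystem("difluoroheptane")
  b <- buildBasis(sys16, 3, connectivity = TRUE)
  b <- filterCoherence(b, 1L, which(isotopes(sys16) == "19F"))
  b <- filterLongitudinal(b, which(isotopes(sys16) == "1H"))
  sb <- symmetrize(b, sys16)
  rep <- reductionReport(sb)
  expect_gte(nrow(rep), 4)
  expect_true(all(diff(rep$dimension) <= 0))
})
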