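## equality of two Q/q assignments up to per-parent complementation
## (assignments that the additive coding cannot distinguish)
sameSegregation <- function(qa, qb) {
  p1 <- identical(qa[1:4], qb[1:4]) || identical(qa[1:4], !qb[1:4])
  p2 <- identical(qa[5:8], qb[5:8]) || identical(qa[5:8], !qb[5:8])
  p1 && p2
}

test_that("homologue effects: degenerate and indicator cases", {
  ## all weights equal: every hbar equals the population mean
  n <- 16
  X <- matrix(1, n, 8) * 0.5
  X[, c(1, 5)] <- 0.5  # all equal anyway
  y <- rnorm(n, 1, 0.2)
  eff <- homologueEffects(y, X)
  expect_equal(eff$effect, rep(0, 8), tolerance = 1e-12)
  ## carrier-indicator weights give carrier means
  pop <- tinyPopulation(80, seed = 60)
  d <- simulateDosageGrid(pop, 1)
  X <- dosageAt(d, "chr1", 10)
  y <- rnorm(80, 1, 0.1)
  eff <- homologueEffects(y, X)
  carrierMean <- sum((X[, 2] / 2) * y) / sum(X[, 2] / 2)
  expect_equal(eff$hbar[2], carrierMean)
  ## weighted effects sum to zero
  expect_equal(sum(eff$effect * eff$weight), 0, tolerance = 1e-9)
})

test_that("a planted homologue effect shows up as a group-mean contrast", {
  case <- plantedScanCase(n = 200, effectHom = 6, effect = 0.3,
                          varE = 0, seed = 61)
  eff <- homologueEffects(case$y, case$dosage, "chr1", 25)
  ## oracle: direct carrier / non-carrier group means on the truth
  copies <- homologueCopies(case$pop, "chr1", 25)[, 6]
  y <- as.numeric(case$y[individualNames(case$pop)])
  w <- copies / 2
  oracle <- sum(w * y) / sum(w) - mean(y)
  expect_equal(eff$effect[6], oracle, tolerance = 1e-10)
  expect_gt(eff$effect[6], 0.1)   # clearly positive for the carrier homologue
  expect_error(homologueEffects(y, matrix(0, 200, 8)), "zero total weight")
})

test_that("bi-allelic enumeration matches the exhaustive oracle", {
  models <- enumerateBiallelicModels()
  add <- models[models$coding == "additive", ]
  ## oracle: enumerate all 2^8, canonicalize, drop double-homozygous
  all256 <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))
  canon <- unique(t(apply(all256, 1, function(v) if (v[1]) !v else v)))
  keep <- apply(canon, 1, function(v)
    !(sum(v[1:4]) %in% c(0, 4) && sum(v[5:8]) %in% c(0, 4)))
  expect_equal(nrow(add), sum(keep))
  expect_equal(nrow(models), 2 * sum(keep))
  ## the qqqq x Qqqq family: exactly one Q in parent 2, none in parent 1
  fam <- add[add$parent1 == "qqqq" & add$parent2 == "Qqqq", ]
  expect_equal(nrow(fam), 4)
  ## non-segregating assignments excluded
  expect_false(any(add$parent1 %in% c("QQQQ", "qqqq") &
                   add$parent2 %in% c("QQQQ", "qqqq")))
  ## canonical form: homologue 1 always carries q
  expect_false(any(add$Q1))
})

test_that("SIC penalizes parameters and rewards fit", {
  n <- 100; k1 <- 2; k2 <- 3; rss <- 1.7
  sic <- function(rss, k) n * log(rss / n) + k * log(n)
  expect_lt(sic(rss, k1), sic(rss, k2))  # equal RSS, fewer parameters wins
  case <- plantedScanCase(n = 100, effectHom = 2, effect = 0.4,
                          varE = 0.03, seed = 62)
  X <- dosageAt(case$dosage, "chr1", 25)
  Q <- c(FALSE, TRUE, rep(FALSE, 6))
  fAdd <- fitBiallelicModel(case$y, X, Q, "additive")
  expect_equal(fAdd$SIC,
               fAdd$n * log(fAdd$RSS / fAdd$n) + 2 * log(fAdd$n))
  ## degenerate predictor errors
  expect_error(fitBiallelicModel(case$y, matrix(0.5, 100, 8),
                                 Q, "additive"), "degenerate")
})

test_that("single-homologue additive model reparameterizes the plain regression", {
  case <- plantedScanCase(n = 90, effectHom = 3, effect = 0.35,
                          varE = 0.04, lambda = 0.9, seed = 63)
  X <- dosageAt(case$dosage, "chr1", 25)
  Q <- rep(FALSE, 8); Q[3] <- TRUE
  fBi <- fitBiallelicModel(case$y, X, Q, "additive")
  fCol <- fitPosition(as.numeric(case$y), cbind(1, X[, 3]))
  expect_equal(fBi$RSS, fCol$RSS1, tolerance = 1e-10)
})

test_that("exact and approximate dominance predictors agree at lambda = 1", {
  case <- plantedScanCase(n = 70, effectHom = 6, effect = 0.4,
                          varE = 0.02, seed = 64)
  gcp <- inheritanceToProbabilities(case$pop, 1)
  X <- dosageAt(case$dosage, "chr1", 25)
  cp <- classProbsAt(gcp, "chr1", 25)
  Q <- rep(FALSE, 8); Q[6] <- TRUE
  fExact <- fitBiallelicModel(case$y, X, Q, "additive+dominance",
                              classProbs = cp)
  fApprox <- fitBiallelicModel(case$y, X, Q, "additive+dominance")
  expect_false(fExact$dominanceApprox)
  expect_true(fApprox$dominanceApprox)
  ## at one-hot class probabilities the exact dominance predictor is the
  ## 0/1 carrier indicator: same fit as regressing on the indicator
  carrier <- as.numeric(homologueCopies(case$pop, "chr1", 25)[, 6] > 0)
  fInd <- fitPosition(as.numeric(case$y),
                      cbind(1, add = rowSums(X[, 6, drop = FALSE]),
                            dom = carrier))
  expect_equal(fExact$RSS, fInd$RSS1, tolerance = 1e-9)
})

test_that("min-SIC search recovers a strong planted QQQQ x QQQq model", {
  case <- plantedScanCase(n = 200, effectHom = 8, effect = 0.5,
                          varE = 0.02, seed = 65)
  gcp <- inheritanceToProbabilities(case$pop, 1)
  models <- biallelicModelSearch(case$y, case$dosage, "chr1", 25,
                                 classProbs = gcp)
  qcols <- paste0("Q", 1:8)
  best <- as.logical(unlist(models[1, qcols]))
  truth <- rep(FALSE, 8); truth[8] <- TRUE
  expect_true(sameSegregation(best, truth))
  expect_equal(models$deltaSIC[1], 0)
})

test_that("model evidence labels weak support under the null", {
  expect_error(modelEvidence(data.frame()), "empty")
  one <- modelEvidence(data.frame(SIC = 5))
  expect_equal(one$deltaSIC, 0)
  ev <- modelEvidence(data.frame(SIC = c(12, 31)))
  expect_equal(ev$evidence[1], "decisive")
  ## permuted phenotype: top models nearly tie
  case <- plantedScanCase(n = 120, effect = 0.4, varE = 0.03, seed = 66)
  set.seed(67)
  weakCount <- 0
  for (i in 1:5) {
    yNull <- setNames(sample(as.numeric(case$y)), names(case$y))
    m <- biallelicModelSearch(yNull, case$dosage, "chr1", 25)
    if (m$deltaSIC[2] < 2) weakCount <- weakCount + 1
  }
  expect_gte(weakCount, 3)
})
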