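test_that("model-B design drops one column per parent and keeps the algebra", {
  pop <- tinyPopulation(20, seed = 40)
  X <- dosageAt(simulateDosageGrid(pop, 0.8), "chr1", 10)
  M <- designMatrixModelB(X)
  expect_equal(colnames(M),
               c("(Intercept)", "X2", "X3", "X4", "X6", "X7", "X8"))
  ## dropped columns recoverable from the constraint
  expect_equal(unname(2 - rowSums(X[, 2:4])), unname(X[, 1]),
               tolerance = 1e-12)
  expect_equal(unname(2 - rowSums(X[, 6:8])), unname(X[, 5]),
               tolerance = 1e-12)
  ## uninformative position flags zero-variance predictors
  Xu <- matrix(0.5, 10, 8)
  zv <- attr(designMatrixModelB(Xu), "zeroVariance")
  expect_true(all(zv[-1]))
  ## constraint violation detected
  Xbad <- X; Xbad[1, 1] <- Xbad[1, 1] + 0.1
  expect_error(designMatrixModelB(Xbad), "constraint")
})

test_that("the choice of dropped columns does not change RSS or LOD", {
  case <- plantedScanCase(n = 40, seed = 41)
  X <- dosageAt(case$dosage, "chr1", 25)
  y <- case$y
  fitA <- fitPosition(y, designMatrixModelB(X))
  ## alternative elimination: drop X2 and X6 instead of X1 and X5
  MB <- cbind(1, X[, c(1, 3, 4, 5, 7, 8)])
  fitB <- fitPosition(y, MB)
  expect_equal(fitA$RSS1, fitB$RSS1, tolerance = 1e-10)
})

test_that("fitPosition matches a brute-force least-squares oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12
    X <- matrix(runif(n * 6), n, 6)
    y <- rnorm(n)
    fit <- fitPosition(y, cbind(1, X))
    expect_equal(fit$RSS1, bruteForceRSS(y, X), tolerance = 1e-8)
    ## coefficients against the normal-equations oracle
    Xs <- cbind(1, X)
    bOracle <- solve(t(Xs) %*% Xs, t(Xs) %*% y)
    expect_equal(unname(fit$coefficients), as.numeric(bOracle),
                 tolerance = 1e-8)
  }
  expect_error(fitPosition(rnorm(5), cbind(1, matrix(1, 5, 2))),
               "at least 8")
})

test_that("degenerate fits are handled: constant y, perfect fit", {
  y <- rep(2, 20)
  X <- matrix(runif(160), 20, 8)
  X[, 1:4] <- 2 * X[, 1:4] / rowSums(X[, 1:4])
  X[, 5:8] <- 2 * X[, 5:8] / rowSums(X[, 5:8])
  fit <- fitPosition(y, designMatrixModelB(X))
  expect_equal(fit$RSS0, 0)
  expect_equal(lodScore(20, fit$RSS0, fit$RSS1), 0)
  ## y exactly linear in one predictor: RSS1 = 0, LOD = Inf
  y2 <- 1 + 3 * X[, 2]
  fit2 <- fitPosition(y2, designMatrixModelB(X))
  expect_lt(fit2$RSS1, 1e-20)
})

test_that("LOD arithmetic and the R2 identity", {
  expect_equal(lodScore(20, 2.0, 0.2), 10)
  expect_equal(lodScore(496, 3.3, 3.3), 0)
  expect_error(lodScore(10, 1, -0.1), "non-negative")
  expect_error(lodScore(10, 1, 2), "RSS0 must be")

  case <- plantedScanCase(n = 60, seed = 43, varE = 0.02)
  scan <- qtlScan(case$y, case$dosage)
  tab <- lodProfile(scan)
  ## identity R2 = 1 - 10^(-2 LOD / n) at every position
  expect_equal(tab$R2, 1 - 10^(-2 * tab$LOD / tab$n), tolerance = 1e-10)
  expect_true(all(tab$LOD >= 0))
})

test_that("scan LOD equals an independent brute-force oracle everywhere", {
  case <- plantedScanCase(n = 20, seed = 44, varE = 0.05, lambda = 0.9)
  scan <- qtlScan(case$y, case$dosage)
  oracle <- bruteForceLOD(as.numeric(case$y[individualNames(case$pop)]),
                          case$dosage)
  expect_equal(lodProfile(scan)$LOD, oracle, tolerance = 1e-8)
})

test_that("planted QTL is recovered near its true position", {
  case <- plantedScanCase(n = 150, effect = 0.5, varE = 0.03, seed = 45)
  scan <- qtlScan(case$y, case$dosage)
  tab <- lodProfile(scan)
  best <- tab[which.max(tab$LOD), ]
  expect_equal(best$chrom, "chr1")
  expect_lt(abs(best$cM - 25), 5)
})

test_that("permutation threshold is deterministic and respects quantile bounds", {
  case <- plantedScanCase(n = 50, seed = 46)
  t1 <- permutationThreshold(case$y, case$dosage, nPerm = 60, seed = 9)
  t2 <- permutationThreshold(case$y, case$dosage, nPerm = 60, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  t3 <- permutationThreshold(case$y, case$dosage, nPerm = 60, seed = 10)
  expect_false(identical(as.numeric(t1), as.numeric(t3)))
  maxima <- attr(t1, "maxima")
  expect_length(maxima, 60)
  ## alpha = 1: the minimum of the permuted maxima
  tAll <- permutationThreshold(case$y, case$dosage, nPerm = 60, alpha = 1,
                               seed = 9)
  expect_equal(as.numeric(tAll), min(maxima))
  expect_error(permutationThreshold(case$y, case$dosage, nPerm = 10),
               "at least 20")
  ## permuted phenotype yields a valid null scan
  yPerm <- setNames(sample(case$y), names(case$y))
  expect_s4_class(qtlScan(yPerm, case$dosage), "ScanResult")
})

test_that("peaks carry LOD-2 intervals truncated at the threshold", {
  ## synthetic unimodal profile: no simulation, by construction
  prof <- data.frame(
    chrom = "chr1", cM = 0:20,
    LOD = c(0.5, 1, 1.5, 2, 3, 4.2, 5.5, 6.5, 7.5, 8.1, 8.4,
            8.0, 7.2, 6.6, 6.0, 5.2, 4.0, 3.0, 2.0, 1.0, 0.5),
    R2 = 0.1, n = 100
  )
  scan <- new("ScanResult", table = prof,
              coefficients = matrix(0, 21, 7))
  pk <- findPeaks(scan, threshold = 4.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$peakCM, 10)
  expect_equal(pk$peakLOD, 8.4)
  ## interval: LOD >= 6.4, positions 7..13
  expect_equal(pk$intervalLo, 7)
  expect_equal(pk$intervalHi, 13)
  ## threshold above peak-2 truncates the interval instead
  pk2 <- findPeaks(scan, threshold = 7)
  expect_equal(c(pk2$intervalLo, pk2$intervalHi), c(8, 12))
  ## flat profile below threshold: no peaks
  prof$LOD <- 1
  scanFlat <- new("ScanResult", table = prof,
                  coefficients = matrix(0, 21, 7))
  expect_equal(nrow(findPeaks(scanFlat, 4.5)), 0)
})

test_that("two planted QTLs on different chromosomes give two peaks", {
  map <- tinyMap(c(chr1 = 50, chr2 = 50))
  pop <- simulatePopulation(150, map, seed = 47)
  q1 <- plantedQTL("chr1", 20, effects = c("2" = 0.4), mu = 0.9)
  q2eff <- homologueCopies(pop, "chr2", 30)[, 7]
  ph <- simulatePhenotypes(pop, q1, varE = 0.02, varYear = 0,
                           varBlock = 0, seed = 48)
  y <- tapply(ph$protein, ph$clone, mean)[individualNames(pop)]
  y <- y + 0.4 * q2eff   # second QTL injected directly
  dosage <- simulateDosageGrid(pop, 1)
  scan <- runNaiveScan(setNames(as.numeric(y), individualNames(pop)),
                       dosage, nPerm = 100, seed = 49)
  pk <- scanPeaks(scan)
  expect_equal(sort(unique(pk$chrom)), c("chr1", "chr2"))
  expect_equal(nrow(pk), 2)
})

test_that("missing phenotypes are dropped with n recorded", {
  case <- plantedScanCase(n = 60, seed = 50)
  y <- case$y
  y[c(3, 10)] <- NA
  scan <- qtlScan(y, case$dosage)
  expect_equal(unique(lodProfile(scan)$n), 58)
  ## mismatched individuals error
  names(y)[1] <- "unknown_clone"
  expect_error(qtlScan(y, case$dosage), "do not match")
})
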