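test_that("bivalent gametes carry two distinct homologues and respect the grid", {
  map <- geneticMap(c(chrA = 80))
  set.seed(1)
  for (i in 1:50) {
    g <- simulateGamete(map, "chrA", meiosisConfig())
    expect_true(all(g[1, ] != g[2, ]))
    expect_equal(ncol(g), sum(gridPositions(map)$chrom == "chrA"))
  }
  expect_error(simulateGamete(map, "nope", meiosisConfig()),
               "unknown chromosome")
})

test_that("homologue transmission frequency is 1/2 per label", {
  map <- geneticMap(c(chrA = 10), step = 10)  # 2 grid positions
  set.seed(2)
  hits <- matrix(0, 2, 4)
  nG <- 4000
  for (i in seq_len(nG)) {
    g <- simulateGamete(map, "chrA", meiosisConfig())
    for (p in 1:2) hits[p, unique(g[, p])] <- hits[p, unique(g[, p])] + 1
  }
  expect_true(all(abs(hits / nG - 0.5) < 0.03))
})

test_that("zero recombination distance gives identical label pairs", {
  map <- geneticMap(c(chrA = 0.1), step = 0.1)  # two positions 0.1 cM apart
  set.seed(3)
  agree <- replicate(200, {
    g <- simulateGamete(map, "chrA", meiosisConfig())
    identical(sort(g[, 1]), sort(g[, 2]))
  })
  ## 0.1 cM: recombination probability ~0.1% per chromatid
  expect_gt(mean(agree), 0.99)
})

test_that("simulatePopulation is deterministic and correctly shaped", {
  map <- tinyMap()
  p1 <- simulatePopulation(25, map, seed = 7)
  p2 <- simulatePopulation(25, map, seed = 7)
  expect_identical(p1@h1a, p2@h1a)
  expect_identical(p1@h2b, p2@h2b)
  expect_equal(nIndividuals(p1), 25)
  expect_equal(ncol(p1@h1a), nrow(gridPositions(map)))
  p3 <- simulatePopulation(25, map, seed = 8)
  expect_false(identical(p1@h1a, p3@h1a))
})

test_that("double-reduction locus frequency tracks the configured rate", {
  map <- geneticMap(c(chrA = 100))
  cfg <- meiosisConfig(quadrivalentRate = 1, doubleReductionRate = 0.1)
  pop <- simulatePopulation(150, map, cfg, cfg, seed = 11)
  drFrac <- mean(pop@h1a == pop@h1b)
  expect_gt(drFrac, 0.07)
  expect_lt(drFrac, 0.13)
  ## no DR at all without quadrivalents
  pop0 <- tinyPopulation(40, seed = 12)
  expect_true(all(pop0@h1a != pop0@h1b))
  expect_true(all(pop0@h2a != pop0@h2b))
})

test_that("meiosis config validates its rate ranges", {
  expect_error(meiosisConfig(-0.1, 0), "quadrivalentRate")
  expect_error(meiosisConfig(0, 0.3), "doubleReductionRate")
})

test_that("linkage decays with Haldane distance", {
  map <- geneticMap(c(chrA = 60), step = 5)
  pop <- simulatePopulation(800, map, seed = 13)
  pos <- gridPositions(map)
  carrier <- function(cm) {
    cc <- homologueCopies(pop, "chrA", cm)
    cc[, 1] > 0
  }
  c0 <- carrier(0)
  for (d in c(10, 30, 60)) {
    r <- (1 - exp(-2 * d / 100)) / 2
    obs <- cor(c0, carrier(d))
    expect_lt(abs(obs - (1 - 2 * r)), 0.08)
  }
  ## monotone decay over distance
  cors <- vapply(c(5, 20, 45), function(d) cor(c0, carrier(d)), numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("simplex-style segregation: carrier fraction of one homologue is 1/2", {
  pop <- tinyPopulation(600, seed = 14)
  cc <- homologueCopies(pop, "chr1", 10)
  frac <- mean(cc[, 1] > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 600))  # 3-sigma binomial band
})

test_that("blurred probabilities interpolate between truth and uniform", {
  pop <- tinyPopulation(12, seed = 15)
  g1 <- inheritanceToProbabilities(pop, 1)
  expect_true(all(g1@prob1 %in% c(0, 1)))
  d1 <- simulateDosageGrid(pop, 1)
  expect_true(all(assay(d1, "X1") %in% 0:2))
  g0 <- inheritanceToProbabilities(pop, 0)
  d0 <- classesToDosage(g0)
  expect_equal(max(abs(assay(d0, "X3") - 0.5)), 0, tolerance = 1e-12)
  ghalf <- inheritanceToProbabilities(pop, 0.7)
  s <- rowSums(ghalf@prob1, dims = 2)
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
  expect_error(inheritanceToProbabilities(pop, 1.2), "lambda")
})

test_that("planted QTL effects appear in the phenotypes as specified", {
  pop <- tinyPopulation(60, seed = 16)
  qtlNull <- plantedQTL("chr1", 25, mu = 0.93)
  ph0 <- simulatePhenotypes(pop, qtlNull, varE = 0, varYear = 0,
                            varBlock = 0, seed = 17)
  expect_equal(ph0$protein, rep(0.93, nrow(ph0)))
  ## protein column consistent with the raw-measurement columns
  expect_equal(ph0$protein,
               proteinContent(ph0$pfj_protein, tuberMoisture(ph0$dry_matter)))

  a <- 0.25
  qtl <- plantedQTL("chr1", 25, effects = c("6" = a), mu = 0.93)
  ph <- simulatePhenotypes(pop, qtl, varE = 0, varYear = 0,
                           varBlock = 0, seed = 18)
  copies <- unname(homologueCopies(pop, "chr1", 25)[ph$clone, 6])
  expect_equal(ph$protein, 0.93 + a * copies)
  ## deterministic given seed
  ph2 <- simulatePhenotypes(pop, qtl, varE = 0, varYear = 0,
                            varBlock = 0, seed = 18)
  expect_identical(ph, ph2)
})
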