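test_that("trait derivation formulas and their boundaries", {
  expect_equal(tuberMoisture(20), 80)
  expect_equal(tuberMoisture(0), 100)
  expect_equal(tuberMoisture(100), 0)
  expect_error(tuberMoisture(101), "\\[0, 100\\]")
  expect_equal(proteinContent(1.2, 77.5), 0.93)
  expect_equal(proteinContent(3.7, 100), 3.7)
  expect_equal(proteinContent(0, 60), 0)
  expect_error(proteinContent(-1, 50), "non-negative")
})

test_that("protein content is bilinear in its arguments", {
  p <- c(0.5, 1.1, 2.0); m <- c(70, 80, 90)
  for (s in c(2, 5)) {
    expect_equal(proteinContent(s * p, m), s * proteinContent(p, m))
    expect_equal(proteinContent(p, s * m), s * proteinContent(p, m))
  }
  expect_equal(proteinContent(p[1] + p[2], m),
               proteinContent(p[1], m) + proteinContent(p[2], m))
})

test_that("ANOVA mean squares: degenerate and constructed cases", {
  tab <- expand.grid(clone = paste0("c", 1:10), year = 2013, block = 1:2)
  tab$protein <- 1
  ms <- anovaMeanSquares(tab, "within")
  expect_equal(ms$MS_G, 0)
  expect_equal(ms$MS_E, 0)

  ## clone effects only, no noise: MS_E ~ 0, MS_G > 0
  eff <- rnorm(10)
  tab$protein <- 1 + eff[as.integer(tab$clone)]
  ms <- anovaMeanSquares(tab, "within")
  expect_lt(ms$MS_E, 1e-20)
  expect_gt(ms$MS_G, 0)

  expect_error(anovaMeanSquares(tab[tab$block == 1, ], "within"),
               ">= 2 blocks")
  expect_error(anovaMeanSquares(tab, "between"), ">= 2 years")
})

test_that("one-way mean squares match E[MS] = sigma2_E + r sigma2_G", {
  ## theory-of-ANOVA oracle at moderate size, averaged over replicates
  set.seed(20)
  s2G <- 0.02; s2E <- 0.05; r <- 2; nClone <- 80
  msG <- msE <- numeric(60)
  for (i in seq_along(msG)) {
    g <- rnorm(nClone, 0, sqrt(s2G))
    tab <- expand.grid(clone = paste0("c", seq_len(nClone)),
                       year = 1, block = seq_len(r))
    tab$protein <- g[as.integer(tab$clone)] + rnorm(nrow(tab), 0, sqrt(s2E))
    ms <- anovaMeanSquares(tab, "within")
    msG[i] <- ms$MS_G; msE[i] <- ms$MS_E
  }
  expect_equal(mean(msG), s2E + r * s2G, tolerance = 0.12)
  expect_equal(mean(msE), s2E, tolerance = 0.08)
})

test_that("variance components follow the mean-square identities", {
  vc <- varianceComponents(list(MS_G = 0.05, MS_E = 0.03), r = 2,
                           model = "within")
  expect_equal(componentEstimates(vc)[["sigma2_G"]], 0.01)
  vc0 <- varianceComponents(list(MS_G = 0.04, MS_E = 0.04), r = 2,
                            model = "within")
  expect_equal(componentEstimates(vc0)[["sigma2_G"]], 0)
  ## two-way: MS_GxY = MS_E gives zero interaction variance
  vc2 <- varianceComponents(list(MS_G = 0.10, MS_GxY = 0.03, MS_E = 0.03),
                            r = 2, y = 2, model = "between")
  est <- componentEstimates(vc2)
  expect_equal(est[["sigma2_GxY"]], 0)
  expect_equal(est[["sigma2_G"]], (0.10 - 0.03) / 4)
  ## negative raw estimates floored, raw kept
  vcn <- varianceComponents(list(MS_G = 0.02, MS_E = 0.05), r = 2,
                            model = "within")
  expect_equal(componentEstimates(vcn)[["sigma2_G"]], 0)
  expect_lt(componentEstimates(vcn, raw = TRUE)[["sigma2_G"]], 0)
  expect_error(varianceComponents(list(MS_G = 1, MS_E = 1), r = 0,
                                  model = "within"), ">= 1")
})

test_that("heritability is monotone in its components", {
  s2Gs <- seq(0.005, 0.08, length.out = 8)
  h <- vapply(s2Gs, function(s)
    heritability(varianceComponentSet(s, 0.04, r = 2)), numeric(1))
  expect_true(all(diff(h) > 0))
  s2Es <- seq(0.01, 0.2, length.out = 8)
  h2 <- vapply(s2Es, function(s)
    heritability(varianceComponentSet(0.02, s, r = 2)), numeric(1))
  expect_true(all(diff(h2) < 0))
  expect_equal(heritability(varianceComponentSet(0, 0.05, r = 2)), 0)
})

test_that("BLUEs reduce to clone means in one year and absorb year shifts", {
  tab <- expand.grid(clone = paste0("c", 1:12), year = 2013, block = 1:2)
  set.seed(21)
  tab$protein <- rnorm(nrow(tab), 1, 0.1)
  b <- computeBLUEs(tab)
  m <- tapply(tab$protein, tab$clone, mean)
  expect_equal(b$blue[match(names(m), b$clone)], as.numeric(m),
               tolerance = 1e-10)

  ## balanced two-year data with an additive year shift: BLUEs invariant
  ## up to a common constant
  tab2 <- expand.grid(clone = paste0("c", 1:12), year = c(2013, 2014),
                      block = 1:2)
  tab2$protein <- rnorm(nrow(tab2), 1, 0.1)
  tab2s <- tab2
  delta <- 0.6
  tab2s$protein <- tab2s$protein + delta * (tab2s$year == 2014)
  b1 <- computeBLUEs(tab2)
  b2 <- computeBLUEs(tab2s)
  d <- b2$blue - b1$blue[match(b2$clone, b1$clone)]
  expect_lt(max(d) - min(d), 1e-6)
})

test_that("multi-year BLUEs rank clones better than a single-year mean", {
  set.seed(22)
  nClone <- 60
  g <- rnorm(nClone, 0, sqrt(0.04))
  tab <- expand.grid(clone = sprintf("c%02d", seq_len(nClone)),
                     year = 1:3, block = 1:2)
  yearEff <- rnorm(3, 0, 0.1)
  tab$protein <- 1 + g[as.integer(tab$clone)] + yearEff[tab$year] +
    rnorm(nrow(tab), 0, sqrt(0.06))
  b <- computeBLUEs(tab)
  rBlue <- cor(b$blue[match(sprintf("c%02d", seq_len(nClone)), b$clone)],
               g, method = "spearman")
  one <- tab[tab$year == 1, ]
  m1 <- tapply(one$protein, one$clone, mean)
  rOne <- cor(as.numeric(m1)[match(sprintf("c%02d", seq_len(nClone)),
                                   names(m1))], g, method = "spearman")
  expect_gt(rBlue, rOne)
})
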