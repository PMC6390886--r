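## Shared fixture builders. Everything is generated in code at test time;
## sizes are kept small enough that a full suite run stays quick.

## tiny two-chromosome map
tinyMap <- function(lens = c(chr1 = 50, chr2 = 40), step = 1) {
  geneticMap(lens, step = step)
}

## small population with fully known inheritance
tinyPopulation <- function(n = 30, map = tinyMap(), seed = 101,
                           quadrivalentRate = 0, drRate = 0) {
  cfg <- meiosisConfig(quadrivalentRate, drRate)
  simulatePopulation(n, map, cfg, cfg, seed = seed)
}

## phenotype vector (named by clone) from a planted single-homologue QTL
plantedScanCase <- function(n = 120, effectHom = 2, effect = 0.4,
                            varE = 0.04, lambda = 1, seed = 42,
                            map = tinyMap(), qtlChrom = "chr1",
                            qtlCM = 25, mu = 0.93) {
  pop <- tinyPopulation(n, map, seed = seed)
  qtl <- plantedQTL(qtlChrom, qtlCM,
                    effects = setNames(effect, as.character(effectHom)),
                    mu = mu)
  ph <- simulatePhenotypes(pop, qtl, years = 1, blocksPerYear = 2,
                           varE = varE, varYear = 0, varBlock = 0,
                           seed = seed + 1)
  y <- tapply(ph$protein, ph$clone, mean)
  y <- setNames(as.numeric(y), names(y))
  list(pop = pop, qtl = qtl, pheno = ph, y = y,
       dosage = simulateDosageGrid(pop, lambda))
}

## independent brute-force OLS oracle: residual sum of squares via
## explicit normal equations / pseudo-inverse, no shared code with the
## scan path
bruteForceRSS <- function(y, X) {
  Xs <- cbind(1, X)
  b <- MASS::ginv(t(Xs) %*% Xs) %*% t(Xs) %*% y
  sum((y - Xs %*% b)^2)
}

## brute-force LOD profile over all grid positions of a dosage object
bruteForceLOD <- function(y, dosage) {
  pos <- gridPositions(dosage)
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  vapply(seq_len(nrow(pos)), function(p) {
    X <- dosageAt(dosage, pos$chrom[p], pos$cM[p])[, c(2:4, 6:8)]
    rss1 <- bruteForceRSS(y, X)
    if (rss0 == rss1) 0 else n / 2 * log10(rss0 / rss1)
  }, numeric(1))
}
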