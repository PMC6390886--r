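## Tetrasomic meiosis and F1 population simulator. This is the testbed
## for the whole pipeline: it produces populations with fully known
## inheritance so that scans, effect estimates and model searches can be
## checked against planted truth.

## The three ways of pairing homologues {1,2,3,4} into two bivalents.
.BIVALENT_PAIRINGS <- list(
  rbind(c(1L, 2L), c(3L, 4L)),
  rbind(c(1L, 3L), c(2L, 4L)),
  rbind(c(1L, 4L), c(2L, 3L))
)

## Crossover breakpoints along a chromosome of length L cM under
## Haldane's model: count ~ Poisson(L/100), positions uniform.
.haldaneBreakpoints <- function(L) {
  k <- rpois(1L, L / 100)
  if (k == 0L) numeric() else sort(runif(k, 0, L))
}

## One chromatid alternating between two homologue labels, evaluated at
## the grid positions `pos`.
.bivalentChromatid <- function(labels2, pos, L) {
  bp <- .haldaneBreakpoints(L)
  start <- sample.int(2L, 1L)
  nSwitch <- findInterval(pos, bp)
  labels2[((start - 1L + nSwitch) %% 2L) + 1L]
}

#' Simulate one gamete of a tetraploid parent
#'
#' Draws a single 2n gamete along the grid of one chromosome. With
#' probability `1 - quadrivalentRate` the four homologues pair into two
#' bivalents (uniform over the three possible pairings) and each bivalent
#' delivers one recombinant chromatid, so the two transmitted labels are
#' always distinct. With probability `quadrivalentRate` the chromosome
#' forms a quadrivalent: the two chromatids are then drawn segment-wise
#' over all four homologues, and at any locus they are copies of the same
#' homologue (a double-reduction product) with probability
#' `doubleReductionRate`. Recombination breakpoints follow Haldane's
#' model (Poisson with mean length/100 per chromatid, no interference).
#'
#' @param map a [GeneticMap-class].
#' @param chromosome chromosome name (must be on the map).
#' @param config a [MeiosisConfig-class].
#' @return integer matrix (2 x positions) of homologue labels in 1..4,
#'   one row per transmitted chromatid, columns following the chromosome
#'   grid.
#' @examples
#' map <- geneticMap(c(chr1 = 100))
#' set.seed(1)
#' g <- simulateGamete(map, "chr1", meiosisConfig())
#' all(g[1, ] != g[2, ])  # bivalent mode: labels always distinct
#' @export
simulateGamete <- function(map, chromosome, config) {
  stopifnot(is(map, "GeneticMap"), is(config, "MeiosisConfig"))
  if (!chromosome %in% map@chromosomes)
    stop("unknown chromosome: ", chromosome)
  L <- chromosomeLengths(map)[[chromosome]]
  pos <- map@grid$cM[map@grid$chrom == chromosome]
  P <- length(pos)

  if (runif(1) >= config@quadrivalentRate) {
    pairing <- .BIVALENT_PAIRINGS[[sample.int(3L, 1L)]]
    rbind(
      .bivalentChromatid(pairing[1L, ], pos, L),
      .bivalentChromatid(pairing[2L, ], pos, L)
    )
  } else {
    ## quadrivalent: redraw the (possibly identical) label pair on each
    ## segment between the pooled breakpoints of the two chromatids
    bp <- sort(c(.haldaneBreakpoints(L), .haldaneBreakpoints(L)))
    seg <- findInterval(pos, bp) + 1L
    nSeg <- max(seg)
    a <- sample.int(4L, nSeg, replace = TRUE)
    dr <- runif(nSeg) < config@doubleReductionRate
    shift <- sample.int(3L, nSeg, replace = TRUE)  # offset to a distinct label
    b <- ifelse(dr, a, ((a - 1L + shift) %% 4L) + 1L)
    rbind(a[seg], b[seg])
  }
}

#' Simulate an autotetraploid F1 population
#'
#' Crosses two tetraploid parents, each meiosis governed by its own
#' [MeiosisConfig-class], and records the realized homologue transmission
#' of every individual at every grid position. Identical arguments and
#' seed yield an identical population.
#'
#' @param n number of F1 individuals (>= 1).
#' @param map a [GeneticMap-class].
#' @param configP1,configP2 meiosis configurations of parent 1 and 2.
#' @param seed integer seed.
#' @return A [TrueInheritance-class].
#' @examples
#' map <- geneticMap(c(chr1 = 100))
#' pop <- simulatePopulation(20, map, meiosisConfig(), meiosisConfig(),
#'                           seed = 1)
#' pop
#' @export
simulatePopulation <- function(n, map, configP1 = meiosisConfig(),
                               configP2 = meiosisConfig(), seed = 1) {
  stopifnot(n >= 1, is(map, "GeneticMap"))
  set.seed(seed)
  P <- nrow(map@grid)
  h1a <- h1b <- h2a <- h2b <- matrix(0L, n, P)
  colIdx <- split(seq_len(P), map@grid$chrom)[unique(map@grid$chrom)]
  for (ind in seq_len(n)) {
    for (ch in map@chromosomes) {
      idx <- colIdx[[ch]]
      g1 <- simulateGamete(map, ch, configP1)
      g2 <- simulateGamete(map, ch, configP2)
      h1a[ind, idx] <- pmin(g1[1L, ], g1[2L, ])
      h1b[ind, idx] <- pmax(g1[1L, ], g1[2L, ])
      h2a[ind, idx] <- pmin(g2[1L, ], g2[2L, ]) + 4L
      h2b[ind, idx] <- pmax(g2[1L, ], g2[2L, ]) + 4L
    }
  }
  ids <- sprintf("F1_%04d", seq_len(n))
  rownames(h1a) <- rownames(h1b) <- rownames(h2a) <- rownames(h2b) <- ids
  new("TrueInheritance",
    map = map, h1a = h1a, h1b = h1b, h2a = h2a, h2b = h2b,
    quadrivalent = configP1@quadrivalentRate > 0 ||
      configP2@quadrivalentRate > 0,
    individuals = ids
  )
}

#' True homologue copy numbers at one position
#'
#' @param truth a [TrueInheritance-class].
#' @param chrom chromosome name.
#' @param cM grid position.
#' @return integer matrix (individuals x 8): copies (0, 1 or 2) of each
#'   parental homologue carried. Rows sum to 2 per parent.
#' @export
homologueCopies <- function(truth, chrom, cM) {
  stopifnot(is(truth, "TrueInheritance"))
  i <- .gridIndex(truth@map@grid, chrom, cM)
  n <- length(truth@individuals)
  out <- matrix(0L, n, 8, dimnames = list(truth@individuals,
                                          paste0("X", 1:8)))
  idx <- seq_len(n)
  add <- function(lab) out[cbind(idx, lab)] <<- out[cbind(idx, lab)] + 1L
  add(truth@h1a[, i]); add(truth@h1b[, i])
  add(truth@h2a[, i]); add(truth@h2b[, i])
  out
}

#' Blur true inheritance into gamete-class probabilities
#'
#' Emulates the posterior uncertainty of probabilistic haplotype
#' reconstruction: at every individual and position, the class
#' distribution is the mixture `lambda * truth + (1 - lambda) * uniform`
#' over the class set, independently per parent. `lambda = 1` reproduces
#' the truth exactly (one-hot distributions); `lambda = 0` is the
#' completely uninformative uniform distribution. Double-reduction classes
#' (11, 22, 33, 44) are part of the class set only when the population
#' was simulated with quadrivalents enabled.
#'
#' @param truth a [TrueInheritance-class].
#' @param lambda informativeness in \[0, 1\].
#' @return A [GameteClassProb-class].
#' @export
inheritanceToProbabilities <- function(truth, lambda = 1) {
  stopifnot(is(truth, "TrueInheritance"))
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  classes <- c("12", "13", "14", "23", "24", "34")
  if (truth@quadrivalent) classes <- c(classes, "11", "22", "33", "44")
  K <- length(classes)
  n <- length(truth@individuals)
  P <- nrow(truth@map@grid)

  classIndex <- function(a, b) {  # a, b in 1..4, a <= b
    lab <- paste0(a, b)
    match(lab, classes)
  }
  k1 <- matrix(classIndex(truth@h1a, truth@h1b), n, P)
  k2 <- matrix(classIndex(truth@h2a - 4L, truth@h2b - 4L), n, P)

  off <- (1 - lambda) / K
  prob1 <- array(off, dim = c(n, P, K))
  prob2 <- array(off, dim = c(n, P, K))
  flat <- cbind(rep(seq_len(n), P), rep(seq_len(P), each = n))
  prob1[cbind(flat, as.vector(k1))] <- off + lambda
  prob2[cbind(flat, as.vector(k2))] <- off + lambda

  new("GameteClassProb",
    map = truth@map, classes = classes, prob1 = prob1, prob2 = prob2,
    individuals = truth@individuals
  )
}

#' Simulate dosage grid directly from a population
#'
#' Convenience wrapper: blur the truth at informativeness `lambda` and
#' convert gamete classes to expected homologue dosages.
#'
#' @inheritParams inheritanceToProbabilities
#' @return A [HomologueDosage-class].
#' @export
simulateDosageGrid <- function(truth, lambda = 1) {
  classesToDosage(inheritanceToProbabilities(truth, lambda))
}

#' Simulate phenotypes for a population with a planted QTL
#'
#' Generates a replicated multi-year trial table under
#' `y_ijk = mu + sum_i alpha_i C_i + d 1[carrier] + g_i + year_k +
#' block_jk + (g x year)_ik + e_ijk`, where `C_i` is the true copy number
#' of homologue i at the QTL, `g_i` a clone-level polygenic effect,
#' and the remaining terms are independent Gaussian year, block-within-
#' year, clone-by-year and residual effects. Raw-measurement columns
#' (PFJ protein and tuber dry matter) are back-filled so that
#' [proteinContent()] applied to them reproduces the simulated trait.
#'
#' @param truth a [TrueInheritance-class].
#' @param qtl a [PlantedQTL-class] on the population's map.
#' @param years number of years (>= 1).
#' @param blocksPerYear replicates per year.
#' @param varPolygenic clone-level polygenic variance.
#' @param varGxY clone-by-year interaction variance.
#' @param varE residual variance.
#' @param varYear,varBlock year and block-within-year effect variances.
#'   The trial design terms the QTL models ignore; defaults are small on
#'   the scale of a trait with mean ~0.9.
#' @param dryMatterMean,dryMatterSD distribution of tuber dry matter (%)
#'   used to back-fill the raw-measurement columns.
#' @param seed integer seed; identical inputs give identical tables.
#' @return data.frame with columns `clone`, `year`, `block`,
#'   `pfj_protein`, `dry_matter`, `protein`.
#' @export
simulatePhenotypes <- function(truth, qtl, years = 1, blocksPerYear = 2,
                               varPolygenic = 0, varGxY = 0, varE = 0,
                               varYear = 5e-4, varBlock = 5e-4,
                               dryMatterMean = 22, dryMatterSD = 1,
                               seed = 1) {
  stopifnot(is(truth, "TrueInheritance"), is(qtl, "PlantedQTL"))
  set.seed(seed)
  copies <- homologueCopies(truth, qtl@chrom, qtl@cM)
  carrier <- if (length(qtl@qHomologues))
    as.numeric(rowSums(copies[, qtl@qHomologues, drop = FALSE]) > 0)
  else 0
  g <- qtl@mu + as.numeric(copies %*% qtl@effects) + qtl@dominance * carrier

  n <- length(truth@individuals)
  polyg <- rnorm(n, 0, sqrt(varPolygenic))
  yearEff <- rnorm(years, 0, sqrt(varYear))
  blockEff <- matrix(rnorm(years * blocksPerYear, 0, sqrt(varBlock)),
                     years, blocksPerYear)
  gxy <- matrix(rnorm(n * years, 0, sqrt(varGxY)), n, years)

  rec <- expand.grid(cloneIdx = seq_len(n), year = seq_len(years),
                     block = seq_len(blocksPerYear))
  y <- g[rec$cloneIdx] + polyg[rec$cloneIdx] +
    yearEff[rec$year] + blockEff[cbind(rec$year, rec$block)] +
    gxy[cbind(rec$cloneIdx, rec$year)] +
    rnorm(nrow(rec), 0, sqrt(varE))

  dm <- pmin(pmax(rnorm(nrow(rec), dryMatterMean, dryMatterSD), 1), 99)
  moisture <- 100 - dm
  data.frame(
    clone = truth@individuals[rec$cloneIdx],
    year = 2000L + rec$year,
    block = rec$block,
    pfj_protein = y * 100 / moisture,
    dry_matter = dm,
    protein = y,
    stringsAsFactors = FALSE
  )
}
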