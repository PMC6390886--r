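## Marker and individual quality control on SNP allele dosages before
## any map or IBD work: missing-rate filters plus a chi-square test of
## offspring segregation against the tetrasomic expectation.

#' Gamete dosage distribution of a tetraploid parent
#'
#' Under random bivalent pairing (no double reduction), a parent with
#' allele dosage d transmits a 2-chromosome gamete whose allele dosage k
#' is hypergeometric: `choose(d, k) choose(4 - d, 2 - k) / choose(4, 2)`.
#'
#' @param dosage parental allele dosage in 0..4.
#' @return numeric(3), probabilities of gamete dosage 0, 1, 2.
#' @export
gameteDosageDist <- function(dosage) {
  stopifnot(dosage %in% 0:4)
  k <- 0:2
  p <- choose(dosage, k) * choose(4 - dosage, 2 - k) / choose(4, 2)
  setNames(p, as.character(k))
}

#' Expected tetrasomic offspring segregation
#'
#' Convolution of the two parental gamete dosage distributions: the
#' expected distribution of offspring allele dosage 0..4 for a marker
#' with the given parental dosages, assuming random bivalent pairing.
#' E.g. simplex x nulliplex gives 1:1 for dosages 0:1 and duplex x
#' nulliplex gives 1:4:1 for dosages 0:1:2.
#'
#' @param parent1,parent2 parental allele dosages in 0..4.
#' @return numeric(5), probabilities of offspring dosage 0..4.
#' @examples
#' expectedSegregation(1, 0)  # 1:1 over dosages 0 and 1
#' expectedSegregation(2, 0)  # 1:4:1 over dosages 0, 1, 2
#' @export
expectedSegregation <- function(parent1, parent2) {
  g1 <- gameteDosageDist(parent1)
  g2 <- gameteDosageDist(parent2)
  out <- numeric(5)
  for (a in 0:2) for (b in 0:2)
    out[a + b + 1] <- out[a + b + 1] + g1[a + 1] * g2[b + 1]
  setNames(out, as.character(0:4))
}

#' Marker and individual QC on an allele dosage matrix
#'
#' Three filters, applied in order: (1) markers with more than
#' `maxMarkerMissing` missing values are dropped; (2) individuals with
#' more than `maxIndivMissing` missing values over the retained markers
#' are dropped; (3) markers whose offspring dosage counts deviate from
#' the tetrasomic expectation for their parental dosage pair
#' (chi-square goodness-of-fit at `segAlpha`) are dropped as skewed.
#' Offspring observed in dosage classes that are impossible under the
#' expectation also fail the segregation filter. The segregation null
#' assumes bivalent-only gametes; double reduction perturbs the ratios
#' far less than the test's sensitivity at typical population sizes.
#'
#' @param x a [DosageMatrix-class].
#' @param maxMarkerMissing maximum tolerated marker missing rate
#'   (default 0.05).
#' @param maxIndivMissing maximum tolerated individual missing rate
#'   (default 0.10).
#' @param segAlpha significance level of the segregation chi-square test
#'   (default 0.001).
#' @return list with `dosages` (the filtered [DosageMatrix-class]),
#'   `markers` (per-marker report: missing rate, segregation p-value,
#'   dropped flag and reason) and `individualsDropped`.
#' @export
qcMarkers <- function(x, maxMarkerMissing = 0.05, maxIndivMissing = 0.10,
                      segAlpha = 0.001) {
  stopifnot(is(x, "DosageMatrix"))
  d <- x@dosages
  mMiss <- rowMeans(is.na(d))
  keepM <- mMiss <= maxMarkerMissing
  iMiss <- colMeans(is.na(d[keepM, , drop = FALSE]))
  keepI <- iMiss <= maxIndivMissing

  pSeg <- rep(NA_real_, nrow(d))
  segFail <- rep(FALSE, nrow(d))
  for (m in which(keepM)) {
    obs <- tabulate(d[m, keepI] + 1L, nbins = 5L)
    if (sum(obs) == 0L) next
    expP <- expectedSegregation(x@parent1[m], x@parent2[m])
    possible <- expP > 0
    if (any(obs[!possible] > 0)) {
      segFail[m] <- TRUE
      pSeg[m] <- 0
      next
    }
    if (sum(possible) < 2L) next   # monomorphic expectation: nothing to test
    pSeg[m] <- suppressWarnings(
      chisq.test(obs[possible], p = expP[possible])$p.value)
    segFail[m] <- pSeg[m] < segAlpha
  }
  keep <- keepM & !segFail
  reason <- rep("", nrow(d))
  reason[!keepM] <- "missing_rate"
  reason[keepM & segFail] <- "segregation"
  report <- data.frame(
    marker = rownames(d),
    missingRate = mMiss,
    pSegregation = pSeg,
    dropped = !keep,
    reason = reason,
    stringsAsFactors = FALSE
  )
  filtered <- dosageMatrix(d[keep, keepI, drop = FALSE],
                           x@parent1[keep], x@parent2[keep])
  list(dosages = filtered, markers = report,
       individualsDropped = colnames(d)[!keepI])
}
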