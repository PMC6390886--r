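## Generics and accessor methods. Downstream code never touches slots
## directly outside this file and the constructors.

#' Grid positions of an object
#'
#' @param x a GeneticMap, TrueInheritance, GameteClassProb or
#'   HomologueDosage.
#' @return data.frame with columns `chrom` and `cM`.
#' @export
setGeneric("gridPositions", function(x) standardGeneric("gridPositions"))

#' @rdname gridPositions
#' @export
setMethod("gridPositions", "GeneticMap", function(x) x@grid)

#' @rdname gridPositions
#' @export
setMethod("gridPositions", "TrueInheritance", function(x) x@map@grid)

#' @rdname gridPositions
#' @export
setMethod("gridPositions", "GameteClassProb", function(x) x@map@grid)

#' @rdname gridPositions
#' @export
setMethod("gridPositions", "HomologueDosage", function(x) {
  as.data.frame(rowData(x))[, c("chrom", "cM")]
})

#' Chromosome names of an object
#' @param x a GeneticMap or an object carrying one.
#' @return character vector.
#' @export
setGeneric("chromosomeNames", function(x) standardGeneric("chromosomeNames"))

#' @rdname chromosomeNames
#' @export
setMethod("chromosomeNames", "GeneticMap", function(x) x@chromosomes)

#' @rdname chromosomeNames
#' @export
setMethod("chromosomeNames", "TrueInheritance", function(x) x@map@chromosomes)

#' @rdname chromosomeNames
#' @export
setMethod("chromosomeNames", "GameteClassProb", function(x) x@map@chromosomes)

#' @rdname chromosomeNames
#' @export
setMethod("chromosomeNames", "HomologueDosage", function(x) {
  unique(rowData(x)$chrom)
})

#' Chromosome lengths (cM) of a GeneticMap
#' @param x a [GeneticMap-class].
#' @return named numeric vector.
#' @export
chromosomeLengths <- function(x) {
  stopifnot(is(x, "GeneticMap"))
  setNames(x@lengths, x@chromosomes)
}

#' Number of individuals in an object
#' @param x a TrueInheritance, GameteClassProb or HomologueDosage.
#' @return integer(1).
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "TrueInheritance", function(x) length(x@individuals))

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "GameteClassProb", function(x) length(x@individuals))

#' @rdname nIndividuals
#' @export
setMethod("nIndividuals", "HomologueDosage", function(x) ncol(x))

#' Individual identifiers
#' @param x a TrueInheritance, GameteClassProb or HomologueDosage.
#' @return character vector.
#' @export
setGeneric("individualNames", function(x) standardGeneric("individualNames"))

#' @rdname individualNames
#' @export
setMethod("individualNames", "TrueInheritance", function(x) x@individuals)

#' @rdname individualNames
#' @export
setMethod("individualNames", "GameteClassProb", function(x) x@individuals)

#' @rdname individualNames
#' @export
setMethod("individualNames", "HomologueDosage", function(x) colnames(x))

## ---- position lookup -------------------------------------------------

## row index of (chrom, cM) in a grid data.frame; error when absent
.gridIndex <- function(grid, chrom, cM) {
  i <- which(grid$chrom == as.character(chrom) &
               abs(grid$cM - cM) < 1e-8)
  if (length(i) != 1L)
    stop("position ", chrom, ":", cM, " is not on the map grid")
  i
}

#' Homologue dosages of all individuals at one position
#'
#' @param x a [HomologueDosage-class].
#' @param chrom chromosome name.
#' @param cM position in cM (must be a grid position).
#' @return numeric matrix (individuals x 8) with columns X1..X8.
#' @export
dosageAt <- function(x, chrom, cM) {
  stopifnot(is(x, "HomologueDosage"))
  i <- .gridIndex(gridPositions(x), chrom, cM)
  out <- vapply(1:8, function(h) assay(x, h)[i, ], numeric(ncol(x)))
  colnames(out) <- paste0("X", 1:8)
  rownames(out) <- colnames(x)
  out
}

#' Gamete-class probabilities of all individuals at one position
#'
#' @param x a [GameteClassProb-class].
#' @param chrom chromosome name.
#' @param cM grid position in cM.
#' @return list with matrices `p1` and `p2` (individuals x classes).
#' @export
classProbsAt <- function(x, chrom, cM) {
  stopifnot(is(x, "GameteClassProb"))
  i <- .gridIndex(gridPositions(x), chrom, cM)
  p1 <- x@prob1[, i, , drop = TRUE]
  p2 <- x@prob2[, i, , drop = TRUE]
  if (is.null(dim(p1))) {   # single individual
    p1 <- matrix(p1, nrow = 1)
    p2 <- matrix(p2, nrow = 1)
  }
  colnames(p1) <- colnames(p2) <- x@classes
  rownames(p1) <- rownames(p2) <- x@individuals
  list(p1 = p1, p2 = p2)
}

#' Gamete class labels of a GameteClassProb
#' @param x a [GameteClassProb-class].
#' @return character vector of class labels.
#' @export
gameteClasses <- function(x) {
  stopifnot(is(x, "GameteClassProb"))
  x@classes
}

## ---- ScanResult accessors --------------------------------------------

#' LOD profile of a scan
#' @param x a [ScanResult-class].
#' @return data.frame with chrom, cM, LOD, R2, n per position.
#' @export
lodProfile <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@table
}

#' Fitted model-B coefficients of a scan
#' @param x a [ScanResult-class].
#' @return matrix (positions x 7).
#' @export
scanCoefficients <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@coefficients
}

#' Genome-wide LOD threshold stored in a scan
#' @param x a [ScanResult-class].
#' @return numeric(1), NA when no threshold has been attached.
#' @export
lodThreshold <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@threshold
}

#' Peaks stored in a scan
#' @param x a [ScanResult-class].
#' @return data.frame of peaks with LOD-2 intervals.
#' @export
scanPeaks <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@peaks
}

## ---- VarianceComponents accessors ------------------------------------

#' Extract variance-component estimates
#'
#' @param x a [VarianceComponents-class].
#' @param raw return the raw (possibly negative) estimates instead of the
#'   zero-floored ones?
#' @return named numeric with sigma2_G, sigma2_GxY (NA for within-year)
#'   and sigma2_E.
#' @export
componentEstimates <- function(x, raw = FALSE) {
  stopifnot(is(x, "VarianceComponents"))
  if (raw) x@raw
  else c(sigma2_G = x@sigma2G, sigma2_GxY = x@sigma2GxY,
         sigma2_E = x@sigma2E)
}

## ---- show methods -----------------------------------------------------

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@chromosomes), "chromosome(s),",
      sum(object@lengths), "cM total, grid step", object@step, "cM\n")
  cat("  ", nrow(object@grid), "grid positions\n")
})

setMethod("show", "MeiosisConfig", function(object) {
  cat("MeiosisConfig: quadrivalentRate =", object@quadrivalentRate,
      ", doubleReductionRate =", object@doubleReductionRate,
      "(Haldane recombination)\n")
})

setMethod("show", "TrueInheritance", function(object) {
  cat("TrueInheritance:", length(object@individuals), "individuals x",
      nrow(object@map@grid), "positions",
      if (object@quadrivalent) "(quadrivalents enabled)" else
        "(bivalents only)", "\n")
})

setMethod("show", "GameteClassProb", function(object) {
  cat("GameteClassProb:", length(object@individuals), "individuals x",
      nrow(object@map@grid), "positions,",
      length(object@classes), "gamete classes per parent\n")
})

setMethod("show", "PlantedQTL", function(object) {
  cat("PlantedQTL at", object@chrom, ":", object@cM, "cM; mu =",
      object@mu, "\n  effects:", paste(signif(object@effects, 3),
      collapse = " "), "\n")
  if (object@dominance != 0)
    cat("  dominance", object@dominance, "keyed to homologues",
        paste(object@qHomologues, collapse = ","), "\n")
})

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", nrow(object@table), "positions on",
      length(unique(object@table$chrom)), "chromosome(s)\n")
  cat("  max LOD:", round(max(object@table$LOD), 2), "at",
      object@table$chrom[which.max(object@table$LOD)], ":",
      object@table$cM[which.max(object@table$LOD)], "cM\n")
  if (!is.na(object@threshold))
    cat("  threshold:", round(object@threshold, 2),
        "(", object@nPerm, "permutations, alpha =", object@alpha, ")\n")
  if (nrow(object@peaks))
    cat("  peaks:", nrow(object@peaks), "above threshold\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", object@model, "-year model )\n", sep = "")
  est <- componentEstimates(object)
  for (nm in names(est))
    if (!is.na(est[[nm]])) cat(" ", nm, "=", signif(est[[nm]], 4), "\n")
  cat("  r =", object@r, ", y =", object@y, "\n")
})

setMethod("show", "DosageMatrix", function(object) {
  cat("DosageMatrix:", nrow(object@dosages), "markers x",
      ncol(object@dosages), "individuals\n")
})
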