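## Central S4 classes. All user-visible state goes through accessors in
## AllGenerics.R; slots are implementation detail.

#' GeneticMap: a chromosome-level genetic map with an evaluation grid
#'
#' Holds chromosome names, lengths in centiMorgan and the regular cM grid
#' at which IBD probabilities and scans are evaluated. Positions are
#' 0-based from the first mapped position of each chromosome and rounded
#' to 0.1 cM.
#'
#' @slot chromosomes character, chromosome names.
#' @slot lengths numeric, map length of each chromosome in cM.
#' @slot step numeric(1), grid step in cM.
#' @slot grid data.frame with columns `chrom` and `cM`, strictly
#'   increasing within chromosome.
#' @export
setClass("GeneticMap",
  representation(
    chromosomes = "character",
    lengths = "numeric",
    step = "numeric",
    grid = "data.frame"
  )
)

setValidity("GeneticMap", function(object) {
  msg <- character()
  if (length(object@chromosomes) != length(object@lengths))
    msg <- c(msg, "one length per chromosome required")
  if (any(object@lengths <= 0))
    msg <- c(msg, "chromosome lengths must be > 0")
  if (anyDuplicated(object@chromosomes))
    msg <- c(msg, "duplicated chromosome names")
  if (length(object@step) != 1L || object@step <= 0)
    msg <- c(msg, "step must be a single positive number")
  if (!all(c("chrom", "cM") %in% names(object@grid)))
    msg <- c(msg, "grid must have columns 'chrom' and 'cM'")
  else {
    byChr <- split(object@grid$cM, object@grid$chrom)
    if (!all(vapply(byChr, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "grid positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneticMap
#'
#' @param lengths named numeric vector of chromosome lengths in cM; names
#'   are chromosome names (defaults to `"1"`, `"2"`, ...).
#' @param step grid step in cM (default 1).
#' @return A [GeneticMap-class] object whose grid runs from 0 to the
#'   chromosome length at `step` intervals, rounded to 0.1 cM.
#' @examples
#' map <- geneticMap(c(chr1 = 100, chr2 = 80))
#' head(gridPositions(map))
#' @export
geneticMap <- function(lengths, step = 1) {
  if (is.null(names(lengths)))
    names(lengths) <- as.character(seq_along(lengths))
  grid <- do.call(rbind, lapply(names(lengths), function(ch) {
    cm <- round(seq(0, lengths[[ch]], by = step), 1)
    data.frame(chrom = ch, cM = cm, stringsAsFactors = FALSE)
  }))
  new("GeneticMap",
    chromosomes = names(lengths),
    lengths = unname(lengths),
    step = step,
    grid = grid
  )
}

#' MeiosisConfig: parameters of one parent's tetrasomic meiosis
#'
#' @slot quadrivalentRate probability per meiosis per chromosome that the
#'   four homologues pair as a quadrivalent rather than two bivalents.
#' @slot doubleReductionRate probability, at a given locus of a
#'   quadrivalent-derived gamete, that the two chromatids are copies of the
#'   same parental homologue (a double-reduction product). Bounded by the
#'   theoretical maximum of 1/4.
#' @export
setClass("MeiosisConfig",
  representation(
    quadrivalentRate = "numeric",
    doubleReductionRate = "numeric"
  )
)

setValidity("MeiosisConfig", function(object) {
  msg <- character()
  q <- object@quadrivalentRate
  d <- object@doubleReductionRate
  if (length(q) != 1L || is.na(q) || q < 0 || q > 1)
    msg <- c(msg, "quadrivalentRate must be in [0, 1]")
  if (length(d) != 1L || is.na(d) || d < 0 || d > 0.25)
    msg <- c(msg, "doubleReductionRate must be in [0, 0.25]")
  if (length(msg)) msg else TRUE
})

#' Construct a MeiosisConfig
#'
#' Recombination always follows Haldane's map function (crossover count
#' Poisson with mean map length in Morgan, no interference).
#'
#' @param quadrivalentRate probability of quadrivalent pairing, in \[0, 1\].
#' @param doubleReductionRate per-locus double-reduction probability of a
#'   quadrivalent gamete, in \[0, 0.25\].
#' @return A [MeiosisConfig-class] object.
#' @export
meiosisConfig <- function(quadrivalentRate = 0, doubleReductionRate = 0) {
  new("MeiosisConfig",
    quadrivalentRate = quadrivalentRate,
    doubleReductionRate = doubleReductionRate
  )
}

#' TrueInheritance: realized parental homologue transmission of an F1
#' population
#'
#' For every individual and grid position, the unordered pair of parent-1
#' homologues (labels 1..4) and parent-2 homologues (labels 5..8) carried.
#' A pair repeats a label only for double-reduction products.
#'
#' @slot map the [GeneticMap-class].
#' @slot h1a,h1b integer matrices (individuals x positions), parent-1
#'   labels in 1..4 with `h1a <= h1b`.
#' @slot h2a,h2b integer matrices, parent-2 labels in 5..8.
#' @slot quadrivalent logical(1), whether quadrivalent meiosis (and hence
#'   double reduction) was enabled for either parent.
#' @slot individuals character, individual identifiers.
#' @export
setClass("TrueInheritance",
  representation(
    map = "GeneticMap",
    h1a = "matrix", h1b = "matrix",
    h2a = "matrix", h2b = "matrix",
    quadrivalent = "logical",
    individuals = "character"
  )
)

setValidity("TrueInheritance", function(object) {
  msg <- character()
  dims <- lapply(list(object@h1a, object@h1b, object@h2a, object@h2b), dim)
  if (length(unique(dims)) != 1L)
    msg <- c(msg, "label matrices must share dimensions")
  if (nrow(object@h1a) != length(object@individuals))
    msg <- c(msg, "one row per individual required")
  if (ncol(object@h1a) != nrow(object@map@grid))
    msg <- c(msg, "one column per grid position required")
  if (!all(object@h1a %in% 1:4 & object@h1b %in% 1:4))
    msg <- c(msg, "parent-1 labels must be in 1..4")
  if (!all(object@h2a %in% 5:8 & object@h2b %in% 5:8))
    msg <- c(msg, "parent-2 labels must be in 5..8")
  if (any(object@h1a > object@h1b) || any(object@h2a > object@h2b))
    msg <- c(msg, "label pairs must be sorted")
  if (!object@quadrivalent &&
      (any(object@h1a == object@h1b) || any(object@h2a == object@h2b)))
    msg <- c(msg, "repeated labels require quadrivalent meiosis")
  if (length(msg)) msg else TRUE
})

#' PlantedQTL: a known QTL injected into simulated phenotypes
#'
#' The single-locus model is
#' `y = mu + sum_i alpha_i X_i + d * 1[Q carrier]`, where `X_i` is the
#' copy number of parental homologue i (parent 1: i = 1..4, parent 2:
#' i = 5..8) at the QTL position, `alpha_i` are per-copy homologue
#' effects and `d` an optional dominance deviation for individuals
#' carrying at least one copy of a Q-labelled homologue.
#'
#' @slot chrom chromosome name.
#' @slot cM position in cM (must lie on the map grid).
#' @slot effects numeric(8), per-copy effects alpha_1..alpha_8 in trait
#'   units.
#' @slot dominance numeric(1), dominance deviation `d` in trait units.
#' @slot qHomologues integer, the homologues labelled Q for the carrier
#'   indicator (may be empty when `dominance` is 0).
#' @slot mu numeric(1), intercept (population mean in the absence of
#'   effects).
#' @export
setClass("PlantedQTL",
  representation(
    chrom = "character",
    cM = "numeric",
    effects = "numeric",
    dominance = "numeric",
    qHomologues = "integer",
    mu = "numeric"
  )
)

setValidity("PlantedQTL", function(object) {
  msg <- character()
  if (length(object@effects) != 8L || any(!is.finite(object@effects)))
    msg <- c(msg, "effects must be 8 finite values")
  if (!is.finite(object@mu) || !is.finite(object@dominance))
    msg <- c(msg, "mu and dominance must be finite")
  if (length(object@qHomologues) &&
      !all(object@qHomologues %in% 1:8))
    msg <- c(msg, "qHomologues must be in 1..8")
  if (length(msg)) msg else TRUE
})

#' Construct a PlantedQTL
#'
#' @param chrom chromosome name.
#' @param cM map position in cM.
#' @param effects numeric(8) per-copy homologue effects, or a named sparse
#'   specification like `c("6" = 0.3)` (unnamed homologues get 0).
#' @param dominance dominance deviation (default 0).
#' @param qHomologues homologues regarded as carrying the Q allele for the
#'   dominance indicator; defaults to the homologues with non-zero
#'   additive effect.
#' @param mu intercept in trait units.
#' @return A [PlantedQTL-class].
#' @examples
#' qtl <- plantedQTL("chr1", 50, effects = c("6" = 0.3), mu = 0.93)
#' @export
plantedQTL <- function(chrom, cM, effects = numeric(8), dominance = 0,
                       qHomologues = NULL, mu = 0) {
  if (!is.null(names(effects))) {
    eff <- numeric(8)
    eff[as.integer(names(effects))] <- effects
    effects <- eff
  }
  if (is.null(qHomologues)) qHomologues <- which(effects != 0)
  new("PlantedQTL",
    chrom = as.character(chrom), cM = cM, effects = effects,
    dominance = dominance, qHomologues = as.integer(qHomologues), mu = mu
  )
}

#' GameteClassProb: per-parent gamete-class probabilities of an F1
#' population
#'
#' The primary IBD object: for every individual and grid position, a
#' probability distribution over the ordered parental gamete classes.
#' Each parent contributes 6 bivalent-derived classes (unordered pairs of
#' distinct homologues: 12, 13, 14, 23, 24, 34) plus, when quadrivalent
#' meiosis is enabled, 4 double-reduction classes (11, 22, 33, 44). This
#' emulates the posterior output of probabilistic haplotype reconstruction
#' from SNP dosages (e.g. TetraOrigin).
#'
#' @slot map the [GeneticMap-class].
#' @slot classes character vector of class labels (parent-local homologue
#'   numbering 1..4).
#' @slot prob1,prob2 numeric arrays (individuals x positions x classes)
#'   for parent 1 and parent 2; each per-parent vector sums to 1.
#' @slot individuals character identifiers.
#' @export
setClass("GameteClassProb",
  representation(
    map = "GeneticMap",
    classes = "character",
    prob1 = "array",
    prob2 = "array",
    individuals = "character"
  )
)

setValidity("GameteClassProb", function(object) {
  msg <- character()
  d1 <- dim(object@prob1); d2 <- dim(object@prob2)
  if (!identical(d1, d2))
    msg <- c(msg, "prob1 and prob2 must share dimensions")
  if (d1[3] != length(object@classes))
    msg <- c(msg, "third dimension must match the class labels")
  if (d1[1] != length(object@individuals))
    msg <- c(msg, "first dimension must match individuals")
  if (d1[2] != nrow(object@map@grid))
    msg <- c(msg, "second dimension must match the map grid")
  if (min(object@prob1, object@prob2) < 0)
    msg <- c(msg, "probabilities must be non-negative")
  s1 <- rowSums(object@prob1, dims = 2)
  s2 <- rowSums(object@prob2, dims = 2)
  if (max(abs(s1 - 1), abs(s2 - 1)) > 1e-9)
    msg <- c(msg, "per-parent class probabilities must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' HomologueDosage: expected parental homologue dosages on a cM grid
#'
#' A [SummarizedExperiment::SummarizedExperiment-class] with eight assays
#' `X1`..`X8`: rows are grid positions (rowData columns `chrom`, `cM`),
#' columns are individuals, and assay `Xi` holds the expected copy number
#' of parental homologue i (parent 1: X1..X4, parent 2: X5..X8). At every
#' individual and position the parental dosages satisfy
#' `X1 + X2 + X3 + X4 = 2` and `X5 + X6 + X7 + X8 = 2`, with each
#' `Xi` in \[0, 2\]. This is the predictor object of the single-locus QTL
#' models.
#'
#' @export
setClass("HomologueDosage", contains = "SummarizedExperiment")

setValidity("HomologueDosage", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!identical(an, paste0("X", 1:8)))
    return("assays must be X1..X8, in order")
  if (!all(c("chrom", "cM") %in% names(rowData(object))))
    return("rowData must contain 'chrom' and 'cM'")
  tol <- 1e-6
  s1 <- assay(object, "X1") + assay(object, "X2") +
    assay(object, "X3") + assay(object, "X4")
  s2 <- assay(object, "X5") + assay(object, "X6") +
    assay(object, "X7") + assay(object, "X8")
  if (max(abs(s1 - 2)) > tol || max(abs(s2 - 2)) > tol)
    msg <- c(msg, "parental dosages must sum to 2 per individual and position")
  rng <- range(vapply(1:8, function(i) range(assay(object, i)), numeric(2)))
  if (rng[1] < -tol || rng[2] > 2 + tol)
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' Construct a HomologueDosage from per-homologue matrices
#'
#' @param assays list of 8 matrices (positions x individuals), one per
#'   homologue X1..X8.
#' @param chrom,cM position annotation, one value per row.
#' @param individuals column (individual) names.
#' @return A [HomologueDosage-class].
#' @export
homologueDosage <- function(assays, chrom, cM, individuals = NULL) {
  stopifnot(length(assays) == 8L)
  names(assays) <- paste0("X", 1:8)
  if (!is.null(individuals))
    assays <- lapply(assays, function(a) { colnames(a) <- individuals; a })
  rn <- paste0(chrom, "_", format(cM, trim = TRUE))
  assays <- lapply(assays, function(a) { rownames(a) <- rn; a })
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(chrom = as.character(chrom), cM = as.numeric(cM))
  )
  new("HomologueDosage", se)
}

#' ScanResult: per-position statistics of a single-locus QTL scan
#'
#' @slot table data.frame with one row per grid position: `chrom`, `cM`,
#'   `LOD`, `R2`, `n` (phenotyped individuals used).
#' @slot coefficients matrix (positions x 7) of fitted model-B
#'   coefficients: intercept and the retained homologue-dosage terms
#'   a2, a3, a4, a6, a7, a8.
#' @slot threshold numeric(1), genome-wide LOD threshold (NA until set).
#' @slot peaks data.frame of per-chromosome peaks with LOD-2 support
#'   intervals (empty until [findPeaks()] is applied).
#' @slot nPerm,alpha permutation settings backing `threshold`.
#' @export
setClass("ScanResult",
  representation(
    table = "data.frame",
    coefficients = "matrix",
    threshold = "numeric",
    peaks = "data.frame",
    nPerm = "integer",
    alpha = "numeric"
  ),
  prototype(
    threshold = NA_real_,
    peaks = data.frame(),
    nPerm = NA_integer_,
    alpha = NA_real_
  )
)

setValidity("ScanResult", function(object) {
  msg <- character()
  need <- c("chrom", "cM", "LOD", "R2", "n")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must contain", paste(need, collapse = ", ")))
  else {
    if (any(object@table$LOD < 0, na.rm = TRUE))
      msg <- c(msg, "LOD must be non-negative")
    if (any(object@table$R2 < -1e-12 | object@table$R2 > 1 + 1e-12,
            na.rm = TRUE))
      msg <- c(msg, "R2 must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' VarianceComponents: ANOVA variance components of a trait
#'
#' Estimates are reported floored at zero (the standard convention for
#' method-of-moments ANOVA estimators), with the raw values retained.
#'
#' @slot model "within" (one-way, single year) or "between" (two-way,
#'   multiple years).
#' @slot sigma2G,sigma2GxY,sigma2E floored estimates of the clone,
#'   clone-by-year and residual variance (trait-squared units);
#'   `sigma2GxY` is NA for the within-year model.
#' @slot raw named numeric of raw (unfloored) estimates.
#' @slot meanSquares named numeric of the mean squares used.
#' @slot r number of replicates (blocks), `y` number of years.
#' @slot y number of years.
#' @export
setClass("VarianceComponents",
  representation(
    model = "character",
    sigma2G = "numeric",
    sigma2GxY = "numeric",
    sigma2E = "numeric",
    raw = "numeric",
    meanSquares = "numeric",
    r = "numeric",
    y = "numeric"
  )
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (!object@model %in% c("within", "between"))
    msg <- c(msg, "model must be 'within' or 'between'")
  if (object@r < 1 || object@y < 1)
    msg <- c(msg, "r and y must be >= 1")
  if (length(msg)) msg else TRUE
})

#' DosageMatrix: integer SNP allele dosages of an F1 population
#'
#' Marker-by-individual allele dosage scores in 0..4 (NA = missing), with
#' the parental dosages per marker. Input to marker QC.
#'
#' @slot dosages integer matrix, markers x individuals.
#' @slot parent1,parent2 integer parental dosages per marker, in 0..4.
#' @export
setClass("DosageMatrix",
  representation(
    dosages = "matrix",
    parent1 = "integer",
    parent2 = "integer"
  )
)

setValidity("DosageMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (!all(d[!is.na(d)] %in% 0:4))
    msg <- c(msg, "offspring dosages must be in 0..4 or NA")
  if (length(object@parent1) != nrow(d) || length(object@parent2) != nrow(d))
    msg <- c(msg, "one parental dosage per marker required")
  if (anyNA(object@parent1) || anyNA(object@parent2) ||
      !all(c(object@parent1, object@parent2) %in% 0:4))
    msg <- c(msg, "parental dosages must be known and in 0..4")
  if (length(msg)) msg else TRUE
})

#' Construct a DosageMatrix
#'
#' @param dosages markers x individuals matrix of dosages in 0..4 (NA =
#'   missing). Row names are marker names, column names individuals.
#' @param parent1,parent2 parental dosages, one per marker.
#' @return A [DosageMatrix-class].
#' @export
dosageMatrix <- function(dosages, parent1, parent2) {
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("m", seq_len(nrow(dosages)))
  new("DosageMatrix",
    dosages = dosages,
    parent1 = as.integer(parent1),
    parent2 = as.integer(parent2)
  )
}
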