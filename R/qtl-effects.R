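## Homologue-effect estimation at a QTL position, and the exhaustive
## bi-allelic (Q/q) model search ranked by the Schwarz information
## criterion.

#' Average homologue effects at a position
#'
#' For each of the 8 parental homologues, the IBD-probability-weighted
#' trait mean `hbar_i = sum_n pi_in y_n / sum_n pi_in` with weights
#' `pi_in = X_in / 2` (the probability of carrying homologue i, up to
#' double-reduction corrections), and the effect `hbar_i - ybar` against
#' the population mean. The weighted effects sum to zero because the
#' per-individual weights sum to 2 per parent.
#'
#' @param y phenotype vector (names matched against the dosage
#'   individuals when available).
#' @param dosage a [HomologueDosage-class], or directly an
#'   (individuals x 8) dosage matrix.
#' @param chrom,cM position (required when `dosage` is a
#'   HomologueDosage).
#' @return data.frame with one row per homologue: `homologue`, `hbar`,
#'   `effect`, `weight` (= sum of pi_i).
#' @export
homologueEffects <- function(y, dosage, chrom = NULL, cM = NULL) {
  X <- if (is(dosage, "HomologueDosage")) {
    stopifnot(!is.null(chrom), !is.null(cM))
    dosageAt(dosage, chrom, cM)
  } else dosage
  stopifnot(is.matrix(X), ncol(X) == 8L)
  if (!is.null(names(y)) && !is.null(rownames(X))) {
    stopifnot(all(names(y) %in% rownames(X)))
    X <- X[names(y), , drop = FALSE]
  } else stopifnot(length(y) == nrow(X))
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  pi <- X / 2
  w <- colSums(pi)
  if (any(w == 0))
    stop("zero total weight for homologue(s): ",
         paste(which(w == 0), collapse = ", "))
  hbar <- as.numeric(crossprod(pi, y)) / w
  data.frame(
    homologue = 1:8,
    hbar = hbar,
    effect = hbar - mean(y),
    weight = w
  )
}

## canonical form of a Q/q assignment: flip Q<->q so homologue 1 is q
.canonicalAssignment <- function(v) {
  if (v[1L]) !v else v
}

.genotypeString <- function(v4) {
  nQ <- sum(v4)
  paste0(strrep("Q", nQ), strrep("q", 4 - nQ))
}

#' Enumerate candidate bi-allelic QTL models
#'
#' All 2^8 assignments of alleles Q/q to the 8 parental homologues,
#' de-duplicated under the global Q<->q swap (canonical form: homologue 1
#' carries q) and with non-segregating assignments (both parents
#' homozygous) removed. Each assignment is emitted twice, once with
#' additive coding and once with additive + dominance coding.
#'
#' @return data.frame with columns `Q1`..`Q8` (logical: homologue
#'   carries Q), `parent1`, `parent2` (genotype strings such as
#'   `"QQQq"`), `cross` (e.g. `"qqqq x Qqqq"`) and `coding`
#'   (`"additive"` or `"additive+dominance"`).
#' @export
enumerateBiallelicModels <- function() {
  grids <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))
  colnames(grids) <- paste0("Q", 1:8)
  canon <- t(apply(grids, 1, .canonicalAssignment))
  canon <- unique(canon)
  seg <- apply(canon, 1, function(v) {
    p1 <- sum(v[1:4]); p2 <- sum(v[5:8])
    !(p1 %in% c(0L, 4L) && p2 %in% c(0L, 4L))
  })
  canon <- canon[seg, , drop = FALSE]
  base <- as.data.frame(canon)
  base$parent1 <- apply(canon[, 1:4, drop = FALSE], 1, .genotypeString)
  base$parent2 <- apply(canon[, 5:8, drop = FALSE], 1, .genotypeString)
  base$cross <- paste(base$parent1, "x", base$parent2)
  out <- rbind(
    cbind(base, coding = "additive", stringsAsFactors = FALSE),
    cbind(base, coding = "additive+dominance", stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

## probability of zero Q copies in the gamete from one parent, from
## gamete-class probabilities (exact) at one position
.probZeroQ <- function(classProbs, qLocal) {
  classes <- colnames(classProbs)
  zero <- vapply(classes, function(cl) {
    a <- as.integer(substr(cl, 1, 1))
    b <- as.integer(substr(cl, 2, 2))
    !(a %in% qLocal) && !(b %in% qLocal)
  }, logical(1))
  rowSums(classProbs[, zero, drop = FALSE])
}

#' Fit one bi-allelic QTL model at a position
#'
#' The additive predictor is the expected Q dosage (sum of the dosages of
#' the Q-labelled homologues, in 0..4). The dominance predictor is the
#' probability of carrying at least one Q copy, computed exactly from the
#' gamete-class probabilities when supplied; otherwise a
#' products-of-marginals approximation from the dosages is used and
#' flagged. The fit is ordinary least squares; the Schwarz information
#' criterion is `SIC = n ln(RSS/n) + k ln(n)` with k the number of
#' fitted parameters including the intercept.
#'
#' @param y phenotype vector (no NAs after alignment).
#' @param X (individuals x 8) dosage matrix at the position.
#' @param Q logical(8), the Q-labelled homologues.
#' @param coding `"additive"` or `"additive+dominance"`.
#' @param classProbs optional list with `p1`, `p2` matrices from
#'   [classProbsAt()] for the exact dominance predictor.
#' @return list with `coding`, `coefficients`, `RSS`, `SIC`, `k`, `n`,
#'   `alleleClassMeans` (fitted trait mean at each integer Q dosage
#'   observed) and `dominanceApprox` (TRUE when the marginal
#'   approximation was used).
#' @export
fitBiallelicModel <- function(y, X, Q, coding = c("additive",
                                                  "additive+dominance"),
                              classProbs = NULL) {
  coding <- match.arg(coding)
  stopifnot(is.matrix(X), ncol(X) == 8L, length(Q) == 8L)
  keep <- !is.na(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  add <- rowSums(X[, Q, drop = FALSE])
  if (max(add) - min(add) < 1e-10)
    stop("degenerate additive predictor (zero variance)")
  design <- cbind(`(Intercept)` = 1, add = add)
  approxDom <- FALSE
  if (coding == "additive+dominance") {
    if (!is.null(classProbs)) {
      z1 <- .probZeroQ(classProbs$p1[keep, , drop = FALSE], which(Q[1:4]))
      z2 <- .probZeroQ(classProbs$p2[keep, , drop = FALSE],
                       which(Q[5:8]))
    } else {
      ## marginal approximation: parent gamete as two independent draws
      d1 <- pmin(rowSums(X[, 1:4, drop = FALSE][, Q[1:4], drop = FALSE]), 2)
      d2 <- pmin(rowSums(X[, 5:8, drop = FALSE][, Q[5:8], drop = FALSE]), 2)
      z1 <- (1 - d1 / 2)^2
      z2 <- (1 - d2 / 2)^2
      approxDom <- TRUE
    }
    dom <- 1 - z1 * z2   # P(at least one Q copy)
    if (max(dom) - min(dom) < 1e-10)
      stop("degenerate dominance predictor (zero variance)")
    design <- cbind(design, dom = dom)
  }
  fit <- fitPosition(y, design)
  k <- ncol(design)
  sic <- n * log(fit$RSS1 / n) + k * log(n)
  lev <- sort(unique(round(add)))
  acm <- setNames(
    fit$coefficients[["(Intercept)"]] + fit$coefficients[["add"]] * lev,
    paste0("Qdosage", lev)
  )
  list(coding = coding, coefficients = fit$coefficients, RSS = fit$RSS1,
       SIC = sic, k = k, n = n, alleleClassMeans = acm,
       dominanceApprox = approxDom)
}

#' Exhaustive bi-allelic model search at a position
#'
#' Fits every canonical segregating Q/q assignment (see
#' [enumerateBiallelicModels()]) in both codings and ranks them by SIC.
#' Assignments whose predictors are degenerate at this position (zero
#' variance) are skipped.
#'
#' @param y phenotype vector.
#' @param dosage a [HomologueDosage-class].
#' @param chrom,cM the position to analyse.
#' @param classProbs optional [GameteClassProb-class] for the exact
#'   dominance predictor.
#' @return data.frame of fitted models with `cross`, `coding`, `RSS`,
#'   `k`, `SIC`, `deltaSIC` and `evidence` columns, sorted by SIC (see
#'   [modelEvidence()]); allele assignments in columns `Q1`..`Q8`.
#' @export
biallelicModelSearch <- function(y, dosage, chrom, cM,
                                 classProbs = NULL) {
  stopifnot(is(dosage, "HomologueDosage"))
  X <- dosageAt(dosage, chrom, cM)
  y <- .alignPhenotype(y, dosage)
  cp <- if (!is.null(classProbs)) {
    stopifnot(is(classProbs, "GameteClassProb"))
    classProbsAt(classProbs, chrom, cM)
  }
  models <- enumerateBiallelicModels()
  qcols <- paste0("Q", 1:8)
  fits <- lapply(seq_len(nrow(models)), function(i) {
    Q <- as.logical(unlist(models[i, qcols]))
    tryCatch(
      fitBiallelicModel(y, X, Q, coding = models$coding[i],
                        classProbs = cp),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  models <- models[ok, , drop = FALSE]
  fits <- fits[ok]
  if (!length(fits)) stop("no non-degenerate bi-allelic model at this position")
  models$RSS <- vapply(fits, `[[`, numeric(1), "RSS")
  models$k <- vapply(fits, `[[`, numeric(1), "k")
  models$SIC <- vapply(fits, `[[`, numeric(1), "SIC")
  models$dominanceApprox <- vapply(fits, `[[`, logical(1),
                                   "dominanceApprox")
  modelEvidence(models)
}

#' Rank bi-allelic models by SIC differences
#'
#' Adds `deltaSIC = SIC - min(SIC)` and sorts. The strength of support
#' for the best model is judged from the runner-up difference: below 2
#' the evidence is labelled `"weak"` (competing models are essentially
#' indistinguishable), 2-6 `"positive"`, 6-10 `"strong"`, above 10
#' `"decisive"`.
#'
#' @param models data.frame with at least an `SIC` column.
#' @return the data.frame sorted by SIC with `deltaSIC` and (first row)
#'   `evidence` columns.
#' @export
modelEvidence <- function(models) {
  if (!nrow(models)) stop("empty model list")
  models <- models[order(models$SIC), , drop = FALSE]
  models$deltaSIC <- models$SIC - models$SIC[1L]
  runnerUp <- if (nrow(models) > 1L) models$deltaSIC[2L] else Inf
  models$evidence <- NA_character_
  models$evidence[1L] <-
    if (runnerUp < 2) "weak"
    else if (runnerUp < 6) "positive"
    else if (runnerUp < 10) "strong"
    else "decisive"
  rownames(models) <- NULL
  models
}
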