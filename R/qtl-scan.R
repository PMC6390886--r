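## The naive single-locus genome scan: at every grid position the
## phenotype is regressed on the expected homologue dosages under the
## reduced "model B" parameterization (one dosage column dropped per
## parent to remove the sum-to-2 collinearity), and the fit is expressed
## as a LOD score against the intercept-only null.

.MODEL_B_COLUMNS <- c(2L, 3L, 4L, 6L, 7L, 8L)

#' Model-B design matrix at one position
#'
#' Because the parental dosages obey `X1+X2+X3+X4 = 2` and
#' `X5+X6+X7+X8 = 2`, the full 8-term additive model is
#' over-parameterized; one term per parent (here X1 and X5) is dropped.
#' The choice of dropped columns does not affect the residual sum of
#' squares or the LOD.
#'
#' @param X numeric matrix (individuals x 8) of homologue dosages, e.g.
#'   from [dosageAt()].
#' @param tol tolerance on the parental sum constraints.
#' @return design matrix (individuals x 7): intercept plus
#'   X2, X3, X4, X6, X7, X8. Columns with (near) zero variance are
#'   flagged in the `"zeroVariance"` attribute.
#' @export
designMatrixModelB <- function(X, tol = 1e-6) {
  stopifnot(is.matrix(X), ncol(X) == 8L)
  s1 <- rowSums(X[, 1:4, drop = FALSE])
  s2 <- rowSums(X[, 5:8, drop = FALSE])
  if (max(abs(s1 - 2)) > tol || max(abs(s2 - 2)) > tol)
    stop("dosage constraint violated: parental sums differ from 2")
  M <- cbind(1, X[, .MODEL_B_COLUMNS, drop = FALSE])
  colnames(M) <- c("(Intercept)", paste0("X", .MODEL_B_COLUMNS))
  zv <- c(FALSE, apply(M[, -1, drop = FALSE], 2, function(v)
    max(v) - min(v) < tol))
  attr(M, "zeroVariance") <- zv
  M
}

#' Least-squares fit at one position
#'
#' Ordinary least squares of the phenotype on a design matrix, with
#' rank-deficient designs resolved by the minimum-norm solution (SVD
#' pseudo-inverse), plus the intercept-only null fit.
#'
#' @param y numeric phenotype vector (no NAs).
#' @param design design matrix including an intercept column, as from
#'   [designMatrixModelB()].
#' @return list with `coefficients`, `fitted`, `RSS1` (full model
#'   residual sum of squares), `RSS0` (intercept-only) and `n`.
#' @export
fitPosition <- function(y, design) {
  n <- length(y)
  if (n < 8L) stop("at least 8 phenotyped individuals required")
  stopifnot(nrow(design) == n)
  sv <- svd(design)
  tol <- max(dim(design)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  coefs <- sv$v[, keep, drop = FALSE] %*%
    (crossprod(sv$u[, keep, drop = FALSE], y) / sv$d[keep])
  fit <- as.numeric(design %*% coefs)
  list(
    coefficients = setNames(as.numeric(coefs), colnames(design)),
    fitted = fit,
    RSS1 = sum((y - fit)^2),
    RSS0 = sum((y - mean(y))^2),
    n = n
  )
}

#' LOD score from residual sums of squares
#'
#' `LOD = (n/2) log10(RSS0 / RSS1)`, with the degenerate case
#' `RSS0 = RSS1` (including 0/0 for a constant phenotype) defined as 0.
#' Equivalently `LOD = -(n/2) log10(1 - R2)`.
#'
#' @param n number of individuals in the fit.
#' @param rss0 residual sum of squares of the null (no-QTL) model.
#' @param rss1 residual sum of squares of the full model.
#' @return non-negative LOD score (Inf for a perfect fit).
#' @examples
#' lodScore(20, 2.0, 0.2)  # 10
#' @export
lodScore <- function(n, rss0, rss1) {
  if (rss1 < 0) stop("RSS1 must be non-negative")
  if (rss0 < rss1 - 1e-12 * max(rss0, 1))
    stop("RSS0 must be >= RSS1")
  if (rss0 == rss1) return(0)
  if (rss1 == 0) return(Inf)
  max(0, n / 2 * log10(rss0 / rss1))
}

## Orthonormal bases of the model-B column spaces at every position.
## Precomputing these makes a scan a single matrix product per position,
## which is what keeps permutation thresholds cheap.
.scanBases <- function(dosage, keep) {
  P <- nrow(dosage)
  asys <- lapply(1:8, function(h) assay(dosage, h)[, keep, drop = FALSE])
  nk <- sum(keep)
  lapply(seq_len(P), function(p) {
    X <- vapply(asys, function(a) a[p, ], numeric(nk))
    M <- designMatrixModelB(X)
    qrM <- qr(M)
    qr.Q(qrM)[, seq_len(qrM$rank), drop = FALSE]
  })
}

## Align a phenotype vector with the dosage columns: match by name when
## named, else require equal length.
.alignPhenotype <- function(y, dosage) {
  ids <- colnames(dosage)
  if (!is.null(names(y)) && !is.null(ids)) {
    if (!all(names(y) %in% ids))
      stop("phenotype names do not match dosage individuals")
    out <- setNames(rep(NA_real_, ncol(dosage)), ids)
    out[names(y)] <- y
    out
  } else {
    if (length(y) != ncol(dosage))
      stop("phenotype length (", length(y),
           ") does not match individuals (", ncol(dosage), ")")
    y
  }
}

#' Naive single-locus QTL scan
#'
#' At every grid position, fits the model-B regression of the phenotype
#' on the retained homologue dosages and records the LOD score,
#' `R2 = 1 - RSS1/RSS0` and the fitted coefficients. Missing phenotypes
#' are dropped (the number used enters the LOD formula). Positions are
#' fitted by minimum-norm least squares so uninformative regions do not
#' change the model dimension.
#'
#' @param y phenotype vector; if named, names are matched against the
#'   dosage individuals.
#' @param dosage a [HomologueDosage-class].
#' @return A [ScanResult-class] (no threshold or peaks attached yet).
#' @seealso [runNaiveScan()] for the scan + threshold + peaks pipeline.
#' @export
qtlScan <- function(y, dosage) {
  stopifnot(is(dosage, "HomologueDosage"))
  y <- .alignPhenotype(y, dosage)
  keep <- !is.na(y)
  yk <- y[keep]
  n <- length(yk)
  if (n < 8L) stop("at least 8 phenotyped individuals required")
  pos <- gridPositions(dosage)
  P <- nrow(pos)
  rss0 <- sum((yk - mean(yk))^2)

  lod <- r2 <- numeric(P)
  coefs <- matrix(NA_real_, P, 7,
                  dimnames = list(NULL, c("(Intercept)",
                                          paste0("X", .MODEL_B_COLUMNS))))
  asys <- lapply(1:8, function(h) assay(dosage, h)[, keep, drop = FALSE])
  for (p in seq_len(P)) {
    X <- vapply(asys, function(a) a[p, ], numeric(n))
    fit <- fitPosition(yk, designMatrixModelB(X))
    lod[p] <- lodScore(n, fit$RSS0, fit$RSS1)
    r2[p] <- if (fit$RSS0 > 0) 1 - fit$RSS1 / fit$RSS0 else 0
    coefs[p, ] <- fit$coefficients
  }
  new("ScanResult",
    table = data.frame(chrom = pos$chrom, cM = pos$cM, LOD = lod,
                       R2 = pmin(pmax(r2, 0), 1), n = n,
                       stringsAsFactors = FALSE),
    coefficients = coefs
  )
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes the phenotype against the intact genotype rows (preserving
#' the LD structure of the dosages), rescans, and takes the empirical
#' `(1 - alpha)` quantile of the genome-wide maximum LOD. Deterministic
#' given the seed.
#'
#' @param y phenotype vector (names matched as in [qtlScan()]).
#' @param dosage a [HomologueDosage-class].
#' @param nPerm number of permutation cycles (>= 20; 1000 in routine
#'   use).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed integer seed.
#' @return numeric LOD threshold, with the per-permutation maxima in
#'   attribute `"maxima"`.
#' @export
permutationThreshold <- function(y, dosage, nPerm = 1000, alpha = 0.05,
                                 seed = 1) {
  stopifnot(is(dosage, "HomologueDosage"))
  if (nPerm < 20L) stop("nPerm must be at least 20")
  y <- .alignPhenotype(y, dosage)
  keep <- !is.na(y)
  yk <- y[keep]
  n <- length(yk)
  if (n < 8L) stop("at least 8 phenotyped individuals required")
  yc <- yk - mean(yk)
  rss0 <- sum(yc^2)
  set.seed(seed)
  Yp <- vapply(seq_len(nPerm), function(i) yc[sample.int(n)], numeric(n))
  bases <- .scanBases(dosage, keep)
  ## max LOD over positions == LOD at min RSS1 over positions
  minRSS1 <- rep(Inf, nPerm)
  for (Q in bases) {
    expl <- colSums(crossprod(Q, Yp)^2)
    minRSS1 <- pmin(minRSS1, rss0 - expl)
  }
  minRSS1 <- pmax(minRSS1, 0)
  maxima <- ifelse(minRSS1 == 0, Inf,
                   pmax(0, n / 2 * log10(rss0 / minRSS1)))
  thr <- sort(maxima)[max(1L, ceiling((1 - alpha) * nPerm))]
  structure(thr, maxima = maxima, nPerm = nPerm, alpha = alpha,
            seed = seed)
}

#' Peaks and LOD-2 support intervals of a scan
#'
#' Per chromosome, reports the maximum-LOD position when it exceeds the
#' threshold (ties broken toward the lower cM position). The LOD-2
#' support interval is the contiguous run of positions around the peak
#' with `LOD >= peak - 2`, truncated to positions above the threshold.
#'
#' @param scan a [ScanResult-class].
#' @param threshold genome-wide LOD threshold, e.g. from
#'   [permutationThreshold()].
#' @return data.frame with one row per significant peak: `chrom`,
#'   `peakCM`, `peakLOD`, `R2`, `intervalLo`, `intervalHi`.
#' @export
findPeaks <- function(scan, threshold) {
  stopifnot(is(scan, "ScanResult"))
  tab <- lodProfile(scan)
  out <- lapply(unique(tab$chrom), function(ch) {
    sub <- tab[tab$chrom == ch, ]
    i <- which.max(sub$LOD)          # first max = lower cM on the grid
    if (!(sub$LOD[i] > threshold)) return(NULL)
    elig <- sub$LOD >= (sub$LOD[i] - 2) & sub$LOD >= threshold
    lo <- i; while (lo > 1L && elig[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < nrow(sub) && elig[hi + 1L]) hi <- hi + 1L
    data.frame(chrom = ch, peakCM = sub$cM[i], peakLOD = sub$LOD[i],
               R2 = sub$R2[i], intervalLo = sub$cM[lo],
               intervalHi = sub$cM[hi], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), peakCM = numeric(),
                      peakLOD = numeric(), R2 = numeric(),
                      intervalLo = numeric(), intervalHi = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Scan, threshold and peak detection in one call
#'
#' Convenience pipeline: [qtlScan()], then [permutationThreshold()],
#' then [findPeaks()], returning a fully populated
#' [ScanResult-class].
#'
#' @inheritParams permutationThreshold
#' @return A [ScanResult-class] with threshold and peaks attached.
#' @export
runNaiveScan <- function(y, dosage, nPerm = 1000, alpha = 0.05,
                         seed = 1) {
  scan <- qtlScan(y, dosage)
  thr <- permutationThreshold(y, dosage, nPerm = nPerm, alpha = alpha,
                              seed = seed)
  scan@threshold <- as.numeric(thr)
  scan@nPerm <- as.integer(nPerm)
  scan@alpha <- alpha
  scan@peaks <- findPeaks(scan, as.numeric(thr))
  scan
}
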