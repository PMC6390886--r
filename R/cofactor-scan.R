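## Cofactor (composite) QTL analysis: fix the naive QTL peaks as
## cofactors, regress them out, and rescan the residuals with a fresh
## permutation threshold.

#' Residualize a phenotype on cofactor QTL positions
#'
#' Jointly regresses the phenotype on the model-B design columns of all
#' cofactor positions (plus an intercept) by minimum-norm least squares
#' and returns the residuals, aligned with the dosage individuals.
#' With no cofactors the residuals are simply the centered phenotype.
#'
#' @param y phenotype vector (names matched against the dosage
#'   individuals when available; NAs are preserved as NA residuals).
#' @param dosage a [HomologueDosage-class].
#' @param cofactors data.frame with columns `chrom` and `cM` (grid
#'   positions), e.g. the peaks of a naive scan. May be empty.
#' @return numeric residual vector of length `ncol(dosage)`, named by
#'   individual.
#' @export
residualize <- function(y, dosage, cofactors) {
  stopifnot(is(dosage, "HomologueDosage"))
  y <- .alignPhenotype(y, dosage)
  keep <- !is.na(y)
  yk <- y[keep]
  out <- setNames(rep(NA_real_, length(y)), colnames(dosage))
  if (is.null(cofactors) || nrow(cofactors) == 0L) {
    out[keep] <- yk - mean(yk)
    return(out)
  }
  blocks <- lapply(seq_len(nrow(cofactors)), function(i) {
    X <- dosageAt(dosage, cofactors$chrom[i], cofactors$cM[i])[keep, ,
                                                               drop = FALSE]
    designMatrixModelB(X)[, -1, drop = FALSE]
  })
  design <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  fit <- fitPosition(yk, design)
  out[keep] <- yk - fit$fitted
  out
}

## human-readable label for a cofactor set, e.g. "2 (30) + 3 (69)"
.cofactorLabel <- function(cof) {
  if (!nrow(cof)) return("(none)")
  paste(sprintf("%s (%g)", cof$chrom, cof$cM), collapse = " + ")
}

## is a peak "new", i.e. not explained by any naive peak? A peak is
## considered known when it falls inside the LOD-2 interval of a naive
## peak on the same chromosome (fallback: within `window` cM of the
## naive peak position when no interval is available).
.isNewPeak <- function(peak, naivePeaks, window = 15) {
  same <- naivePeaks[naivePeaks$chrom == peak$chrom, , drop = FALSE]
  if (!nrow(same)) return(TRUE)
  covered <- if (all(c("intervalLo", "intervalHi") %in% names(same))) {
    peak$peakCM >= same$intervalLo & peak$peakCM <= same$intervalHi
  } else {
    abs(peak$peakCM - same$peakCM) <= window
  }
  !any(covered)
}

#' Cofactor QTL analysis over all subsets of naive peaks
#'
#' For every non-empty subset of the naive peaks (including the full
#' set), the phenotype is residualized on the subset's positions, the
#' residuals are rescanned, a fresh permutation threshold is computed on
#' the residuals (same permutation engine as the naive scan), and
#' significant peaks are reported. Peaks that are not explained by any
#' naive peak — outside every naive LOD-2 interval on their chromosome —
#' are flagged as newly identified ("masked") QTLs. Cofactor positions
#' are frozen at the naive peak positions and their design columns are
#' not refit during permutation.
#'
#' @param y phenotype vector.
#' @param dosage a [HomologueDosage-class].
#' @param naivePeaks data.frame of naive-scan peaks (needs `chrom`,
#'   `peakCM`; interval columns are used for the novelty rule when
#'   present). Must be non-empty.
#' @param nPerm permutation cycles per subset (default 1000).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed; each subset uses `seed + subset index`.
#' @return list with `summary` (one row per subset: cofactor label,
#'   threshold, detected peaks, new QTLs) and `analyses` (per subset:
#'   the cofactor set, residuals, threshold and the peaks data.frame
#'   with a `new` flag).
#' @export
cofactorAnalysis <- function(y, dosage, naivePeaks, nPerm = 1000,
                             alpha = 0.05, seed = 1) {
  stopifnot(is(dosage, "HomologueDosage"))
  if (is.null(naivePeaks) || nrow(naivePeaks) == 0L)
    stop("empty naive peak list")
  k <- nrow(naivePeaks)
  subsets <- unlist(lapply(seq_len(k), function(m)
    combn(k, m, simplify = FALSE)), recursive = FALSE)

  analyses <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    cof <- naivePeaks[subsets[[s]], , drop = FALSE]
    cofPos <- data.frame(chrom = cof$chrom, cM = cof$peakCM,
                         stringsAsFactors = FALSE)
    res <- residualize(y, dosage, cofPos)
    scan <- qtlScan(res, dosage)
    thr <- permutationThreshold(res, dosage, nPerm = nPerm,
                                alpha = alpha, seed = seed + s)
    peaks <- findPeaks(scan, as.numeric(thr))
    peaks$new <- if (nrow(peaks))
      vapply(seq_len(nrow(peaks)), function(i)
        .isNewPeak(peaks[i, ], naivePeaks), logical(1))
    else logical(0)
    analyses[[s]] <- list(cofactors = cofPos, residuals = res,
                          threshold = as.numeric(thr), scan = scan,
                          peaks = peaks)
    rows[[s]] <- data.frame(
      cofactors = .cofactorLabel(cofPos),
      threshold = as.numeric(thr),
      peaks = if (nrow(peaks))
        paste(sprintf("%.1f (%s-%g)", peaks$peakLOD, peaks$chrom,
                      peaks$peakCM), collapse = "; ")
      else "N.S.",
      R2 = if (nrow(peaks))
        paste(sprintf("%.3f", peaks$R2), collapse = "; ")
      else "N.S.",
      newQTLs = if (any(peaks$new))
        paste(sprintf("%s (%g)", peaks$chrom[peaks$new],
                      peaks$peakCM[peaks$new]), collapse = "; ")
      else "No",
      stringsAsFactors = FALSE
    )
  }
  list(summary = do.call(rbind, rows), analyses = analyses)
}
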