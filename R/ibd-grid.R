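## Gamete classes -> expected homologue dosages, grid interpolation and
## genotypic information coefficients.

## copies of homologue j (columns) contributed by each class label (rows)
.classContribution <- function(classes) {
  C <- matrix(0, length(classes), 4)
  for (k in seq_along(classes)) {
    a <- as.integer(substr(classes[k], 1, 1))
    b <- as.integer(substr(classes[k], 2, 2))
    C[k, a] <- C[k, a] + 1
    C[k, b] <- C[k, b] + 1
  }
  C
}

#' Convert gamete-class probabilities to expected homologue dosages
#'
#' The expected dosage of homologue i is the probability-weighted copy
#' count over the gamete classes: a bivalent class such as 13 contributes
#' one copy each to X1 and X3, a double-reduction class such as 22
#' contributes two copies to X2. The map is linear, so the parental
#' constraints `X1+X2+X3+X4 = 2` and `X5+X6+X7+X8 = 2` hold exactly for
#' any normalized class vector.
#'
#' @param x a [GameteClassProb-class].
#' @return A [HomologueDosage-class] on the same grid.
#' @export
classesToDosage <- function(x) {
  stopifnot(is(x, "GameteClassProb"))
  n <- length(x@individuals)
  P <- nrow(x@map@grid)
  K <- length(x@classes)
  C <- .classContribution(x@classes)
  X1 <- matrix(x@prob1, n * P, K) %*% C   # (ind, pos) x homologue
  X2 <- matrix(x@prob2, n * P, K) %*% C
  asy <- c(
    lapply(1:4, function(j) t(matrix(X1[, j], n, P))),
    lapply(1:4, function(j) t(matrix(X2[, j], n, P)))
  )
  homologueDosage(asy, chrom = x@map@grid$chrom, cM = x@map@grid$cM,
                  individuals = x@individuals)
}

#' Interpolate homologue dosages onto a regular cM grid
#'
#' Dosages known at (possibly irregular) marker positions are carried
#' onto a regular grid by per-homologue linear interpolation (constant
#' extrapolation beyond the terminal markers). Interpolated values are
#' clamped to \[0, 2\] and renormalized so the parental sums equal 2;
#' for linear interpolation of valid inputs both steps are no-ops, they
#' only guard degenerate input. Values at grid points that coincide with
#' marker positions are preserved exactly.
#'
#' @param x a [HomologueDosage-class] at marker positions (at least 2 per
#'   chromosome).
#' @param step grid step in cM (default 1).
#' @param lengths optional named chromosome lengths in cM; defaults to
#'   the last marker position per chromosome.
#' @return A [HomologueDosage-class] on the regular grid.
#' @export
interpolateToGrid <- function(x, step = 1, lengths = NULL) {
  stopifnot(is(x, "HomologueDosage"))
  pos <- gridPositions(x)
  chroms <- unique(pos$chrom)
  if (is.null(lengths))
    lengths <- vapply(chroms, function(ch) max(pos$cM[pos$chrom == ch]),
                      numeric(1))
  outChrom <- character(); outCM <- numeric()
  pieces <- vector("list", length(chroms))
  n <- ncol(x)
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sel <- which(pos$chrom == ch)
    if (length(sel) < 2L)
      stop("chromosome ", ch, " has fewer than 2 support positions")
    src <- pos$cM[sel]
    tgt <- round(seq(0, lengths[[ch]], by = step), 1)
    block <- lapply(1:8, function(h) {
      a <- assay(x, h)[sel, , drop = FALSE]
      apply(a, 2, function(v)
        approx(src, v, xout = tgt, method = "linear", rule = 2)$y)
    })
    pieces[[ci]] <- block
    outChrom <- c(outChrom, rep(ch, length(tgt)))
    outCM <- c(outCM, tgt)
  }
  asy <- lapply(1:8, function(h)
    do.call(rbind, lapply(pieces, `[[`, h)))
  ## guard: clamp and renormalize the parental sums
  asy <- lapply(asy, function(a) pmin(pmax(a, 0), 2))
  s1 <- asy[[1]] + asy[[2]] + asy[[3]] + asy[[4]]
  s2 <- asy[[5]] + asy[[6]] + asy[[7]] + asy[[8]]
  for (h in 1:4) asy[[h]] <- 2 * asy[[h]] / s1
  for (h in 5:8) asy[[h]] <- 2 * asy[[h]] / s2
  homologueDosage(asy, chrom = outChrom, cM = outCM,
                  individuals = colnames(x))
}

#' Genotypic information coefficient (GIC) per homologue and position
#'
#' Measures how informative the IBD probabilities are for inferring
#' homologue-specific QTL effects. With the carrier probability
#' `p_in = min(X_in, 1)` of individual n for homologue i, the GIC is
#' `1 - 4 * mean_n(p_in (1 - p_in))`: 1 when every carrier probability is
#' 0 or 1 (fully informative), 0 when all are 1/2 (no information).
#'
#' @param x a [HomologueDosage-class] with at least one individual.
#' @return data.frame with `chrom`, `cM` and columns `GIC1`..`GIC8`.
#' @export
gic <- function(x) {
  stopifnot(is(x, "HomologueDosage"))
  if (ncol(x) == 0L) stop("empty population")
  pos <- gridPositions(x)
  vals <- vapply(1:8, function(h) {
    p <- pmin(assay(x, h), 1)
    1 - 4 * rowMeans(p * (1 - p))
  }, numeric(nrow(x)))
  vals <- matrix(vals, nrow = nrow(x), ncol = 8,
                 dimnames = list(NULL, paste0("GIC", 1:8)))
  cbind(pos, as.data.frame(vals))
}
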