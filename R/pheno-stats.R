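## Trait derivation and phenotype statistics: ANOVA mean squares,
## variance components, broad-sense heritability, adjusted clone means.

#' Tuber moisture content from dry matter
#'
#' @param dryMatter tuber dry matter in percent, in \[0, 100\].
#' @return moisture in percent: `100 - dryMatter`.
#' @export
tuberMoisture <- function(dryMatter) {
  if (any(is.na(dryMatter)) || any(dryMatter < 0 | dryMatter > 100))
    stop("dry matter must be in [0, 100]")
  100 - dryMatter
}

#' Protein content corrected for tuber moisture
#'
#' The trait analysed throughout the package: soluble protein measured in
#' potato fruit juice (PFJ, % w/v) corrected by tuber moisture content,
#' `pfjProtein * moisture / 100`. The result is treated as a
#' dimensionless product of the two percentages.
#'
#' @param pfjProtein soluble protein concentration in PFJ (% w/v), >= 0.
#' @param moisture tuber moisture content in percent, >= 0.
#' @return protein content in trait units.
#' @examples
#' proteinContent(1.2, 77.5)  # 0.93
#' @export
proteinContent <- function(pfjProtein, moisture) {
  if (any(is.na(pfjProtein)) || any(pfjProtein < 0))
    stop("PFJ protein must be non-negative")
  if (any(is.na(moisture)) || any(moisture < 0))
    stop("moisture must be non-negative")
  pfjProtein * moisture / 100
}

.traitFactors <- function(table, trait) {
  need <- c("clone", "year", "block", trait)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(
    y = table[[trait]],
    clone = factor(table$clone),
    year = factor(table$year),
    block = factor(table$block)
  )
}

#' ANOVA mean squares of the clone, clone-by-year and residual terms
#'
#' Within-year model (single year): `y = mu + clone + block + e`.
#' Between-years model: `y = mu + clone + block(year) + clone:year + e`
#' with block nested in year. Mean squares are computed from type-II
#' sums of squares via nested least-squares model comparisons, so
#' unbalanced tables (clones missing a cell) are handled; clones and
#' clone-by-year are the terms of interest, block(-in-year) is a design
#' term.
#'
#' @param table phenotype data.frame with columns `clone`, `year`,
#'   `block` and the trait.
#' @param model `"within"` (requires a single year, >= 2 blocks) or
#'   `"between"` (>= 2 years).
#' @param trait trait column name (default `"protein"`).
#' @return list with `MS_G`, `MS_GxY` (NA for within), `MS_E`, the
#'   degrees of freedom, and the design summary `r` (blocks) and `y`
#'   (years).
#' @export
anovaMeanSquares <- function(table, model = c("within", "between"),
                             trait = "protein") {
  model <- match.arg(model)
  d <- .traitFactors(table, trait)
  d <- d[!is.na(d$y), ]
  d <- droplevels(d)
  nYears <- nlevels(d$year)
  nBlocks <- nlevels(d$block)

  if (model == "within") {
    if (nYears != 1L)
      stop("within-year model requires a single year; subset the table")
    if (nBlocks < 2L)
      stop("within-year model requires >= 2 blocks (replicates)")
    fitFull <- lm(y ~ block + clone, data = d)
    if (df.residual(fitFull) < 1L)
      stop("unreplicated data: no residual degrees of freedom")
    fit0 <- lm(y ~ block, data = d)
    ssG <- deviance(fit0) - deviance(fitFull)
    dfG <- df.residual(fit0) - df.residual(fitFull)
    list(model = model,
         MS_G = ssG / dfG,
         MS_GxY = NA_real_,
         MS_E = deviance(fitFull) / df.residual(fitFull),
         df = c(G = dfG, E = df.residual(fitFull)),
         r = nBlocks, y = 1L)
  } else {
    if (nYears < 2L)
      stop("between-years model requires >= 2 years")
    d$yb <- droplevels(interaction(d$year, d$block))
    fitFull <- lm(y ~ clone + yb + clone:year, data = d)
    if (df.residual(fitFull) < 1L)
      stop("unreplicated data: no residual degrees of freedom")
    fitNoInt <- lm(y ~ clone + yb, data = d)
    fitNoClone <- lm(y ~ yb, data = d)
    ssGxY <- deviance(fitNoInt) - deviance(fitFull)
    dfGxY <- df.residual(fitNoInt) - df.residual(fitFull)
    ssG <- deviance(fitNoClone) - deviance(fitNoInt)
    dfG <- df.residual(fitNoClone) - df.residual(fitNoInt)
    list(model = model,
         MS_G = ssG / dfG,
         MS_GxY = ssGxY / dfGxY,
         MS_E = deviance(fitFull) / df.residual(fitFull),
         df = c(G = dfG, GxY = dfGxY, E = df.residual(fitFull)),
         r = nBlocks, y = nYears)
  }
}

#' Variance components from ANOVA mean squares
#'
#' Method-of-moments estimators: within-year
#' `sigma2_G = (MS_G - MS_E) / r`; between-years
#' `sigma2_G = (MS_G - MS_GxY) / (r y)`,
#' `sigma2_GxY = (MS_GxY - MS_E) / r`; and `sigma2_E = MS_E` in both.
#' Negative estimates are floored at zero in the reported components and
#' kept unmodified in the `raw` slot.
#'
#' @param ms a list as returned by [anovaMeanSquares()], or a named
#'   numeric/list with `MS_G`, `MS_E` and (between-years) `MS_GxY`.
#' @param r number of replicates (blocks); defaults to `ms$r`.
#' @param y number of years; defaults to `ms$y`.
#' @param model `"within"` or `"between"`; defaults to `ms$model`.
#' @return A [VarianceComponents-class].
#' @examples
#' vc <- varianceComponents(list(MS_G = 0.05, MS_E = 0.03), r = 2,
#'                          model = "within")
#' componentEstimates(vc)  # sigma2_G = 0.01
#' @export
varianceComponents <- function(ms, r = NULL, y = NULL, model = NULL) {
  if (is.null(r)) r <- ms$r
  if (is.null(y)) y <- if (!is.null(ms$y)) ms$y else 1L
  if (is.null(model)) model <- ms$model
  model <- match.arg(model, c("within", "between"))
  if (is.null(r) || r < 1 || y < 1)
    stop("r and y must be >= 1")
  msG <- ms$MS_G; msE <- ms$MS_E
  if (model == "within") {
    raw <- c(sigma2_G = (msG - msE) / r, sigma2_GxY = NA_real_,
             sigma2_E = msE)
  } else {
    msGxY <- ms$MS_GxY
    if (is.null(msGxY) || is.na(msGxY))
      stop("between-years components require MS_GxY")
    raw <- c(sigma2_G = (msG - msGxY) / (r * y),
             sigma2_GxY = (msGxY - msE) / r,
             sigma2_E = msE)
  }
  new("VarianceComponents",
    model = model,
    sigma2G = max(raw[["sigma2_G"]], 0),
    sigma2GxY = if (model == "within") NA_real_
      else max(raw[["sigma2_GxY"]], 0),
    sigma2E = max(raw[["sigma2_E"]], 0),
    raw = raw,
    meanSquares = c(MS_G = msG,
                    MS_GxY = if (model == "within") NA_real_ else ms$MS_GxY,
                    MS_E = msE),
    r = r, y = y
  )
}

#' Assemble a VarianceComponents object from known estimates
#'
#' For evaluating heritability on externally reported variance components
#' (no mean squares involved).
#'
#' @param sigma2G clone (genotypic) variance.
#' @param sigma2E residual variance.
#' @param r number of replicates.
#' @param sigma2GxY clone-by-year variance (between-years model only).
#' @param y number of years.
#' @param model `"within"` or `"between"`.
#' @return A [VarianceComponents-class].
#' @examples
#' vc <- varianceComponentSet(sigma2G = 0.013, sigma2E = 0.039, r = 2)
#' heritability(vc)  # 0.40
#' @export
varianceComponentSet <- function(sigma2G, sigma2E, r,
                                 sigma2GxY = NA_real_, y = 1,
                                 model = c("within", "between")) {
  model <- match.arg(model)
  new("VarianceComponents",
    model = model, sigma2G = sigma2G,
    sigma2GxY = if (model == "within") NA_real_ else sigma2GxY,
    sigma2E = sigma2E,
    raw = c(sigma2_G = sigma2G, sigma2_GxY = sigma2GxY,
            sigma2_E = sigma2E),
    meanSquares = c(MS_G = NA_real_, MS_GxY = NA_real_, MS_E = NA_real_),
    r = r, y = y
  )
}

#' Broad-sense heritability from variance components
#'
#' Within-year: `H2 = sigma2_G / (sigma2_G + sigma2_E / r)`.
#' Between-years:
#' `H2 = sigma2_G / (sigma2_G + sigma2_GxY / y + sigma2_E / (r y))`.
#'
#' @param vc a [VarianceComponents-class].
#' @return H2 in \[0, 1\] (multiply by 100 for percent).
#' @examples
#' heritability(varianceComponentSet(0.013, 0.039, r = 2))  # 0.40
#' heritability(varianceComponentSet(0.021, 0.034, r = 2))  # 0.55
#' @export
heritability <- function(vc) {
  stopifnot(is(vc, "VarianceComponents"))
  s2G <- vc@sigma2G; s2E <- vc@sigma2E
  denom <- if (vc@model == "within") {
    s2G + s2E / vc@r
  } else {
    s2G + vc@sigma2GxY / vc@y + s2E / (vc@r * vc@y)
  }
  if (!is.finite(denom) || denom == 0) {
    if (s2G == 0) return(0)
    stop("heritability undefined: zero denominator")
  }
  s2G / denom
}

#' Best linear unbiased estimates (adjusted clone means)
#'
#' Fits `trait = genotype + year + error` with genotype fixed and year
#' (and error) random, by REML, and returns the fixed genotype
#' estimates. With a single year no year adjustment is possible and the
#' BLUEs reduce to ordinary clone means.
#'
#' @param table phenotype data.frame with `clone`, `year` and the trait.
#' @param trait trait column name (default `"protein"`).
#' @return data.frame with columns `clone` and `blue`.
#' @export
computeBLUEs <- function(table, trait = "protein") {
  need <- c("clone", "year", trait)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(y = table[[trait]],
                  clone = factor(table$clone),
                  year = factor(table$year))
  d <- droplevels(d[!is.na(d$y), ])
  if (!nrow(d)) stop("no phenotype records")
  if (nlevels(d$year) < 2L) {
    fit <- lm(y ~ 0 + clone, data = d)
    est <- coef(fit)
  } else {
    fit <- lme4::lmer(y ~ 0 + clone + (1 | year), data = d, REML = TRUE)
    est <- lme4::fixef(fit)
  }
  data.frame(
    clone = sub("^clone", "", names(est)),
    blue = unname(est),
    stringsAsFactors = FALSE
  )
}
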