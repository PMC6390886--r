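## Delimited-text readers and writers. All tabular outputs are plain
## tab-separated text with a commented "# key: value" header block
## carrying provenance (no standard format exists for tetraploid IBD
## tables). Writers and readers round-trip losslessly.

## format doubles so that read-back is bit-identical
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.writeDelim <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", names(header), ": ", unname(header)), con)
  isNum <- vapply(df, is.double, logical(1))
  df[isNum] <- lapply(df[isNum], .fmtNum)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readDelim <- function(path, required) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df
}

## header block of a written file, as a named character vector
.readHeader <- function(path) {
  lines <- readLines(path, n = 100)
  lines <- lines[startsWith(lines, "# ")]
  if (!length(lines)) return(character())
  kv <- sub("^# ", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  setNames(vals, keys)
}

#' Read / write a marker map table
#'
#' A marker map is a delimited table with columns `marker`, `chrom` and
#' `cM`.
#'
#' @param path file path.
#' @return `readMarkerMap`: data.frame with the three columns, positions
#'   increasing within chromosome.
#' @export
readMarkerMap <- function(path) {
  df <- .readDelim(path, c("marker", "chrom", "cM"))
  df$chrom <- as.character(df$chrom)
  bad <- which(is.na(df$cM))
  if (length(bad))
    stop("non-numeric cM at row(s): ", paste(bad, collapse = ", "))
  df[order(match(df$chrom, unique(df$chrom)), df$cM), ]
}

#' @rdname readMarkerMap
#' @param map data.frame with columns `marker`, `chrom`, `cM`.
#' @export
writeMarkerMap <- function(map, path) {
  .writeDelim(map[, c("marker", "chrom", "cM")], path,
              c(type = "marker_map"))
  invisible(path)
}

#' Genetic map from a marker table
#'
#' Chromosome lengths are taken as the last marker position per
#' chromosome (positions are 0-based from the first mapped marker).
#'
#' @param markers data.frame as from [readMarkerMap()].
#' @param step grid step in cM.
#' @return A [GeneticMap-class].
#' @export
geneticMapFromMarkers <- function(markers, step = 1) {
  lens <- vapply(split(markers$cM, markers$chrom), max, numeric(1))
  geneticMap(lens[unique(markers$chrom)], step = step)
}

#' Read / write gamete-class probability tables
#'
#' Long format with columns `individual`, `chrom`, `cM`, `parent` (1 or
#' 2), `class` (e.g. `"13"`, `"22"`) and `probability`. The reader
#' validates that every per-parent distribution sums to 1 (tolerance
#' 1e-6) and reconstructs the [GameteClassProb-class]; the map grid is
#' inferred from the distinct positions.
#'
#' @param path file path.
#' @param step grid step of the reconstructed map; default inferred from
#'   the position spacing.
#' @return `readGameteClassProbs`: a [GameteClassProb-class].
#' @export
readGameteClassProbs <- function(path, step = NULL) {
  df <- .readDelim(path, c("individual", "chrom", "cM", "parent",
                           "class", "probability"))
  df$chrom <- as.character(df$chrom)
  df$class <- as.character(df$class)
  inds <- unique(df$individual)
  chroms <- unique(df$chrom)
  posKey <- unique(df[, c("chrom", "cM")])
  posKey <- posKey[order(match(posKey$chrom, chroms), posKey$cM), ]
  classes <- unique(df$class)
  biv <- c("12", "13", "14", "23", "24", "34")
  dr <- c("11", "22", "33", "44")
  classes <- c(biv, intersect(dr, classes))
  if (!all(unique(df$class) %in% classes))
    stop("unknown gamete class label(s): ",
         paste(setdiff(unique(df$class), classes), collapse = ", "))
  n <- length(inds); P <- nrow(posKey); K <- length(classes)
  i <- match(df$individual, inds)
  p <- match(paste(df$chrom, df$cM), paste(posKey$chrom, posKey$cM))
  k <- match(df$class, classes)
  prob1 <- array(0, c(n, P, K)); prob2 <- array(0, c(n, P, K))
  is1 <- df$parent == 1
  prob1[cbind(i[is1], p[is1], k[is1])] <- df$probability[is1]
  prob2[cbind(i[!is1], p[!is1], k[!is1])] <- df$probability[!is1]
  s1 <- rowSums(prob1, dims = 2); s2 <- rowSums(prob2, dims = 2)
  if (max(abs(s1 - 1), abs(s2 - 1)) > 1e-6) {
    bad <- which(abs(s1 - 1) > 1e-6 | abs(s2 - 1) > 1e-6, arr.ind = TRUE)
    stop("probabilities do not sum to 1 (tolerance 1e-6), e.g. for ",
         "individual ", inds[bad[1, 1]], " at ",
         posKey$chrom[bad[1, 2]], ":", posKey$cM[bad[1, 2]])
  }
  if (is.null(step)) {
    d <- diff(posKey$cM[posKey$chrom == chroms[1]])
    step <- if (length(d)) min(d) else 1
  }
  lens <- vapply(split(posKey$cM, posKey$chrom), max, numeric(1))
  map <- geneticMap(lens[chroms], step = step)
  if (!isTRUE(all.equal(map@grid$cM, posKey$cM)) ||
      !identical(as.character(map@grid$chrom), posKey$chrom))
    stop("positions do not form a regular grid at step ", step)
  new("GameteClassProb", map = map, classes = classes, prob1 = prob1,
      prob2 = prob2, individuals = as.character(inds))
}

#' @rdname readGameteClassProbs
#' @param x a [GameteClassProb-class].
#' @export
writeGameteClassProbs <- function(x, path) {
  stopifnot(is(x, "GameteClassProb"))
  grid <- gridPositions(x)
  n <- length(x@individuals); P <- nrow(grid); K <- length(x@classes)
  long <- function(arr, parent) data.frame(
    individual = rep(x@individuals, P * K),
    chrom = rep(rep(grid$chrom, each = n), K),
    cM = rep(rep(grid$cM, each = n), K),
    parent = parent,
    class = rep(x@classes, each = n * P),
    probability = as.vector(arr),
    stringsAsFactors = FALSE
  )
  df <- rbind(long(x@prob1, 1L), long(x@prob2, 2L))
  .writeDelim(df, path, c(type = "gamete_class_probabilities",
                          classes = paste(x@classes, collapse = ",")))
  invisible(path)
}

#' Read / write phenotype tables
#'
#' Delimited text with header columns `clone`, `year`, `block` and
#' either the derived trait `protein` or the raw measurements
#' `pfj_protein` (% w/v) and `dry_matter` (%), from which the trait is
#' derived as [proteinContent()] of the PFJ protein and
#' [tuberMoisture()]. Schema violations are reported with row numbers.
#'
#' @param path file path.
#' @return `readPhenotypes`: data.frame with at least `clone`, `year`,
#'   `block`, `protein`.
#' @export
readPhenotypes <- function(path) {
  df <- .readDelim(path, c("clone", "year", "block"))
  hasRaw <- all(c("pfj_protein", "dry_matter") %in% names(df))
  if (!hasRaw && !"protein" %in% names(df))
    stop("file ", path, " lacks required column(s): ",
         "protein (or pfj_protein + dry_matter)")
  dup <- duplicated(df[, c("clone", "year", "block")])
  if (any(dup))
    stop("duplicate (clone, year, block) record(s) at row(s): ",
         paste(which(dup), collapse = ", "))
  if (hasRaw) {
    bad <- which(df$dry_matter < 0 | df$dry_matter > 100)
    if (length(bad))
      stop("dry matter outside [0, 100] at row(s): ",
           paste(bad, collapse = ", "))
    bad <- which(df$pfj_protein < 0)
    if (length(bad))
      stop("negative PFJ protein at row(s): ",
           paste(bad, collapse = ", "))
    if (!"protein" %in% names(df))
      df$protein <- proteinContent(df$pfj_protein,
                                   tuberMoisture(df$dry_matter))
  }
  df$clone <- as.character(df$clone)
  df
}

#' @rdname readPhenotypes
#' @param table phenotype data.frame.
#' @export
writePhenotypes <- function(table, path) {
  .writeDelim(table, path, c(type = "phenotypes"))
  invisible(path)
}

#' Read / write scan results
#'
#' The per-position table plus the fitted coefficients; the threshold
#' and permutation settings travel in the comment header.
#'
#' @param path file path.
#' @return `readScanResult`: a [ScanResult-class] (peaks are stored
#'   separately, see [writePeaks()]).
#' @export
readScanResult <- function(path) {
  df <- .readDelim(path, c("chrom", "cM", "LOD", "R2", "n"))
  df$chrom <- as.character(df$chrom)
  hdr <- .readHeader(path)
  coefCols <- c("b0", paste0("a", c(2, 3, 4, 6, 7, 8)))
  coefs <- as.matrix(df[, intersect(coefCols, names(df)), drop = FALSE])
  colnames(coefs) <- c("(Intercept)", paste0("X", c(2, 3, 4, 6, 7, 8)))
  obj <- new("ScanResult",
    table = df[, c("chrom", "cM", "LOD", "R2", "n")],
    coefficients = coefs,
    threshold = if ("threshold" %in% names(hdr))
      as.numeric(hdr[["threshold"]]) else NA_real_,
    nPerm = if ("nPerm" %in% names(hdr))
      as.integer(hdr[["nPerm"]]) else NA_integer_,
    alpha = if ("alpha" %in% names(hdr))
      as.numeric(hdr[["alpha"]]) else NA_real_
  )
  obj
}

#' @rdname readScanResult
#' @param scan a [ScanResult-class].
#' @param extra named character vector merged into the comment header
#'   (e.g. the seed).
#' @export
writeScanResult <- function(scan, path, extra = character()) {
  stopifnot(is(scan, "ScanResult"))
  df <- lodProfile(scan)
  cf <- scanCoefficients(scan)
  colnames(cf) <- c("b0", paste0("a", c(2, 3, 4, 6, 7, 8)))
  df <- cbind(df, as.data.frame(cf))
  hdr <- c(type = "scan_result",
           threshold = .fmtNum(lodThreshold(scan)),
           nPerm = as.character(scan@nPerm),
           alpha = as.character(scan@alpha),
           extra)
  .writeDelim(df, path, hdr)
  invisible(path)
}

#' Read / write peak tables
#' @param path file path.
#' @return `readPeaks`: data.frame of peaks with LOD-2 intervals.
#' @export
readPeaks <- function(path) {
  df <- .readDelim(path, c("chrom", "peakCM", "peakLOD", "R2",
                           "intervalLo", "intervalHi"))
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname readPeaks
#' @param peaks data.frame as from [findPeaks()].
#' @param extra named character header entries.
#' @export
writePeaks <- function(peaks, path, extra = character()) {
  .writeDelim(peaks, path, c(type = "peaks", extra))
  invisible(path)
}

#' Read / write homologue dosage grids
#'
#' Wide format: one row per position and individual with columns
#' `chrom`, `cM`, `individual`, `X1`..`X8`.
#'
#' @param path file path.
#' @return `readHomologueDosage`: a [HomologueDosage-class].
#' @export
readHomologueDosage <- function(path) {
  df <- .readDelim(path, c("chrom", "cM", "individual",
                           paste0("X", 1:8)))
  df$chrom <- as.character(df$chrom)
  inds <- unique(df$individual)
  posKey <- unique(df[, c("chrom", "cM")])
  i <- match(df$individual, inds)
  p <- match(paste(df$chrom, df$cM), paste(posKey$chrom, posKey$cM))
  asy <- lapply(1:8, function(h) {
    m <- matrix(NA_real_, nrow(posKey), length(inds))
    m[cbind(p, i)] <- df[[paste0("X", h)]]
    m
  })
  homologueDosage(asy, chrom = posKey$chrom, cM = posKey$cM,
                  individuals = as.character(inds))
}

#' @rdname readHomologueDosage
#' @param x a [HomologueDosage-class].
#' @export
writeHomologueDosage <- function(x, path) {
  stopifnot(is(x, "HomologueDosage"))
  pos <- gridPositions(x)
  n <- ncol(x); P <- nrow(pos)
  df <- data.frame(
    chrom = rep(pos$chrom, each = n),
    cM = rep(pos$cM, each = n),
    individual = rep(colnames(x), P),
    stringsAsFactors = FALSE
  )
  for (h in 1:8)
    df[[paste0("X", h)]] <- as.vector(t(assay(x, h)))
  .writeDelim(df, path, c(type = "homologue_dosage"))
  invisible(path)
}

#' Read / write a run configuration
#'
#' YAML round-trip of the run parameters (seeds, grid step, permutation
#' settings, file paths, simulation parameters).
#'
#' @param path file path.
#' @return `readRunConfig`: named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  cfg
}

#' @rdname readRunConfig
#' @param config named list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
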