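#' Filter proteins by missingness
#'
#' Keeps a protein if its overall missing fraction is below
#' \code{maxFrac}, or if at least one region group observed it in every
#' sample. Protein order is preserved.
#'
#' @param x \linkS4class{ProteoExperiment} (state \code{"raw"} or
#'   \code{"log2"}) with sample metadata attached.
#' @param maxFrac Maximum tolerated overall missing fraction (strict).
#' @return Filtered \linkS4class{ProteoExperiment}.
#' @export
filterMissing <- function(x, maxFrac = 0.5) {
  stopifnot(is(x, "ProteoExperiment"))
  if (!procState(x) %in% c("raw", "log2")) {
    stop("filterMissing expects state 'raw' or 'log2', got '",
         procState(x), "'")
  }
  region <- regionLabels(x)
  m <- missingMask(x)
  overallOk <- rowMeans(m) < maxFrac
  groupOk <- rep(FALSE, nrow(x))
  for (r in unique(region)) {
    idx <- which(region == r)
    groupOk <- groupOk | rowSums(m[, idx, drop = FALSE]) == 0L
  }
  keep <- overallOk | groupOk
  if (!any(keep)) {
    stop("all proteins dropped by the missingness filter; ",
         "consider raising maxFrac")
  }
  x[keep, ]
}

#' Log2-transform raw intensities
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"raw"}; all
#'   observed intensities must be strictly positive (zeros encode
#'   non-detection and must already be missing).
#' @return \linkS4class{ProteoExperiment} with state \code{"log2"}; the
#'   missing mask is unchanged.
#' @export
log2Transform <- function(x) {
  stopifnot(is(x, "ProteoExperiment"))
  if (procState(x) != "raw") {
    stop("log2Transform expects state 'raw', got '", procState(x), "'")
  }
  v <- abundance(x)
  if (any(v <= 0, na.rm = TRUE)) {
    stop("non-missing intensities <= 0 found; map zeros to missing first")
  }
  assay(x, "abundance") <- log2(v)
  x@state <- "log2"
  validObject(x)
  x
}

#' Median-normalize log2 intensities
#'
#' Per sample, subtracts that sample's median over observed values, then
#' adds back the grand median of the pre-normalization per-sample
#' medians, so every sample's observed median ends up at the same
#' constant while values stay on the log2 intensity scale. Idempotent.
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"log2"} (or
#'   \code{"normalized"}, in which case it is a no-op up to numerics).
#' @return \linkS4class{ProteoExperiment} with state \code{"normalized"}.
#' @export
medianNormalize <- function(x) {
  stopifnot(is(x, "ProteoExperiment"))
  if (!procState(x) %in% c("log2", "normalized")) {
    stop("medianNormalize expects state 'log2', got '", procState(x), "'")
  }
  v <- abundance(x)
  meds <- apply(v, 2, stats::median, na.rm = TRUE)
  if (any(is.na(meds))) {
    stop("sample(s) with zero observed values: ",
         paste(colnames(x)[is.na(meds)], collapse = ", "))
  }
  grand <- stats::median(meds)
  assay(x, "abundance") <- sweep(v, 2, meds) + grand
  x@state <- "normalized"
  validObject(x)
  x
}

#' Impute remaining missing values by iterative random-forest regression
#'
#' Round-robin chained imputation in the style of forest-based
#' imputation for expression matrices: missing cells are initialized at
#' the protein's observed mean, then proteins are swept in decreasing
#' missingness order, each protein's missing cells re-predicted from all
#' other proteins' current values by a random-forest regressor, until
#' the relative change of the imputed cells stops decreasing (or
#' \code{maxIter} sweeps). Observed cells are never modified, and the
#' result is deterministic under \code{seed}.
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"normalized"};
#'   every protein must have at least one observed value.
#' @param seed Integer seed.
#' @param maxIter Maximum number of sweeps.
#' @param numTrees Trees per forest.
#' @param tol Relative-change convergence floor.
#' @return \linkS4class{ProteoExperiment} with state \code{"imputed"}
#'   (all-FALSE missing mask).
#' @export
imputeMissing <- function(x, seed, maxIter = 10, numTrees = 100,
                          tol = 1e-4) {
  stopifnot(is(x, "ProteoExperiment"))
  if (missing(seed)) stop("an explicit seed is required")
  if (procState(x) != "normalized") {
    stop("imputeMissing expects state 'normalized', got '", procState(x), "'")
  }
  v <- abundance(x)
  m <- missingMask(x)
  allMiss <- rowSums(!m) == 0L
  if (any(allMiss)) {
    stop("protein(s) with all values missing (filter first): ",
         paste(rownames(x)[allMiss], collapse = ", "))
  }
  if (any(m)) {
    nMissRow <- rowSums(m)
    targets <- order(nMissRow, decreasing = TRUE)
    targets <- targets[nMissRow[targets] > 0L]
    # mean-initialize
    for (p in targets) v[p, m[p, ]] <- mean(v[p, !m[p, ]])
    prevDelta <- Inf
    prevV <- v
    for (iter in seq_len(maxIter)) {
      for (k in seq_along(targets)) {
        p <- targets[k]
        obs <- !m[p, ]
        xs <- t(v[-p, , drop = FALSE])
        colnames(xs) <- sprintf("f%d", seq_len(ncol(xs)))
        fit <- ranger::ranger(
          x = xs[obs, , drop = FALSE], y = v[p, obs],
          num.trees = numTrees, num.threads = 1,
          seed = (seed + 7919L * iter + k) %% .Machine$integer.max)
        v[p, !obs] <- stats::predict(
          fit, data = xs[!obs, , drop = FALSE],
          num.threads = 1)$predictions
      }
      imp <- v[m]
      delta <- sum((imp - prevV[m])^2) / max(sum(imp^2), .Machine$double.eps)
      if (delta >= prevDelta) {
        v <- prevV  # change stopped decreasing: keep previous sweep
        break
      }
      prevV <- v
      if (delta < tol) break
      prevDelta <- delta
    }
  }
  assay(x, "abundance") <- v
  assay(x, "missing") <- matrix(FALSE, nrow(v), ncol(v),
                                dimnames = dimnames(v))
  x@state <- "imputed"
  validObject(x)
  x
}

#' Principal component analysis of an imputed abundance matrix
#'
#' Protein-centered (no scaling) SVD-based PCA of samples. The sign of
#' each component is fixed by making its largest-magnitude loading
#' positive.
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"imputed"}.
#' @param nComponents Number of components (default all).
#' @return List of class \code{"PcaResult"}: \code{scores} (samples x
#'   components), \code{loadings} (proteins x components, orthonormal
#'   columns) and \code{explainedVariance} (fraction of total variance
#'   per component, non-increasing).
#' @export
runPca <- function(x, nComponents = NULL) {
  stopifnot(is(x, "ProteoExperiment"))
  if (procState(x) != "imputed") {
    stop("runPca expects state 'imputed', got '", procState(x), "'")
  }
  v <- abundance(x)
  maxK <- min(nrow(v), ncol(v) - 1L)
  if (is.null(nComponents)) nComponents <- maxK
  if (nComponents > min(nrow(v), ncol(v))) {
    stop("nComponents exceeds min(nProteins, nSamples)")
  }
  pr <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  if (tot < .Machine$double.eps) {
    stop("constant matrix: zero total variance")
  }
  k <- min(nComponents, ncol(pr$rotation))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explainedVariance = (pr$sdev^2 / tot)[seq_len(k)]),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat(sprintf("PcaResult: %d samples, %d proteins, %d components\n",
              nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explainedVariance[seq_len(
        min(5, length(x$explainedVariance)))]), collapse = " "), "\n")
  invisible(x)
}

#' Correlation between PCA loadings and differential-expression log2 FC
#'
#' For a two-group comparison, the loadings of a principal component are
#' expected to be proportional to the per-protein log2 fold change when
#' the component captures the group separation; this returns their
#' Pearson correlation.
#'
#' @param pca \code{PcaResult} from \code{\link{runPca}} on the two
#'   groups' samples.
#' @param de Differential-expression table from
#'   \code{\link{fitModeratedDE}} on the same protein set.
#' @param component Component index (default 1).
#' @return Pearson correlation in [-1, 1].
#' @export
loadingLogfcCorrelation <- function(pca, de, component = 1) {
  load <- pca$loadings
  if (component > ncol(load)) stop("component out of range")
  if (!setequal(rownames(load), de$protein)) {
    stop("PCA and DE tables cover different protein sets")
  }
  l <- load[, component]
  fc <- de$log2fc[match(rownames(load), de$protein)]
  if (stats::sd(fc) == 0 || stats::sd(l) == 0) {
    stop("correlation undefined: zero variance in loadings or log2fc")
  }
  stats::cor(l, fc)
}
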