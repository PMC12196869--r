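#' One-vs-rest t test and Cohen's d for a region
#'
#' Per protein, an unpaired two-tailed two-sample t test of the region's
#' samples against all other samples, with the standardized mean
#' difference (Cohen's d) computed against the pooled
#' (n-1)-weighted standard deviation. The classical equal-variance
#' Student test is the default; Welch's unequal-variance test is
#' available behind \code{welch = TRUE} (d is always pooled-SD based).
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"imputed"}
#'   and sample metadata attached.
#' @param region Region label; the region and its complement each need
#'   >= 2 samples.
#' @param welch Use Welch's test instead of Student's.
#' @return data.frame per protein: \code{protein}, \code{gene},
#'   \code{p}, \code{d}, \code{degenerate} (TRUE when the pooled
#'   variance is zero; such proteins get p = 1 and d = 0).
#' @export
oneVsRestTest <- function(x, region, welch = FALSE) {
  stopifnot(is(x, "ProteoExperiment"))
  if (procState(x) != "imputed") {
    stop("oneVsRestTest expects state 'imputed', got '", procState(x), "'")
  }
  lab <- regionLabels(x)
  i1 <- which(lab == region)
  i2 <- which(lab != region)
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("region and rest each need >= 2 samples")
  }
  v <- abundance(x)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(v[, i1, drop = FALSE])
  m2 <- rowMeans(v[, i2, drop = FALSE])
  var1 <- rowSums((v[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  var2 <- rowSums((v[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / (n1 + n2 - 2)
  degenerate <- sp2 <= .Machine$double.eps

  p <- rep(1, nrow(v))
  d <- rep(0, nrow(v))
  ok <- !degenerate
  if (welch) {
    seW <- sqrt(var1[ok] / n1 + var2[ok] / n2)
    tW <- (m1[ok] - m2[ok]) / seW
    dfW <- seW^4 / ((var1[ok] / n1)^2 / (n1 - 1) +
                      (var2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(-abs(tW), df = dfW)
  } else {
    tS <- (m1[ok] - m2[ok]) / sqrt(sp2[ok] * (1 / n1 + 1 / n2))
    p[ok] <- 2 * stats::pt(-abs(tS), df = n1 + n2 - 2)
  }
  d[ok] <- (m1[ok] - m2[ok]) / sqrt(sp2[ok])
  data.frame(protein = rownames(x), gene = unname(geneMap(x)),
             p = p, d = d, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-vs-rest statistics for every region
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"imputed"}.
#' @param welch Passed to \code{\link{oneVsRestTest}}.
#' @return Named list of per-region statistics tables, in canonical
#'   region order.
#' @export
oneVsRestAllRegions <- function(x, welch = FALSE) {
  regions <- intersect(regionLevels(), unique(regionLabels(x)))
  stats::setNames(lapply(regions, function(r) oneVsRestTest(x, r, welch)),
                  regions)
}

#' Assign up-regulated region-specific proteins
#'
#' For each protein, the candidate regions are those where its
#' one-vs-rest p value is below \code{pThreshold} and its Cohen's d is
#' positive (up-regulated). The protein is assigned to the candidate
#' region with the highest effect size; exact ties are broken by the
#' fixed canonical region order. Proteins with no candidate region stay
#' unassigned.
#'
#' @param statsByRegion Named list of per-region statistics tables from
#'   \code{\link{oneVsRestTest}}, all over the identical protein set.
#' @param pThreshold p-value threshold (default 1e-2).
#' @return A \linkS4class{RegionMarkerSets}.
#' @export
assignRegionSpecific <- function(statsByRegion, pThreshold = 1e-2) {
  regions <- names(statsByRegion)
  if (is.null(regions) || !all(regions %in% regionLevels())) {
    stop("statsByRegion must be named by region labels")
  }
  regions <- intersect(regionLevels(), regions)  # canonical tie-break order
  prot <- statsByRegion[[1L]]$protein
  for (r in regions) {
    if (!identical(statsByRegion[[r]]$protein, prot)) {
      stop("region tables cover inconsistent protein sets")
    }
  }
  asMat <- function(col, mode) {
    m <- matrix(vector(mode, 0), length(prot), length(regions),
                dimnames = list(NULL, regions))
    for (r in regions) m[, r] <- statsByRegion[[r]][[col]]
    m
  }
  pMat <- asMat("p", "numeric")
  dMat <- asMat("d", "numeric")
  degMat <- asMat("degenerate", "logical")
  eligible <- pMat < pThreshold & dMat > 0 & !degMat

  assigned <- rep(NA_character_, length(prot))
  for (i in seq_along(prot)) {
    cand <- which(eligible[i, ])
    if (length(cand)) {
      # which.max returns the first maximum: earlier region wins ties
      assigned[i] <- regions[cand[which.max(dMat[i, cand])]]
    }
  }
  keep <- !is.na(assigned)
  mk <- data.frame(
    region = assigned[keep],
    protein = prot[keep],
    gene = statsByRegion[[1L]]$gene[keep],
    p = pMat[cbind(which(keep), match(assigned[keep], regions))],
    d = dMat[cbind(which(keep), match(assigned[keep], regions))],
    stringsAsFactors = FALSE
  )
  mk <- mk[order(match(mk$region, regionLevels()), -mk$d), , drop = FALSE]
  rownames(mk) <- NULL
  new("RegionMarkerSets", markers = mk, unassigned = prot[!keep],
      pThreshold = pThreshold)
}

#' Export region marker sets as gene sets
#'
#' @param x A \linkS4class{RegionMarkerSets}.
#' @return Named list of gene vectors, one set per region with >= 1
#'   marker.
#' @export
markersAsGeneSets <- function(x) {
  mk <- markerTable(x)
  regions <- intersect(regionLevels(), unique(mk$region))
  stats::setNames(lapply(regions, function(r) markerGenes(x, r)), regions)
}
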