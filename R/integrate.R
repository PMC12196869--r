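#' z-normalize cluster profiles per feature
#'
#' For each feature (row), subtracts the mean over clusters and divides
#' by the sample standard deviation over clusters (n-1 denominator),
#' z = (X - mu) / sigma. Features constant across clusters get z = 0
#' everywhere by convention.
#'
#' @param cp \linkS4class{ClusterProfile} with >= 2 clusters.
#' @return z-scaled \linkS4class{ClusterProfile}.
#' @export
znormalizeProfiles <- function(cp) {
  stopifnot(is(cp, "ClusterProfile"))
  if (ncol(cp) < 2L) stop("need >= 2 clusters to z-normalize")
  v <- assay(cp, "avg")
  mu <- rowMeans(v)
  sdv <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1L))
  z <- (v - mu) / sdv
  z[sdv <= .Machine$double.eps, ] <- 0
  ClusterProfile(z, cellType = colData(cp)$cell_type, zscaled = TRUE)
}

#' Region-by-cluster association z-scores (Query method)
#'
#' For every (region, cluster) pair, maps the region's up-regulated
#' marker proteins to gene symbols, intersects with the reference
#' feature list, sums the cluster's z-normalized expression over the
#' intersection and divides by the intersection size. Genes absent from
#' the reference are excluded from both numerator and denominator. A
#' positive score indicates enrichment of that cluster in the region, a
#' negative score depletion; the magnitude quantifies the extent.
#'
#' @param markers \linkS4class{RegionMarkerSets} with >= 1 non-empty
#'   region.
#' @param zcp z-scaled \linkS4class{ClusterProfile} (see
#'   \code{\link{znormalizeProfiles}}).
#' @return An \linkS4class{EnrichmentMatrix}. Regions with no marker
#'   gene present among the reference features are flagged undefined
#'   (NA row), not silently zero.
#' @export
regionClusterZscore <- function(markers, zcp) {
  stopifnot(is(markers, "RegionMarkerSets"), is(zcp, "ClusterProfile"))
  if (!isZscaled(zcp)) {
    stop("cluster profile must be z-scaled; run znormalizeProfiles() first")
  }
  if (nrow(markerTable(markers)) == 0L) {
    stop("marker sets are empty for every region")
  }
  zmat <- assay(zcp, "avg")
  regions <- regionLevels()
  z <- matrix(NA_real_, length(regions), ncol(zmat),
              dimnames = list(regions, colnames(zmat)))
  nUsed <- integer(length(regions))
  undefined <- character()
  for (i in seq_along(regions)) {
    genes <- markerGenes(markers, regions[i])
    used <- intersect(genes, rownames(zmat))
    nUsed[i] <- length(used)
    if (length(used) == 0L) {
      undefined <- c(undefined, regions[i])
    } else {
      z[i, ] <- colSums(zmat[used, , drop = FALSE]) / length(used)
    }
  }
  new("EnrichmentMatrix", z = z, nGenesUsed = nUsed,
      cellType = unname(clusterCellTypes(zcp)),
      undefinedRegions = undefined)
}

#' Split an enrichment matrix into enrichment and depletion views
#'
#' The enrichment view keeps strictly positive scores (others blanked to
#' NA); the depletion view keeps strictly negative scores. A cluster is
#' omitted from a view when it has no entry of the corresponding sign in
#' any region.
#'
#' @param em An \linkS4class{EnrichmentMatrix}.
#' @return List with matrices \code{enrichment} and \code{depletion}
#'   (regions x retained clusters; cluster cell types in
#'   \code{attr(, "cellType")}).
#' @export
splitMaps <- function(em) {
  stopifnot(is(em, "EnrichmentMatrix"))
  z <- zscores(em)
  ct <- em@cellType
  view <- function(keepSign) {
    w <- z
    w[!(keepSign(w) & is.finite(w))] <- NA_real_
    keepCol <- colSums(!is.na(w)) > 0L
    out <- w[, keepCol, drop = FALSE]
    attr(out, "cellType") <- ct[keepCol]
    out
  }
  list(enrichment = view(function(v) v > 0),
       depletion = view(function(v) v < 0))
}
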