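#' Default per-cell-type cluster counts of the emulated reference
#'
#' Cluster counts per cell type mirroring the public RA synovium
#' single-cell atlas the pipeline integrates against: 9 B/plasma, 5
#' endothelial, 15 myeloid, 14 NK, 10 stromal and 24 T-cell clusters
#' (77 in total).
#'
#' @return Named integer vector over \code{\link{cellTypeLevels}}.
#' @export
defaultClusterCounts <- function() {
  stats::setNames(c(9L, 5L, 15L, 14L, 10L, 24L), cellTypeLevels())
}

.CLUSTER_PREFIX <- c("B/plasma" = "B", "Endothelial" = "E", "Myeloid" = "M",
                     "NK" = "NK", "Stromal" = "F", "T" = "T")

#' Simulate an LCM spatial-proteomics study with planted ground truth
#'
#' Generates a protein-by-sample intensity matrix, its sample metadata,
#' and a ground-truth record. The default design mirrors the profiled
#' cohort: 3 normal-healthy donors contributing lining and sublining
#' ROIs, and 6 RA donors all contributing a lining ROI, four of which
#' also contribute fibrous-sublining and immune-sublining ROIs (20
#' samples over the five region types). Passing an integer
#' \code{donorsPerGroup} instead produces a balanced design with that
#' many independent donors (one sample each) per region.
#'
#' Protein log2 abundances are drawn per protein from a normal baseline
#' (log-normal intensities), with additive donor random intercepts,
#' per-sample global shifts (exercising median normalization),
#' independent noise, and \code{effectLog2} added to each region's
#' planted marker proteins in that region's samples. Missingness is
#' missing-not-at-random: each cell is dropped with probability
#' \code{plogis(intercept + slope * log2abundance)}.
#'
#' @param nProteins Number of protein groups (>= 50).
#' @param donorsPerGroup \code{NULL} for the cohort design, or an integer
#'   number of donors (= samples) per region group.
#' @param nMarkersPerRegion Planted up-regulated markers per region;
#'   marker sets are pairwise disjoint across regions.
#' @param effectLog2 Planted marker shift, log2 units (>= 0).
#' @param noiseSd Residual noise SD, log2 units.
#' @param donorSd SD of donor random intercepts, log2 units.
#' @param sampleShiftRange Per-sample global shifts are drawn uniformly
#'   from \code{[-sampleShiftRange, sampleShiftRange]} (log2 units).
#' @param missingParams Numeric \code{c(intercept, slope)} of the
#'   abundance-to-missingness logistic; \code{c(-Inf, 0)} disables
#'   missingness entirely.
#' @param baselineMean,baselineSd Mean and SD of per-protein baseline
#'   log2 abundance.
#' @param seed Integer seed; outputs are bitwise reproducible.
#' @return List with elements \code{data}
#'   (\linkS4class{ProteoExperiment}, state \code{"raw"}, metadata
#'   attached), \code{meta} (sample metadata data.frame) and
#'   \code{truth} (a \code{SyntheticTruth} list: \code{plantedMarkers},
#'   a region-named list of data.frames with \code{protein},
#'   \code{gene}, \code{effectLog2}; \code{noiseSd};
#'   \code{missingParams}; \code{seed}).
#' @export
#' @examples
#' sim <- generateStudy(nProteins = 60, nMarkersPerRegion = 4, seed = 1)
#' sim$data
generateStudy <- function(nProteins = 1000,
                          donorsPerGroup = NULL,
                          nMarkersPerRegion = 25,
                          effectLog2 = 2,
                          noiseSd = 0.5,
                          donorSd = 0.2,
                          sampleShiftRange = 1,
                          missingParams = c(intercept = 14.3, slope = -0.8),
                          baselineMean = 20,
                          baselineSd = 2,
                          seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (nProteins < 50) stop("nProteins must be >= 50")
  if (effectLog2 < 0) stop("effectLog2 must be >= 0")
  if (nMarkersPerRegion > nProteins / 5) {
    stop("requested marker count exceeds nProteins/5")
  }
  set.seed(seed)
  regions <- regionLevels()

  meta <- if (is.null(donorsPerGroup)) {
    .cohortDesign()
  } else {
    .balancedDesign(as.integer(donorsPerGroup))
  }
  nS <- nrow(meta)

  pid <- sprintf("P%04d", seq_len(nProteins))
  gene <- sprintf("GENE%04d", seq_len(nProteins))

  markerIdx <- matrix(sample.int(nProteins, 5L * nMarkersPerRegion),
                      nrow = nMarkersPerRegion)
  colnames(markerIdx) <- regions
  plantedMarkers <- lapply(regions, function(r) {
    i <- markerIdx[, r]
    data.frame(protein = pid[i], gene = gene[i],
               effectLog2 = rep(effectLog2, length(i)),
               stringsAsFactors = FALSE)
  })
  names(plantedMarkers) <- regions

  baseline <- stats::rnorm(nProteins, baselineMean, baselineSd)
  donors <- unique(meta$donor_id)
  donorInt <- stats::setNames(stats::rnorm(length(donors), 0, donorSd), donors)
  sampleShift <- stats::runif(nS, -sampleShiftRange, sampleShiftRange)

  x <- matrix(baseline, nProteins, nS) +
    matrix(donorInt[meta$donor_id], nProteins, nS, byrow = TRUE) +
    matrix(sampleShift, nProteins, nS, byrow = TRUE) +
    matrix(stats::rnorm(nProteins * nS, 0, noiseSd), nProteins, nS)
  for (r in regions) {
    cols <- which(meta$region == r)
    if (length(cols)) x[markerIdx[, r], cols] <- x[markerIdx[, r], cols] +
        effectLog2
  }
  dimnames(x) <- list(pid, meta$sample_id)

  pMiss <- stats::plogis(missingParams[[1]] + missingParams[[2]] * x)
  drop <- matrix(stats::runif(nProteins * nS) < pMiss, nProteins, nS)
  vals <- 2^x
  vals[drop] <- NA_real_

  pe <- ProteoExperiment(vals, gene = gene, state = "raw")
  pe <- attachSampleMeta(pe, meta)

  truth <- structure(list(
    plantedMarkers = plantedMarkers,
    plantedLinks = NULL,
    effectLog2 = effectLog2,
    noiseSd = noiseSd,
    missingParams = c(intercept = missingParams[[1]],
                      slope = missingParams[[2]]),
    seed = seed,
    proteins = pid,
    genes = stats::setNames(gene, pid)
  ), class = "SyntheticTruth")

  list(data = pe, meta = meta, truth = truth)
}

.cohortDesign <- function() {
  rows <- list()
  for (d in paste0("NH", 1:3)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(d, c("_SL", "_SSL")), donor_id = d,
      disease = "NH", region = c("NH_SL", "NH_SSL"),
      stringsAsFactors = FALSE)
  }
  for (i in 1:6) {
    d <- paste0("RA", i)
    reg <- if (i >= 3) c("RA_SL", "RA_fibrous_SSL", "RA_immune_SSL")
           else "RA_SL"
    suff <- c(RA_SL = "_SL", RA_fibrous_SSL = "_fSSL",
              RA_immune_SSL = "_iSSL")[reg]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = paste0(d, suff), donor_id = d,
      disease = "RA", region = reg, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.balancedDesign <- function(n) {
  if (n < 2L) stop("donorsPerGroup must be >= 2")
  do.call(rbind, lapply(regionLevels(), function(r) {
    data.frame(sample_id = sprintf("%s_D%02d", r, seq_len(n)),
               donor_id = sprintf("%s_D%02d", r, seq_len(n)),
               disease = if (startsWith(r, "NH")) "NH" else "RA",
               region = r, stringsAsFactors = FALSE)
  }))
}

#' Simulate a cluster-averaged single-cell reference with planted links
#'
#' Builds a features-by-clusters average-expression reference emulating
#' a clustered synovium atlas: clusters are grouped into the six cell
#' types with configurable per-type counts (default
#' \code{\link{defaultClusterCounts}}, 77 clusters). The feature list
#' covers \code{coverage} of the study's gene symbols (default 99.3%)
#' plus unrelated background features. Baseline expression is drawn iid
#' per feature and cluster; for every planted (region, cluster) link the
#' linked cluster's expression of that region's planted marker genes is
#' raised by \code{linkLog2}.
#'
#' @param truth \code{SyntheticTruth} from \code{\link{generateStudy}}.
#' @param nClustersPerType Named integer vector of cluster counts over
#'   \code{\link{cellTypeLevels}}.
#' @param linkLog2 Expression boost of linked clusters on their region's
#'   marker genes (>= 0).
#' @param links Optional data.frame (\code{region}, \code{cluster}) of
#'   planted links; by default one randomly chosen cluster per region.
#' @param coverage Fraction of study gene symbols included among the
#'   reference features (>= 0.99 recommended).
#' @param extraFeatureFrac Extra background features, as a fraction of
#'   the number of study genes.
#' @param baseSd SD of baseline cluster expression.
#' @param seed Integer seed.
#' @return List with \code{profile} (\linkS4class{ClusterProfile}) and
#'   \code{truth} (input truth with \code{plantedLinks} and feature
#'   bookkeeping added).
#' @export
generateClusterProfiles <- function(truth,
                                    nClustersPerType = defaultClusterCounts(),
                                    linkLog2 = 2,
                                    links = NULL,
                                    coverage = 0.993,
                                    extraFeatureFrac = 0.2,
                                    baseSd = 1,
                                    seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (!inherits(truth, "SyntheticTruth")) {
    stop("truth must come from generateStudy()")
  }
  if (linkLog2 < 0) stop("linkLog2 must be >= 0")
  set.seed(seed)

  types <- names(nClustersPerType)
  clusters <- unlist(lapply(types, function(tp) {
    sprintf("%s-%d", .CLUSTER_PREFIX[[tp]], seq_len(nClustersPerType[[tp]]) - 1L)
  }), use.names = FALSE)
  cellType <- rep(types, nClustersPerType)

  genes <- unname(truth$genes)
  nKeep <- round(coverage * length(genes))
  kept <- sort(sample(genes, nKeep))
  nExtra <- round(extraFeatureFrac * length(genes))
  extra <- if (nExtra > 0) sprintf("BGF%05d", seq_len(nExtra)) else character()
  feats <- c(kept, extra)

  avg <- matrix(stats::rnorm(length(feats) * length(clusters), 0, baseSd),
                length(feats), length(clusters),
                dimnames = list(feats, clusters))

  if (is.null(links)) {
    links <- data.frame(region = regionLevels(),
                        cluster = sample(clusters, length(regionLevels())),
                        stringsAsFactors = FALSE)
  }
  badR <- setdiff(links$region, names(truth$plantedMarkers))
  if (length(badR)) {
    stop("link references unknown region(s): ", paste(badR, collapse = ", "))
  }
  badC <- setdiff(links$cluster, clusters)
  if (length(badC)) {
    stop("link references unknown cluster(s): ", paste(badC, collapse = ", "))
  }
  for (i in seq_len(nrow(links))) {
    mg <- intersect(truth$plantedMarkers[[links$region[i]]]$gene, feats)
    avg[mg, links$cluster[i]] <- avg[mg, links$cluster[i]] + linkLog2
  }

  truth$plantedLinks <- links
  truth$linkLog2 <- linkLog2
  truth$featureBookkeeping <- list(
    nStudyGenes = length(genes), nKept = nKeep, nExtra = length(extra),
    coveragePct = 100 * nKeep / length(genes))

  list(profile = ClusterProfile(avg, cellType = cellType), truth = truth)
}

#' Build gene sets from synthetic ground truth
#'
#' One set per region (the planted marker genes) plus random background
#' sets drawn from the study gene universe, for exercising preranked
#' GSEA on synthetic runs.
#'
#' @param truth \code{SyntheticTruth} from \code{\link{generateStudy}}.
#' @param nRandom Number of random background sets.
#' @param randomSize Genes per random set.
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
syntheticGeneSets <- function(truth, nRandom = 20, randomSize = 15, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  set.seed(seed)
  sets <- lapply(truth$plantedMarkers, function(df) unique(df$gene))
  names(sets) <- paste0("PLANTED_", names(sets))
  universe <- unname(truth$genes)
  for (i in seq_len(nRandom)) {
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(universe, randomSize)
  }
  sets
}
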