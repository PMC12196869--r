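#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Canonical synovial region-type labels
#'
#' The five histopathological region types profiled by the pipeline, in
#' their fixed display and tie-breaking order: normal-healthy lining,
#' normal-healthy sublining, RA lining, RA fibrous-rich sublining and
#' RA immune-rich sublining.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' regionLevels()
regionLevels <- function() {
  c("NH_SL", "NH_SSL", "RA_SL", "RA_fibrous_SSL", "RA_immune_SSL")
}

#' Canonical reference cell-type labels
#'
#' The six cell types annotating clusters of the single-cell reference.
#'
#' @return Character vector of length six.
#' @export
cellTypeLevels <- function() {
  c("B/plasma", "Endothelial", "Myeloid", "NK", "Stromal", "T")
}

.PROC_STATES <- c("raw", "log2", "normalized", "imputed")

#' ProteoExperiment: protein-by-sample abundance container
#'
#' Extends \linkS4class{SummarizedExperiment} with two assays:
#' \code{abundance} (numeric; \code{NA} at missing cells) and
#' \code{missing} (logical mask, identical shape), plus a processing-state
#' flag (\code{"raw"}, \code{"log2"}, \code{"normalized"} or
#' \code{"imputed"}). Row data carries the mapped gene symbol per protein
#' group; column data carries donor, disease state and region type when a
#' sample-metadata table has been attached.
#'
#' @slot state Processing state of the abundance assay.
#' @export
setClass("ProteoExperiment",
  contains = "SummarizedExperiment",
  slots = c(state = "character")
)

setValidity("ProteoExperiment", function(object) {
  msg <- character()
  an <- assayNames(object)
  if (!all(c("abundance", "missing") %in% an)) {
    msg <- c(msg, "assays 'abundance' and 'missing' are required")
  } else {
    v <- assay(object, "abundance")
    m <- assay(object, "missing")
    if (!is.logical(m)) msg <- c(msg, "'missing' assay must be logical")
    if (!identical(dim(v), dim(m))) {
      msg <- c(msg, "'abundance' and 'missing' must have identical shape")
    } else {
      if (!identical(unname(is.na(v)), unname(m == TRUE))) {
        msg <- c(msg, "missing mask must equal is.na(abundance)")
      }
      if (identical(object@state, "imputed") && any(m)) {
        msg <- c(msg, "state 'imputed' requires an all-FALSE missing mask")
      }
      if (identical(object@state, "raw") && any(v[!m] < 0, na.rm = TRUE)) {
        msg <- c(msg, "raw intensities must be >= 0 where observed")
      }
    }
  }
  if (length(object@state) != 1L || !object@state %in% .PROC_STATES) {
    msg <- c(msg, sprintf("state must be one of %s",
                          paste(.PROC_STATES, collapse = ", ")))
  }
  if (anyDuplicated(rownames(object))) {
    msg <- c(msg, "protein ids (rownames) must be unique")
  }
  if (anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample ids (colnames) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteoExperiment
#'
#' @param abundance Numeric matrix, proteins x samples. \code{NA} encodes
#'   a missing (non-detected) cell.
#' @param gene Character vector of gene symbols, one per protein
#'   (\code{NA} allowed).
#' @param sampleData Optional \code{DataFrame}/\code{data.frame} of
#'   per-sample metadata (rownames = sample ids).
#' @param state Processing state; default \code{"raw"}.
#' @return A \linkS4class{ProteoExperiment}.
#' @export
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' pe <- ProteoExperiment(m, gene = c("FN1", "OGN", "LUM"))
#' pe
ProteoExperiment <- function(abundance, gene = NULL, sampleData = NULL,
                             state = "raw") {
  abundance <- as.matrix(abundance)
  storage.mode(abundance) <- "double"
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance must have protein rownames and sample colnames")
  }
  miss <- is.na(abundance)
  rd <- DataFrame(gene = if (is.null(gene)) rep(NA_character_, nrow(abundance))
                  else as.character(gene),
                  row.names = rownames(abundance))
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(abundance))
  } else {
    DataFrame(sampleData, row.names = colnames(abundance))
  }
  se <- SummarizedExperiment(
    assays = list(abundance = abundance, missing = miss),
    rowData = rd, colData = cd
  )
  new("ProteoExperiment", se, state = state)
}

#' @describeIn ProteoExperiment-accessors Abundance matrix (NA at missing
#'   cells).
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' Accessors for ProteoExperiment
#'
#' @param x A \linkS4class{ProteoExperiment}.
#' @name ProteoExperiment-accessors
#' @aliases abundance missingMask procState geneMap regionLabels
NULL

#' @rdname ProteoExperiment-accessors
#' @export
setMethod("abundance", "ProteoExperiment", function(x) assay(x, "abundance"))

#' @rdname ProteoExperiment-accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname ProteoExperiment-accessors
#' @export
setMethod("missingMask", "ProteoExperiment",
          function(x) assay(x, "missing"))

#' @rdname ProteoExperiment-accessors
#' @export
setGeneric("procState", function(x) standardGeneric("procState"))

#' @rdname ProteoExperiment-accessors
#' @export
setMethod("procState", "ProteoExperiment", function(x) x@state)

#' @rdname ProteoExperiment-accessors
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))

#' @rdname ProteoExperiment-accessors
#' @export
setMethod("geneMap", "ProteoExperiment", function(x) {
  g <- rowData(x)$gene
  names(g) <- rownames(x)
  g
})

#' @rdname ProteoExperiment-accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname ProteoExperiment-accessors
#' @export
setMethod("regionLabels", "ProteoExperiment", function(x) {
  r <- colData(x)$region
  if (is.null(r)) stop("no sample metadata attached; see attachSampleMeta()")
  setNames(as.character(r), colnames(x))
})

setMethod("show", "ProteoExperiment", function(object) {
  cat(sprintf("ProteoExperiment: %d proteins x %d samples [state: %s]\n",
              nrow(object), ncol(object), object@state))
  cat(sprintf("  missing cells: %d (%.1f%%)\n",
              sum(assay(object, "missing")),
              100 * mean(assay(object, "missing"))))
  if (!is.null(colData(object)$region)) {
    tb <- table(colData(object)$region)
    cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "),
        "\n")
  } else {
    cat("  regions: <no sample metadata attached>\n")
  }
})

#' Attach validated sample metadata to a ProteoExperiment
#'
#' Every sample of \code{x} must appear exactly once in \code{meta};
#' disease/region consistency is enforced by \code{\link{validateSampleMeta}}.
#'
#' @param x A \linkS4class{ProteoExperiment}.
#' @param meta data.frame with columns \code{sample_id}, \code{donor_id},
#'   \code{disease}, \code{region}.
#' @return \code{x} with populated \code{colData}.
#' @export
attachSampleMeta <- function(x, meta) {
  meta <- validateSampleMeta(meta)
  missing <- setdiff(colnames(x), meta$sample_id)
  if (length(missing)) {
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(x), meta$sample_id), , drop = FALSE]
  colData(x)$donor_id <- meta$donor_id
  colData(x)$disease <- meta$disease
  colData(x)$region <- factor(meta$region, levels = regionLevels())
  validObject(x)
  x
}

#' ClusterProfile: cluster-averaged expression reference
#'
#' Extends \linkS4class{SummarizedExperiment}: one \code{avg} assay of
#' features x clusters average expression, with a per-cluster cell-type
#' annotation in \code{colData} and a flag recording whether rows have
#' been z-normalized across clusters.
#'
#' @slot zscaled Logical; \code{TRUE} after \code{\link{znormalizeProfiles}}.
#' @export
setClass("ClusterProfile",
  contains = "SummarizedExperiment",
  slots = c(zscaled = "logical")
)

setValidity("ClusterProfile", function(object) {
  msg <- character()
  if (!"avg" %in% assayNames(object)) {
    msg <- c(msg, "assay 'avg' is required")
  } else if (anyNA(assay(object, "avg"))) {
    msg <- c(msg, "cluster profiles must have no missing entries")
  }
  if (is.null(colData(object)$cell_type)) {
    msg <- c(msg, "colData must carry a 'cell_type' annotation")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate feature names")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate cluster ids")
  if (length(object@zscaled) != 1L) msg <- c(msg, "zscaled must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterProfile
#'
#' @param avg Numeric matrix, features x clusters (no \code{NA}).
#' @param cellType Character vector mapping each cluster (column) to its
#'   cell type.
#' @param zscaled Logical flag; \code{TRUE} when rows are already
#'   z-normalized across clusters.
#' @return A \linkS4class{ClusterProfile}.
#' @export
ClusterProfile <- function(avg, cellType, zscaled = FALSE) {
  avg <- as.matrix(avg)
  storage.mode(avg) <- "double"
  if (is.null(rownames(avg)) || is.null(colnames(avg))) {
    stop("avg must have feature rownames and cluster colnames")
  }
  if (length(cellType) != ncol(avg)) {
    stop("cellType must annotate every cluster")
  }
  se <- SummarizedExperiment(
    assays = list(avg = avg),
    colData = DataFrame(cell_type = as.character(cellType),
                        row.names = colnames(avg))
  )
  new("ClusterProfile", se, zscaled = zscaled)
}

#' @rdname ClusterProfile-accessors
#' @export
setGeneric("clusterCellTypes", function(x) standardGeneric("clusterCellTypes"))

#' Accessors for ClusterProfile
#'
#' @param x A \linkS4class{ClusterProfile}.
#' @name ClusterProfile-accessors
NULL

#' @rdname ClusterProfile-accessors
#' @export
setMethod("clusterCellTypes", "ClusterProfile", function(x) {
  setNames(colData(x)$cell_type, colnames(x))
})

#' @rdname ClusterProfile-accessors
#' @export
setGeneric("isZscaled", function(x) standardGeneric("isZscaled"))

#' @rdname ClusterProfile-accessors
#' @export
setMethod("isZscaled", "ClusterProfile", function(x) x@zscaled)

setMethod("show", "ClusterProfile", function(object) {
  tb <- table(colData(object)$cell_type)
  cat(sprintf("ClusterProfile: %d features x %d clusters%s\n",
              nrow(object), ncol(object),
              if (object@zscaled) " (z-scaled)" else ""))
  cat("  cell types:", paste(sprintf("%s=%d", names(tb), tb),
                             collapse = " "), "\n")
})

#' RegionMarkerSets: up-regulated region-specific proteins
#'
#' Result of \code{\link{assignRegionSpecific}}: per region, the proteins
#' assigned to it with their one-vs-rest p value and Cohen's d, plus the
#' unassigned remainder of the protein universe.
#'
#' @slot markers data.frame with columns \code{region}, \code{protein},
#'   \code{gene}, \code{p}, \code{d}.
#' @slot unassigned Character vector of protein ids assigned to no region.
#' @slot pThreshold The p-value threshold used for assignment.
#' @export
setClass("RegionMarkerSets",
  slots = c(markers = "data.frame", unassigned = "character",
            pThreshold = "numeric")
)

setValidity("RegionMarkerSets", function(object) {
  msg <- character()
  mk <- object@markers
  need <- c("region", "protein", "gene", "p", "d")
  if (!all(need %in% names(mk))) {
    msg <- c(msg, sprintf("markers must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(mk$protein)) {
      msg <- c(msg, "a protein may be assigned to at most one region")
    }
    if (nrow(mk) && any(mk$p >= object@pThreshold | mk$d <= 0)) {
      msg <- c(msg, "markers must satisfy p < threshold and d > 0")
    }
    if (length(intersect(mk$protein, object@unassigned))) {
      msg <- c(msg, "assigned and unassigned sets must be disjoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RegionMarkerSets-accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' Accessors for RegionMarkerSets
#'
#' @param x A \linkS4class{RegionMarkerSets}.
#' @param region Optional region label to subset to.
#' @name RegionMarkerSets-accessors
NULL

#' @rdname RegionMarkerSets-accessors
#' @export
setMethod("markerTable", "RegionMarkerSets", function(x) x@markers)

#' @rdname RegionMarkerSets-accessors
#' @export
setGeneric("markerGenes", function(x, region) standardGeneric("markerGenes"))

#' @rdname RegionMarkerSets-accessors
#' @export
setMethod("markerGenes", "RegionMarkerSets", function(x, region) {
  mk <- x@markers[x@markers$region == region, , drop = FALSE]
  g <- ifelse(is.na(mk$gene) | mk$gene == "", mk$protein, mk$gene)
  unique(g)
})

#' @rdname RegionMarkerSets-accessors
#' @export
setGeneric("unassignedProteins",
           function(x) standardGeneric("unassignedProteins"))

#' @rdname RegionMarkerSets-accessors
#' @export
setMethod("unassignedProteins", "RegionMarkerSets",
          function(x) x@unassigned)

setMethod("show", "RegionMarkerSets", function(object) {
  cat(sprintf("RegionMarkerSets (p < %g):\n", object@pThreshold))
  for (r in regionLevels()) {
    cat(sprintf("  %-15s %d markers\n", r,
                sum(object@markers$region == r)))
  }
  cat(sprintf("  unassigned: %d proteins\n", length(object@unassigned)))
})

#' EnrichmentMatrix: region-by-cluster association z-scores
#'
#' Result of the Query integration: one z-score per (region, cluster)
#' pair, the mean z-normalized cluster expression of the region's marker
#' genes. Positive values indicate enrichment of the cluster in the
#' region, negative values depletion.
#'
#' @slot z Numeric matrix, regions x clusters (rows in fixed region
#'   order; NA rows for regions whose markers have no feature overlap).
#' @slot nGenesUsed Integer per region: marker genes found in the
#'   reference feature list.
#' @slot cellType Character vector annotating each cluster column.
#' @slot undefinedRegions Regions whose marker genes had empty
#'   intersection with the reference features.
#' @export
setClass("EnrichmentMatrix",
  slots = c(z = "matrix", nGenesUsed = "integer", cellType = "character",
            undefinedRegions = "character")
)

setValidity("EnrichmentMatrix", function(object) {
  msg <- character()
  if (length(object@cellType) != ncol(object@z)) {
    msg <- c(msg, "cellType must annotate every cluster column")
  }
  if (length(object@nGenesUsed) != nrow(object@z)) {
    msg <- c(msg, "nGenesUsed must have one entry per region row")
  }
  ok <- object@nGenesUsed > 0
  if (any(!is.finite(object@z[ok, , drop = FALSE]))) {
    msg <- c(msg, "z must be finite wherever nGenesUsed > 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname EnrichmentMatrix-accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' Accessors for EnrichmentMatrix
#'
#' @param x An \linkS4class{EnrichmentMatrix}.
#' @name EnrichmentMatrix-accessors
NULL

#' @rdname EnrichmentMatrix-accessors
#' @export
setMethod("zscores", "EnrichmentMatrix", function(x) x@z)

#' @rdname EnrichmentMatrix-accessors
#' @export
setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))

#' @rdname EnrichmentMatrix-accessors
#' @export
setMethod("genesUsed", "EnrichmentMatrix", function(x) {
  setNames(x@nGenesUsed, rownames(x@z))
})

setMethod("show", "EnrichmentMatrix", function(object) {
  cat(sprintf("EnrichmentMatrix: %d regions x %d clusters\n",
              nrow(object@z), ncol(object@z)))
  cat("  genes used per region:",
      paste(sprintf("%s=%d", rownames(object@z), object@nGenesUsed),
            collapse = " "), "\n")
  if (length(object@undefinedRegions)) {
    cat("  undefined regions:",
        paste(object@undefinedRegions, collapse = ", "), "\n")
  }
})
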