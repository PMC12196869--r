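#' Default annotation columns of a DIA-NN pg_matrix file
#'
#' Header fields preceding the per-sample intensity columns in the
#' protein-group matrix written by DIA-NN. Everything after these is
#' treated as a sample column.
#'
#' @return Character vector of column names.
#' @export
pgAnnotationColumns <- function() {
  c("Protein.Group", "Protein.Ids", "Protein.Names", "Genes",
    "First.Protein.Description")
}

#' Read a DIA-NN protein-group abundance matrix
#'
#' Parses the tab-separated \code{pg_matrix} dialect: annotation columns
#' (at minimum a protein-group id column and a genes column) followed by
#' one intensity column per sample. Blank cells, \code{NA}, \code{NaN}
#' and zero intensities all encode non-detection and become missing.
#' Multi-gene protein groups are mapped to the first semicolon-separated
#' gene token.
#'
#' @param path Path to the TSV file.
#' @param annotationCols Annotation column names; sample columns are all
#'   header fields not in this set. Default \code{\link{pgAnnotationColumns}}.
#' @param idCol,genesCol Names of the protein-group id and genes columns.
#' @return A \linkS4class{ProteoExperiment} with \code{state = "raw"}.
#' @export
readPgMatrix <- function(path, annotationCols = pgAnnotationColumns(),
                         idCol = "Protein.Group", genesCol = "Genes") {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("", "NA", "NaN"))
  if (!idCol %in% names(tab)) {
    stop("pg_matrix is missing the protein-group id column '", idCol, "'")
  }
  sampleCols <- setdiff(names(tab), annotationCols)
  if (length(sampleCols) == 0L) {
    stop("pg_matrix has no sample intensity columns")
  }
  ids <- tab[[idCol]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate protein-group ids: ", paste(dup, collapse = ", "))
  }
  vals <- vapply(sampleCols, function(cn) {
    suppressWarnings(as.numeric(tab[[cn]]))
  }, numeric(nrow(tab)))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(ids, sampleCols))
  vals[!is.na(vals) & vals == 0] <- NA_real_
  genes <- if (genesCol %in% names(tab)) {
    vapply(strsplit(ifelse(is.na(tab[[genesCol]]), "", tab[[genesCol]]), ";",
                    fixed = TRUE),
           function(x) if (length(x)) x[[1L]] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, nrow(tab))
  }
  genes[genes == ""] <- NA_character_
  ProteoExperiment(vals, gene = genes, state = "raw")
}

#' Validate a sample-metadata table
#'
#' Checks the four required columns, known region labels, disease/region
#' consistency (disease is NH iff the region is an NH region) and unique
#' sample ids.
#'
#' @param meta data.frame with columns \code{sample_id}, \code{donor_id},
#'   \code{disease} (NH or RA) and \code{region}
#'   (one of \code{\link{regionLevels}}).
#' @return The validated data.frame, region as a factor in canonical order.
#' @export
validateSampleMeta <- function(meta) {
  need <- c("sample_id", "donor_id", "disease", "region")
  if (!all(need %in% names(meta))) {
    stop("sample metadata must have columns ", paste(need, collapse = ", "))
  }
  meta <- as.data.frame(meta)[need]
  for (cn in need) meta[[cn]] <- as.character(meta[[cn]])
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  bad <- setdiff(meta$region, regionLevels())
  if (length(bad)) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }
  if (!all(meta$disease %in% c("NH", "RA"))) {
    stop("disease must be 'NH' or 'RA'")
  }
  isNH <- meta$region %in% c("NH_SL", "NH_SSL")
  mism <- (meta$disease == "NH") != isNH
  if (any(mism)) {
    stop("disease/region mismatch for sample(s): ",
         paste(meta$sample_id[mism], collapse = ", "))
  }
  meta$region <- factor(meta$region, levels = regionLevels())
  meta
}

#' Read a sample-metadata table
#'
#' @param path Path to a tab- or comma-separated table with columns
#'   \code{sample_id}, \code{donor_id}, \code{disease}, \code{region}.
#' @param sep Field separator (default tab).
#' @return Validated data.frame; see \code{\link{validateSampleMeta}}.
#' @export
readSampleMeta <- function(path, sep = "\t") {
  meta <- utils::read.delim(path, sep = sep, header = TRUE,
                            check.names = FALSE,
                            colClasses = "character")
  validateSampleMeta(meta)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members, tab-separated.
#' Duplicate members within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return Named list of unique character vectors; set descriptions in
#'   \code{attr(, "description")}.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(which(nf < 3L), collapse = ", "))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(desc, nm)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions (default the set name).
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a cluster-averaged expression reference
#'
#' Reads a features x clusters delimited matrix and a two-column cluster
#' annotation table (\code{cluster}, \code{cell_type}). Every cluster
#' column of the matrix must be annotated.
#'
#' @param path Path to the expression matrix TSV (first column = feature).
#' @param annotationPath Path to the cluster annotation TSV.
#' @return A \linkS4class{ClusterProfile}.
#' @export
readClusterProfiles <- function(path, annotationPath) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE)
  feats <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- feats
  ann <- utils::read.delim(annotationPath, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (!all(c("cluster", "cell_type") %in% names(ann))) {
    stop("annotation must have columns 'cluster' and 'cell_type'")
  }
  if (anyDuplicated(ann$cluster)) {
    stop("duplicate cluster annotation(s): ",
         paste(unique(ann$cluster[duplicated(ann$cluster)]), collapse = ", "))
  }
  unknown <- setdiff(colnames(mat), ann$cluster)
  if (length(unknown)) {
    stop("cluster(s) present in matrix but absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  ct <- ann$cell_type[match(colnames(mat), ann$cluster)]
  ClusterProfile(mat, cellType = ct)
}

#' Export pipeline objects as TSV
#'
#' Writes matrix-like results as tab-separated text such that the
#' matching import returns an equal object (within float print
#' precision). Methods exist for \linkS4class{ProteoExperiment}
#' (columns: protein, gene, then samples; missing cells blank),
#' \linkS4class{EnrichmentMatrix} (region rows, cluster columns),
#' \linkS4class{RegionMarkerSets}, data.frame and matrix.
#'
#' @param obj Object to write.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
setGeneric("exportTsv", function(obj, path) standardGeneric("exportTsv"))

.writeTsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' @rdname exportTsv
#' @export
setMethod("exportTsv", "ProteoExperiment", function(obj, path) {
  df <- data.frame(protein = rownames(obj), gene = geneMap(obj),
                   state = procState(obj),
                   as.data.frame(abundance(obj), check.names = FALSE),
                   check.names = FALSE)
  .writeTsv(df, path)
})

#' @rdname exportTsv
#' @export
setMethod("exportTsv", "EnrichmentMatrix", function(obj, path) {
  df <- data.frame(region = rownames(obj@z),
                   n_genes_used = obj@nGenesUsed,
                   as.data.frame(obj@z, check.names = FALSE),
                   check.names = FALSE)
  .writeTsv(df, path)
})

#' @rdname exportTsv
#' @export
setMethod("exportTsv", "RegionMarkerSets", function(obj, path) {
  .writeTsv(obj@markers, path)
})

#' @rdname exportTsv
#' @export
setMethod("exportTsv", "data.frame", function(obj, path) {
  .writeTsv(obj, path)
})

#' @rdname exportTsv
#' @export
setMethod("exportTsv", "matrix", function(obj, path) {
  df <- data.frame(id = rownames(obj),
                   as.data.frame(obj, check.names = FALSE),
                   check.names = FALSE)
  .writeTsv(df, path)
})

#' Import a ProteoExperiment written by exportTsv
#'
#' @param path Path to the TSV written by
#'   \code{exportTsv(<ProteoExperiment>, path)}.
#' @return A \linkS4class{ProteoExperiment}.
#' @export
importAbundanceTsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE,
                           na.strings = c("", "NA", "NaN"))
  state <- unique(as.character(tab$state))
  vals <- as.matrix(tab[, setdiff(names(tab), c("protein", "gene", "state")),
                        drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(tab$protein)
  ProteoExperiment(vals, gene = as.character(tab$gene), state = state)
}
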