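.CONFIG_KEYS <- c("paths", "thresholds", "seed", "contrasts", "outdir",
                  "simulate", "gsea", "impute")
.THRESHOLD_KEYS <- c("maxMissingFrac", "fdr", "fc", "markerP")

.defaultThresholds <- function() {
  list(maxMissingFrac = 0.5, fdr = 0.05, fc = 2, markerP = 1e-2)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes an equivalent list),
#' fills defaults and range-checks thresholds. Recognized top-level
#' keys: \code{paths} (pg_matrix, metadata, cluster_profile, annotation,
#' gmt), \code{thresholds} (maxMissingFrac, fdr, fc, markerP),
#' \code{seed}, \code{contrasts} (list of two-element region pairs;
#' default all 10), \code{outdir}, \code{simulate} (generator arguments
#' for a synthetic run; when present, \code{paths} is ignored),
#' \code{gsea} (nPerm, minSize, maxSize) and \code{impute} (maxIter,
#' numTrees).
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return Validated config list of class \code{"RunConfig"}.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  th <- utils::modifyList(.defaultThresholds(),
                          as.list(config$thresholds))
  unknownTh <- setdiff(names(th), .THRESHOLD_KEYS)
  if (length(unknownTh)) {
    stop("unknown threshold key(s): ", paste(unknownTh, collapse = ", "))
  }
  if (th$maxMissingFrac <= 0 || th$maxMissingFrac >= 1) {
    stop("maxMissingFrac must lie in (0, 1)")
  }
  if (th$fdr <= 0 || th$fdr >= 1) stop("fdr must lie in (0, 1)")
  if (th$fc <= 1) stop("fc must be > 1")
  if (th$markerP <= 0 || th$markerP >= 1) stop("markerP must lie in (0, 1)")
  config$thresholds <- th
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)

  if (is.null(config$contrasts)) {
    cb <- utils::combn(regionLevels(), 2)
    config$contrasts <- lapply(seq_len(ncol(cb)), function(i) cb[, i])
  } else {
    config$contrasts <- lapply(config$contrasts, function(p) {
      p <- unlist(p)
      if (length(p) != 2L || !all(p %in% regionLevels())) {
        stop("each contrast must be a pair of region labels")
      }
      p
    })
  }
  if (is.null(config$outdir)) config$outdir <- "spatLCM_out"

  config$gsea <- utils::modifyList(
    list(nPerm = 500, minSize = 10, maxSize = 500), as.list(config$gsea))
  config$impute <- utils::modifyList(
    list(maxIter = 10, numTrees = 100), as.list(config$impute))

  if (is.null(config$simulate)) {
    pp <- config$paths
    for (key in c("pg_matrix", "metadata")) {
      if (is.null(pp[[key]])) stop("paths$", key, " is required")
      if (!file.exists(pp[[key]])) {
        stop("paths$", key, " does not exist: ", pp[[key]])
      }
    }
    for (key in c("cluster_profile", "annotation", "gmt")) {
      if (!is.null(pp[[key]]) && !file.exists(pp[[key]])) {
        stop("paths$", key, " does not exist: ", pp[[key]])
      }
    }
  }
  structure(config, class = c("RunConfig", "list"))
}

.stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes filter, log2 transform, median normalization, imputation,
#' PCA, all configured pairwise differential-expression contrasts,
#' region-marker extraction, cluster-reference integration and preranked
#' GSEA; writes every stage artifact as TSV plus a machine-readable
#' \code{summary.json} into the output directory. Identical
#' configuration and seed give byte-identical summaries.
#'
#' @param config A \code{RunConfig} (see \code{\link{validateConfig}}),
#'   or a path/list coercible to one.
#' @param force Overwrite an existing completed output directory.
#' @return Invisibly, the run summary list.
#' @export
runPipeline <- function(config, force = FALSE) {
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  outdir <- config$outdir
  if (file.exists(file.path(outdir, "summary.json")) && !force) {
    stop("output directory already holds a completed run; use force = TRUE")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  t0 <- proc.time()[["elapsed"]]

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  profile <- NULL
  geneSets <- NULL
  if (!is.null(config$simulate)) {
    sim <- withStage("simulate", {
      args <- config$simulate
      args$seed <- config$seed
      do.call(generateStudy, args)
    })
    pe <- sim$data
    truth <- sim$truth
    cp <- withStage("simulate", generateClusterProfiles(
      truth, seed = config$seed + 1L))
    profile <- cp$profile
    truth <- cp$truth
    geneSets <- syntheticGeneSets(truth, seed = config$seed + 2L)
    writeGmt(geneSets, file.path(outdir, "gene_sets.gmt"))
    .stageLog("simulate", "%d proteins x %d samples, %d clusters",
              nrow(pe), ncol(pe), ncol(profile))
  } else {
    pe <- withStage("read", {
      x <- readPgMatrix(config$paths$pg_matrix)
      attachSampleMeta(x, readSampleMeta(config$paths$metadata))
    })
    if (!is.null(config$paths$cluster_profile)) {
      profile <- withStage("read", readClusterProfiles(
        config$paths$cluster_profile, config$paths$annotation))
    }
    if (!is.null(config$paths$gmt)) {
      geneSets <- withStage("read", readGmt(config$paths$gmt))
    }
    .stageLog("read", "%d proteins x %d samples", nrow(pe), ncol(pe))
  }
  nInput <- nrow(pe)

  pe <- withStage("filter", filterMissing(pe, maxFrac = th$maxMissingFrac))
  .stageLog("filter", "%d proteins retained", nrow(pe))
  pe <- withStage("log2", log2Transform(pe))
  pe <- withStage("normalize", medianNormalize(pe))
  exportTsv(pe, file.path(outdir, "normalized.tsv"))
  pe <- withStage("impute", imputeMissing(
    pe, seed = config$seed + 3L,
    maxIter = config$impute$maxIter, numTrees = config$impute$numTrees))
  exportTsv(pe, file.path(outdir, "imputed.tsv"))
  .stageLog("impute", "matrix complete (%d x %d)", nrow(pe), ncol(pe))

  pca <- withStage("pca", runPca(pe, nComponents = min(5L, ncol(pe) - 1L)))
  exportTsv(pca$scores, file.path(outdir, "pca_scores.tsv"))
  exportTsv(pca$loadings, file.path(outdir, "pca_loadings.tsv"))
  .stageLog("pca", "PC1 %.1f%% of variance", 100 * pca$explainedVariance[1])

  present <- table(regionLabels(pe))
  deTables <- list()
  deSummary <- list()
  for (ct in config$contrasts) {
    a <- ct[1]; b <- ct[2]
    if (is.na(present[a]) || is.na(present[b]) ||
        present[a] < 2 || present[b] < 2) next
    nm <- paste0(a, "_vs_", b)
    de <- withStage("de", fitModeratedDE(
      pe, a, b, fdrThreshold = th$fdr, fcThreshold = th$fc))
    deTables[[nm]] <- de
    exportTsv(de, file.path(outdir, paste0("de_", nm, ".tsv")))
    cnt <- attr(de, "counts")
    deSummary[[nm]] <- list(up = unname(cnt["up"]), down = unname(cnt["down"]))
  }
  .stageLog("de", "%d contrasts", length(deTables))

  ovr <- withStage("markers", oneVsRestAllRegions(pe))
  markers <- withStage("markers", assignRegionSpecific(
    ovr, pThreshold = th$markerP))
  exportTsv(markers, file.path(outdir, "markers.tsv"))
  writeGmt(markersAsGeneSets(markers), file.path(outdir, "markers.gmt"))
  mkCounts <- vapply(regionLevels(), function(r) {
    sum(markerTable(markers)$region == r)
  }, integer(1))
  .stageLog("markers", "%s",
            paste(sprintf("%s=%d", names(mkCounts), mkCounts),
                  collapse = " "))

  integration <- NULL
  if (!is.null(profile)) {
    zcp <- withStage("integrate", znormalizeProfiles(profile))
    em <- withStage("integrate", regionClusterZscore(markers, zcp))
    views <- splitMaps(em)
    exportTsv(em, file.path(outdir, "enrichment.tsv"))
    z <- zscores(em)
    integration <- lapply(rownames(z), function(r) {
      if (all(is.na(z[r, ]))) return(list(top_cluster = NA, z = NA))
      i <- which.max(z[r, ])
      list(top_cluster = colnames(z)[i], z = unname(z[r, i]))
    })
    names(integration) <- rownames(z)
    .stageLog("integrate", "%d clusters in enrichment view",
              ncol(views$enrichment))
  }

  gseaTop <- NULL
  if (!is.null(geneSets) && length(deTables)) {
    gseaTop <- list()
    for (nm in names(deTables)) {
      de <- deTables[[nm]]
      ranking <- stats::setNames(de$log2fc, ifelse(
        is.na(de$gene) | de$gene == "", de$protein, de$gene))
      ranking <- ranking[!duplicated(names(ranking))]
      gres <- withStage("gsea", gseaPreranked(
        ranking, geneSets, nPerm = config$gsea$nPerm,
        minSize = config$gsea$minSize, maxSize = config$gsea$maxSize,
        seed = config$seed + 4L))
      exportTsv(gres, file.path(outdir, paste0("gsea_", nm, ".tsv")))
      act <- gres$set[gres$direction == "activated"]
      sup <- gres$set[gres$direction == "suppressed"]
      gseaTop[[nm]] <- list(
        top_activated = if (length(act)) act[1] else NA,
        top_suppressed = if (length(sup)) sup[length(sup)] else NA)
    }
    .stageLog("gsea", "%d contrasts scored", length(gseaTop))
  }

  summary <- list(
    seed = config$seed,
    thresholds = th,
    n_samples = ncol(pe),
    n_proteins = list(input = nInput, filtered = nrow(pe)),
    pc1_variance_pct = round(100 * pca$explainedVariance[1], 6),
    de_contrasts = deSummary,
    marker_counts = as.list(mkCounts),
    integration = integration,
    gsea = gseaTop
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  .stageLog("done", "%.1f s elapsed", proc.time()[["elapsed"]] - t0)
  invisible(summary)
}
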