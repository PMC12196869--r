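# In-code fixtures shared across test files. Everything is generated at
# test time; no binary data.

# Write a tiny pg_matrix-dialect TSV and return its path.
writePgFixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "pg_matrix.tsv")
  writeLines(lines, path)
  path
}

pgHeader <- function(samples) {
  paste(c("Protein.Group", "Protein.Ids", "Protein.Names", "Genes",
          "First.Protein.Description", samples), collapse = "\t")
}

# A minimal imputed-state ProteoExperiment with attached metadata.
makeImputedPE <- function(values, regions, genes = NULL) {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  }
  meta <- data.frame(
    sample_id = colnames(values),
    donor_id = colnames(values),
    disease = ifelse(startsWith(regions, "NH"), "NH", "RA"),
    region = regions, stringsAsFactors = FALSE)
  pe <- ProteoExperiment(values, gene = genes, state = "imputed")
  attachSampleMeta(pe, meta)
}

# Balanced five-region metadata: n samples per region.
balancedMeta <- function(n) {
  regions <- rep(regionLevels(), each = n)
  data.frame(
    sample_id = sprintf("%s_%d", regions, rep(seq_len(n), times = 5)),
    donor_id = sprintf("%s_%d", regions, rep(seq_len(n), times = 5)),
    disease = ifelse(startsWith(regions, "NH"), "NH", "RA"),
    region = regions, stringsAsFactors = FALSE)
}

# Quadratic-time brute-force BH step-up, independent of p.adjust():
# q_i = min over all p_j >= p_i of m * p_j / #{p <= p_j}, capped at 1.
bruteForceBH <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) m * t / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# Direct evaluation of the missingness-filter rule for one protein's
# missingness pattern (logical vector over samples) and a region factor.
filterRuleOracle <- function(missPattern, regions, maxFrac = 0.5) {
  overall <- mean(missPattern) < maxFrac
  groupComplete <- any(vapply(split(missPattern, regions),
                              function(g) !any(g), logical(1)))
  overall || groupComplete
}
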