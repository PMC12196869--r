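rawPE <- function(values, meta) {
  pe <- ProteoExperiment(values, state = "raw")
  attachSampleMeta(pe, meta)
}

test_that("the missingness filter keeps region-complete or mostly-observed proteins", {
  meta <- balancedMeta(2)  # 10 samples, 2 per region
  v <- matrix(100, 3, 10, dimnames = list(paste0("P", 1:3), meta$sample_id))
  # P1: missing in 6/10 samples and >=1 missing per region group -> dropped
  v[1, c(1, 2, 3, 5, 7, 9)] <- NA
  # P2: fully observed -> kept
  # P3: 60% missing overall, but region group 5 fully observed -> kept
  v[3, 1:6] <- NA
  kept <- rownames(filterMissing(rawPE(v, meta)))
  expect_identical(kept, c("P2", "P3"))
})

test_that("filter decisions equal the truth-table rule on enumerated patterns", {
  meta <- balancedMeta(2)
  regions <- factor(meta$region, levels = regionLevels())
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), 10))[1:200, ]
  v <- matrix(50, nrow(patterns), 10,
              dimnames = list(sprintf("P%03d", seq_len(nrow(patterns))),
                              meta$sample_id))
  v[as.matrix(patterns)] <- NA
  keep <- rownames(filterMissing(rawPE(v, meta)))
  oracle <- vapply(seq_len(nrow(patterns)), function(i) {
    filterRuleOracle(unlist(patterns[i, ]), regions)
  }, logical(1))
  expect_identical(keep, rownames(v)[oracle])
})

test_that("relaxing maxFrac never drops a previously kept protein", {
  set.seed(31)
  meta <- balancedMeta(2)
  v <- matrix(10, 200, 10,
              dimnames = list(sprintf("P%03d", 1:200), meta$sample_id))
  v[matrix(runif(2000) < 0.4, 200, 10)] <- NA
  v[1, ] <- 10  # guarantee a non-empty result at every threshold
  pe <- rawPE(v, meta)
  kept3 <- rownames(filterMissing(pe, maxFrac = 0.3))
  kept5 <- rownames(filterMissing(pe, maxFrac = 0.5))
  kept8 <- rownames(filterMissing(pe, maxFrac = 0.8))
  expect_true(all(kept3 %in% kept5))
  expect_true(all(kept5 %in% kept8))
})

test_that("log2 transform inverts exactly and guards its domain", {
  meta <- balancedMeta(2)
  set.seed(4)
  v <- matrix(2^runif(500, 1, 25), 50, 10,
              dimnames = list(sprintf("P%02d", 1:50), meta$sample_id))
  v[1, 1] <- 8; v[1, 2] <- 1
  pe <- rawPE(v, meta)
  lg <- log2Transform(pe)
  expect_identical(procState(lg), "log2")
  expect_equal(2^abundance(lg), v, tolerance = 1e-12)
  expect_identical(unname(abundance(lg)[1, 1:2]), c(3, 0))
  expect_identical(missingMask(lg), missingMask(pe))
  expect_error(log2Transform(lg), "state 'raw'")
})

test_that("median normalization equalizes sample medians at the grand median", {
  set.seed(12)
  meta <- balancedMeta(2)
  v <- matrix(rnorm(400, 20, 2), 50, 8)
  dimnames(v) <- list(sprintf("P%02d", 1:50), meta$sample_id[1:8])
  v[sample(400, 60)] <- NA
  stopifnot(all(colSums(!is.na(v)) > 0))
  pe <- ProteoExperiment(2^v, state = "raw")
  pe <- attachSampleMeta(pe, meta[1:8, ])
  lg <- log2Transform(pe)
  preMeds <- apply(abundance(lg), 2, median, na.rm = TRUE)
  nm <- medianNormalize(lg)
  postMeds <- apply(abundance(nm), 2, median, na.rm = TRUE)
  expect_equal(unname(postMeds), rep(median(preMeds), 8), tolerance = 1e-9)
  expect_identical(missingMask(nm), missingMask(lg))
  # a pure per-sample shift is removed
  v2 <- abundance(lg)
  v2[, 1] <- v2[, 1] + 3
  lg2 <- lg
  SummarizedExperiment::assay(lg2, "abundance") <- v2
  nm2 <- medianNormalize(lg2)
  m2 <- apply(abundance(nm2), 2, median, na.rm = TRUE)
  expect_equal(max(m2) - min(m2), 0, tolerance = 1e-9)
  # idempotence
  nm3 <- medianNormalize(nm)
  expect_equal(abundance(nm3), abundance(nm), tolerance = 1e-12)
})

test_that("imputation is a seeded no-op on complete data and never touches observed cells", {
  set.seed(77)
  meta <- balancedMeta(2)
  v <- matrix(rnorm(300, 20, 1), 30, 10,
              dimnames = list(sprintf("P%02d", 1:30), meta$sample_id))
  peC <- ProteoExperiment(v, state = "normalized")
  peC <- attachSampleMeta(peC, meta)
  outC <- imputeMissing(peC, seed = 1)
  expect_identical(abundance(outC), v)
  expect_identical(procState(outC), "imputed")

  v2 <- v
  v2[sample(300, 25)] <- NA
  pe <- attachSampleMeta(ProteoExperiment(v2, state = "normalized"), meta)
  out1 <- imputeMissing(pe, seed = 42, numTrees = 30)
  expect_identical(abundance(out1)[!is.na(v2)], v2[!is.na(v2)])
  expect_false(anyNA(abundance(out1)))
  out2 <- imputeMissing(pe, seed = 42, numTrees = 30)
  expect_identical(abundance(out1), abundance(out2))
  out3 <- imputeMissing(pe, seed = 43, numTrees = 30)
  expect_false(identical(abundance(out1), abundance(out3)))
})

test_that("imputation recovers a hidden cell of a collinear protein pair", {
  set.seed(55)
  n <- 80
  meta <- data.frame(sample_id = sprintf("S%02d", 1:n),
                     donor_id = sprintf("S%02d", 1:n),
                     disease = "RA", region = "RA_SL")
  base <- seq(19, 21, length.out = n) + rnorm(n, 0, 0.02)
  v <- rbind(P1 = base, P2 = base,
             matrix(rnorm(6 * n, 20, 1), 6, n,
                    dimnames = list(sprintf("B%d", 1:6), NULL)))
  colnames(v) <- meta$sample_id
  truthVal <- v["P1", 40]
  v["P1", 40] <- NA
  pe <- attachSampleMeta(ProteoExperiment(v, state = "normalized"), meta)
  out <- imputeMissing(pe, seed = 7, numTrees = 300)
  expect_lt(abs(abundance(out)["P1", 40] - truthVal), 0.1)
})

test_that("imputation refuses all-missing proteins", {
  meta <- balancedMeta(2)
  v <- matrix(rnorm(100, 20), 10, 10,
              dimnames = list(sprintf("P%02d", 1:10), meta$sample_id))
  v[3, ] <- NA
  pe <- attachSampleMeta(ProteoExperiment(v, state = "normalized"), meta)
  expect_error(imputeMissing(pe, seed = 1), "all values missing.*P03")
})

test_that("PCA satisfies orthonormality, variance accounting and sign convention", {
  set.seed(19)
  v <- matrix(rnorm(30 * 12, 20, 1), 30, 12,
              dimnames = list(sprintf("P%02d", 1:30), sprintf("S%02d", 1:12)))
  meta <- data.frame(sample_id = colnames(v), donor_id = colnames(v),
                     disease = "RA", region = "RA_SL")
  pe <- attachSampleMeta(ProteoExperiment(v, state = "imputed"), meta)
  pca <- runPca(pe)
  L <- pca$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$explainedVariance) <= 1e-12))
  expect_lte(sum(pca$explainedVariance), 1 + 1e-12)
  # full rank: variance fractions account for everything
  expect_equal(sum(runPca(pe, nComponents = 11)$explainedVariance), 1,
               tolerance = 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(L))) {
    expect_gt(L[which.max(abs(L[, j])), j], 0)
  }
  # reconstruction with all components
  ctr <- rowMeans(v)
  recon <- t(pca$scores %*% t(pca$loadings)) + ctr
  expect_equal(recon, v, tolerance = 1e-8)
})

test_that("PC1 separates two planted groups and duplication leaves loadings fixed", {
  set.seed(23)
  v <- matrix(rnorm(40 * 10, 20, 0.5), 40, 10,
              dimnames = list(sprintf("P%02d", 1:40), sprintf("S%02d", 1:10)))
  v[1:15, 6:10] <- v[1:15, 6:10] + 4
  meta <- data.frame(sample_id = colnames(v), donor_id = colnames(v),
                     disease = rep(c("NH", "RA"), each = 5),
                     region = rep(c("NH_SL", "RA_SL"), each = 5))
  pe <- attachSampleMeta(ProteoExperiment(v, state = "imputed"), meta)
  pca <- runPca(pe, nComponents = 3)
  s1 <- pca$scores[1:5, 1]
  s2 <- pca$scores[6:10, 1]
  # groups fully separated along PC1
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # silhouette-style check: within-group spread below between-group gap
  expect_gt(abs(mean(s1) - mean(s2)), 2 * (sd(s1) + sd(s2)))

  vd <- cbind(v, v)
  colnames(vd) <- c(colnames(v), paste0(colnames(v), "b"))
  metad <- rbind(meta, transform(meta, sample_id = paste0(sample_id, "b"),
                                 donor_id = paste0(donor_id, "b")))
  ped <- attachSampleMeta(ProteoExperiment(vd, state = "imputed"), metad)
  pcad <- runPca(ped, nComponents = 3)
  for (j in 1:3) {
    expect_true(isTRUE(all.equal(pcad$loadings[, j], pca$loadings[, j],
                                 tolerance = 1e-6)) ||
                isTRUE(all.equal(pcad$loadings[, j], -pca$loadings[, j],
                                 tolerance = 1e-6)))
  }
  expect_error(runPca(attachSampleMeta(
    ProteoExperiment(matrix(5, 3, 4, dimnames = list(paste0("P", 1:3),
                                                     meta$sample_id[1:4])),
    state = "imputed"), meta[1:4, ])), "zero total variance")
})

test_that("PCA loadings correlate with log2 fold change for a shift design", {
  set.seed(29)
  delta <- rnorm(60, 0, 1.5)
  v <- matrix(rnorm(60 * 12, 20, 0.05), 60, 12,
              dimnames = list(sprintf("P%02d", 1:60), sprintf("S%02d", 1:12)))
  v[, 7:12] <- v[, 7:12] + delta
  meta <- data.frame(sample_id = colnames(v), donor_id = colnames(v),
                     disease = rep(c("NH", "RA"), each = 6),
                     region = rep(c("NH_SL", "RA_SL"), each = 6))
  pe <- attachSampleMeta(ProteoExperiment(v, state = "imputed"), meta)
  pca <- runPca(pe, nComponents = 2)
  de <- fitModeratedDE(pe, "RA_SL", "NH_SL")
  r <- loadingLogfcCorrelation(pca, de, component = 1)
  expect_gt(abs(r), 0.95)
  # sign flip of the component flips the sign of r only
  flipped <- pca
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  expect_equal(loadingLogfcCorrelation(flipped, de, 1), -r,
               tolerance = 1e-12)
  # degenerate: all-zero log2fc
  de0 <- de
  de0$log2fc <- 0
  expect_error(loadingLogfcCorrelation(pca, de0, 1), "undefined")
  # mismatched protein universe
  expect_error(loadingLogfcCorrelation(pca, de[-1, ], 1), "different protein")
})
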