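test_that("bhAdjust matches hand computation and validates input", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bhAdjust(1.0), 1.0)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, NA)), "\\[0, 1\\]")
  # rank order of input is preserved (monotone in p)
  set.seed(101)
  p <- runif(40)
  q <- bhAdjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p))
})

test_that("bhAdjust equals a quadratic-time brute-force step-up", {
  set.seed(202)
  for (i in 1:60) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), bruteForceBH(p), tolerance = 1e-12)
  }
})

test_that("moderated DE recovers a planted 4-fold change and is antisymmetric", {
  set.seed(303)
  meta <- balancedMeta(5)
  v <- matrix(rnorm(400 * 25, 20, 0.3), 400, 25,
              dimnames = list(sprintf("P%03d", 1:400), meta$sample_id))
  ra <- meta$region == "RA_SL"
  v[1:50, ra] <- v[1:50, ra] + 2  # log2fc truth = 2
  pe <- makeImputedPE(v, meta$region)
  de <- fitModeratedDE(pe, "RA_SL", "NH_SL")
  expect_true(all(de$fdr >= de$p_value - 1e-12))
  expect_true(all(de$fdr <= 1))
  expect_gt(mean(de$log2fc[1:50]), 1.8)
  expect_lt(mean(de$log2fc[1:50]), 2.2)
  expect_identical(de$significant,
                   de$fdr < 0.05 & abs(de$log2fc) > 1)

  rev <- fitModeratedDE(pe, "NH_SL", "RA_SL")
  expect_equal(rev$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(rev$t, -de$t, tolerance = 1e-12)
  expect_equal(rev$p_value, de$p_value, tolerance = 1e-12)
})

test_that("moderated DE matches limma's empirical-Bayes fit on a fixture", {
  skip_if_not_installed("limma")
  n <- 4
  # seed 42 yields a finite prior df, seed 404 an infinite one (no excess
  # dispersion of log s^2); both estimation branches must match limma
  for (fixtureSeed in c(42L, 404L)) {
    set.seed(fixtureSeed)
    v <- matrix(rnorm(300 * 2 * n, 10, 1), 300)
    v[1:30, seq_len(n)] <- v[1:30, seq_len(n)] + 2
    dimnames(v) <- list(sprintf("P%03d", 1:300), sprintf("S%02d", 1:(2 * n)))
    regions <- rep(c("RA_SL", "NH_SL"), each = n)
    pe <- makeImputedPE(v, regions)
    de <- fitModeratedDE(pe, "RA_SL", "NH_SL")
    design <- cbind(A = rep(c(1, 0), each = n), B = rep(c(0, 1), each = n))
    fit <- limma::lmFit(v, design)
    fit <- limma::eBayes(limma::contrasts.fit(
      fit, limma::makeContrasts(A - B, levels = design)))
    prior <- attr(de, "prior")
    expect_equal(unname(prior["d0"]), fit$df.prior, tolerance = 1e-6)
    expect_equal(unname(prior["s02"]), fit$s2.prior, tolerance = 1e-6)
    expect_equal(de$t, unname(fit$t[, 1]), tolerance = 1e-8)
    expect_equal(de$p_value, unname(fit$p.value[, 1]), tolerance = 1e-8)
  }
})

test_that("moderation interpolates between per-protein t and pooled z limits", {
  set.seed(505)
  meta <- balancedMeta(4)
  sub <- meta[meta$region %in% c("RA_SL", "NH_SL"), ]
  # heterogeneous residual variances spanning orders of magnitude -> d0 small,
  # moderated t tracks the classical per-protein Student t
  sds <- 10^runif(300, -3, 2)
  vHet <- matrix(rnorm(300 * 8, 0, 1), 300, 8) * sds + 20
  dimnames(vHet) <- list(sprintf("P%03d", 1:300), sub$sample_id)
  peHet <- makeImputedPE(vHet, sub$region)
  deHet <- fitModeratedDE(peHet, "RA_SL", "NH_SL")
  classicalT <- apply(vHet, 1, function(row) {
    t.test(row[sub$region == "RA_SL"], row[sub$region == "NH_SL"],
           var.equal = TRUE)$statistic
  })
  expect_lt(unname(attr(deHet, "prior")["d0"]), 1)
  # with a vanishing prior df the moderated t tracks the classical t
  expect_lt(median(abs(deHet$t / classicalT - 1)), 0.05)
  expect_gt(cor(deHet$t, classicalT, method = "spearman"), 0.97)

  # homogeneous variances -> d0 large, t ~ pooled-variance z statistic
  vHom <- matrix(rnorm(300 * 8, 20, 1), 300, 8,
                 dimnames = dimnames(vHet))
  peHom <- makeImputedPE(vHom, sub$region)
  deHom <- fitModeratedDE(peHom, "RA_SL", "NH_SL")
  prior <- attr(deHom, "prior")
  expect_gt(unname(prior["d0"]), 20)
  pooledZ <- (deHom$mean_a - deHom$mean_b) /
    sqrt(unname(prior["s02"]) * (1 / 4 + 1 / 4))
  expect_gt(cor(deHom$t, pooledZ), 0.999)
})

test_that("five groups produce exactly choose(5,2) = 10 pairwise tables", {
  set.seed(606)
  meta <- balancedMeta(3)
  v <- matrix(rnorm(60 * 15, 20, 1), 60, 15,
              dimnames = list(sprintf("P%02d", 1:60), meta$sample_id))
  pe <- makeImputedPE(v, meta$region)
  pairs <- combn(regionLevels(), 2)
  tables <- lapply(seq_len(ncol(pairs)), function(i) {
    fitModeratedDE(pe, pairs[1, i], pairs[2, i])
  })
  expect_length(tables, 10L)
})

test_that("significance classification equals a brute-force rule re-check", {
  set.seed(707)
  tab <- data.frame(log2fc = rnorm(500, 0, 1.5),
                    fdr = runif(500)^2)
  tab$log2fc[1:3] <- c(1.5, 0.9, -1.2)
  tab$fdr[1:3] <- c(0.01, 0.001, 0.01)
  out <- classifySignificant(tab)
  expect_true(out$significant[1]); expect_identical(out$direction[1], "up")
  expect_false(out$significant[2])
  expect_true(out$significant[3]); expect_identical(out$direction[3], "down")
  for (i in seq_len(nrow(out))) {
    expect_identical(out$significant[i],
                     out$fdr[i] < 0.05 && abs(out$log2fc[i]) > 1)
  }
  cnt <- attr(out, "counts")
  expect_identical(unname(cnt["up"] + cnt["down"]),
                   sum(out$significant))
})

test_that("anovaTukey matches a from-scratch SSB/SSW + studentized-range oracle", {
  groups <- list(A = c(1, 2, 3), B = c(2, 3, 4), C = c(6, 7, 8))
  res <- anovaTukey(groups)
  # from-scratch one-way ANOVA
  allv <- unlist(groups)
  gm <- mean(allv)
  ni <- lengths(groups)
  mi <- vapply(groups, mean, numeric(1))
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(allv) - length(groups)
  Fstat <- (ssb / dfb) / (ssw / dfw)
  expect_equal(res$F, Fstat, tolerance = 1e-10)
  expect_equal(res$p, pf(Fstat, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-10)
  # Tukey HSD via the studentized range distribution (equal group sizes)
  msw <- ssw / dfw
  for (i in seq_len(nrow(res$pairs))) {
    g1 <- res$pairs$group1[i]; g2 <- res$pairs$group2[i]
    q <- abs(mi[[g1]] - mi[[g2]]) / sqrt(msw / ni[[1]])
    expect_equal(res$pairs$p_adj[i],
                 ptukey(q, nmeans = 3, df = dfw, lower.tail = FALSE),
                 tolerance = 1e-8)
  }
})

test_that("anovaTukey handles identical groups and permutation symmetry", {
  groups <- list(X = c(1, 2, 3, 4), Y = c(1, 2, 3, 4), Z = c(9, 10, 11, 12))
  res <- anovaTukey(groups)
  pXY <- res$pairs$p_adj[res$pairs$group1 %in% c("X", "Y") &
                           res$pairs$group2 %in% c("X", "Y")]
  expect_equal(pXY, 1, tolerance = 1e-9)

  perm <- anovaTukey(groups[c("Z", "X", "Y")])
  key <- function(df) {
    o <- apply(df[, c("group1", "group2")], 1, function(r) {
      paste(sort(r), collapse = "|")
    })
    setNames(df$p_adj, o)
  }
  k1 <- key(res$pairs); k2 <- key(perm$pairs)
  expect_equal(k1[sort(names(k1))], k2[sort(names(k2))], tolerance = 1e-10)

  expect_error(anovaTukey(list(A = 1, B = c(1, 2))), "< 2 values")
  expect_error(anovaTukey(list(A = c(1, 1), B = c(2, 2))),
               "zero within-group variance")
})
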