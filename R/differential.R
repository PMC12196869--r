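#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up false-discovery-rate adjustment, in input order.
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Vector of adjusted p values (same order as input).
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

# Newton inversion of the trigamma function (for the empirical-Bayes
# prior degrees of freedom).
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Per protein, a group-means ordinary-least-squares fit; residual
#' variances are shrunk toward a common prior by empirical Bayes. With
#' per-protein residual variance \eqn{s^2} on \eqn{d} degrees of
#' freedom, the prior \eqn{(d_0, s_0^2)} is estimated by method of
#' moments on the log residual variances and the posterior variance is
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}. The moderated t
#' statistic \eqn{\Delta\bar{x} / (\tilde{s}\sqrt{1/n_a + 1/n_b})} is
#' referred to a t distribution on \eqn{d_0 + d} degrees of freedom
#' (two-sided); FDR control is Benjamini-Hochberg.
#'
#' @param x \linkS4class{ProteoExperiment} with state \code{"imputed"}
#'   and sample metadata attached.
#' @param groupA,groupB Region labels to contrast (log2fc = A - B);
#'   each must have >= 2 samples.
#' @param fdrThreshold,fcThreshold Significance calls: FDR below
#'   \code{fdrThreshold} and fold change above \code{fcThreshold}.
#' @return data.frame with one row per protein: \code{protein},
#'   \code{gene}, \code{log2fc}, \code{mean_a}, \code{mean_b}, \code{t},
#'   \code{p_value}, \code{fdr}, \code{significant}, \code{direction};
#'   prior estimates in \code{attr(, "prior")}.
#' @export
fitModeratedDE <- function(x, groupA, groupB, fdrThreshold = 0.05,
                           fcThreshold = 2) {
  stopifnot(is(x, "ProteoExperiment"))
  if (procState(x) != "imputed") {
    stop("fitModeratedDE expects state 'imputed', got '", procState(x), "'")
  }
  region <- regionLabels(x)
  ia <- which(region == groupA)
  ib <- which(region == groupB)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need >= 2 samples (", groupA, ": ", length(ia),
         ", ", groupB, ": ", length(ib), ")")
  }
  v <- abundance(x)
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(v[, ia, drop = FALSE])
  mb <- rowMeans(v[, ib, drop = FALSE])
  ssa <- rowSums((v[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((v[, ib, drop = FALSE] - mb)^2)
  d <- na + nb - 2
  s2 <- (ssa + ssb) / d
  if (all(s2 <= .Machine$double.eps)) {
    stop("zero residual variance for all proteins")
  }

  pos <- s2 > .Machine$double.eps
  z <- log(s2[pos])
  evar <- stats::var(z) - trigamma(d / 2)
  if (is.finite(evar) && evar > 1e-10) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion in log s^2: infinite prior df, pooled scale
    d0 <- Inf
    s02 <- mean(s2)
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)

  se <- sqrt(s2post * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  # cap the total df at the pooled residual df across proteins
  dfTotal <- min(d0 + d, d * nrow(v))
  pval <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  res <- data.frame(
    protein = rownames(x), gene = unname(geneMap(x)),
    log2fc = ma - mb, mean_a = ma, mean_b = mb,
    t = tstat, p_value = pval, fdr = bhAdjust(pval),
    stringsAsFactors = FALSE, row.names = NULL
  )
  res <- classifySignificant(res, fcThreshold = fcThreshold,
                             fdrThreshold = fdrThreshold)
  attr(res, "prior") <- c(d0 = d0, s02 = s02, df_residual = d)
  attr(res, "contrast") <- c(groupA = groupA, groupB = groupB)
  res
}

#' Classify significance of a differential-expression table
#'
#' A protein is significant when its FDR is below \code{fdrThreshold}
#' and its absolute fold change exceeds \code{fcThreshold}.
#'
#' @param table data.frame with columns \code{log2fc} and \code{fdr}.
#' @param fcThreshold Fold-change threshold (linear scale, > 1).
#' @param fdrThreshold FDR threshold.
#' @return The table with \code{significant} and \code{direction}
#'   columns set; up/down counts in \code{attr(, "counts")}.
#' @export
classifySignificant <- function(table, fcThreshold = 2,
                                fdrThreshold = 0.05) {
  stopifnot(all(c("log2fc", "fdr") %in% names(table)))
  lfcCut <- log2(fcThreshold)
  table$significant <- table$fdr < fdrThreshold & abs(table$log2fc) > lfcCut
  table$direction <- ifelse(!table$significant, "ns",
                            ifelse(table$log2fc > 0, "up", "down"))
  attr(table, "counts") <- c(up = sum(table$direction == "up"),
                             down = sum(table$direction == "down"))
  table
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fixed-effects one-way analysis of variance followed by Tukey's
#' honestly-significant-difference test (studentized-range adjusted p
#' values) for all group pairs.
#'
#' @param valuesByGroup Named list of numeric vectors, one per group;
#'   every group needs >= 2 values and at least one group must have
#'   positive within-group variance.
#' @param alpha Family-wise level used for the Tukey confidence bounds.
#' @return List: \code{F}, \code{p} (overall ANOVA), and \code{pairs}, a
#'   data.frame with \code{group1}, \code{group2}, \code{diff},
#'   \code{p_adj}.
#' @export
anovaTukey <- function(valuesByGroup, alpha = 0.05) {
  if (length(valuesByGroup) < 2L) stop("need >= 2 groups")
  if (is.null(names(valuesByGroup))) {
    names(valuesByGroup) <- paste0("G", seq_along(valuesByGroup))
  }
  if (any(grepl("-", names(valuesByGroup), fixed = TRUE))) {
    stop("group names must not contain '-'")
  }
  sizes <- lengths(valuesByGroup)
  if (any(sizes < 2L)) {
    stop("group(s) with < 2 values: ",
         paste(names(valuesByGroup)[sizes < 2L], collapse = ", "))
  }
  if (all(vapply(valuesByGroup, stats::var, numeric(1)) == 0)) {
    stop("zero within-group variance in every group")
  }
  df <- data.frame(
    value = unlist(valuesByGroup, use.names = FALSE),
    group = factor(rep(names(valuesByGroup), sizes),
                   levels = names(valuesByGroup))
  )
  fit <- stats::aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(
    group1 = vapply(pairNames, `[[`, character(1), 1L),
    group2 = vapply(pairNames, `[[`, character(1), 2L),
    diff = unname(tk[, "diff"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  list(F = sm[["F value"]][1L], p = sm[["Pr(>F)"]][1L], pairs = pairs)
}
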