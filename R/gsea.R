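# Weighted-KS enrichment score from sorted hit positions.
# pos: sorted positions of the set's genes in the ranked list;
# w: |ranking metric| at those positions; N: total genes.
# Returns es and the index (into pos) of the extremum, for the leading
# edge. Hit increments are w/sum(w) (weight exponent 1); if all weights
# are zero the hits fall back to equal increments. Miss decrements are
# 1/(N - k), so the running sum starts and ends at 0.
.esFromPositions <- function(pos, w, N) {
  k <- length(pos)
  nr <- sum(w)
  inc <- if (nr > 0) w / nr else rep(1 / k, k)
  cumhit <- cumsum(inc)
  missPen <- 1 / (N - k)
  j <- seq_len(k)
  top <- cumhit - (pos - j) * missPen        # running sum just after hit
  bot <- c(0, cumhit[-k]) - (pos - j) * missPen  # just before hit
  iTop <- which.max(top)
  iBot <- which.min(bot)
  if (top[iTop] >= -bot[iBot]) {
    list(es = top[iTop], extremum = iTop, positive = TRUE)
  } else {
    list(es = bot[iBot], extremum = iBot, positive = FALSE)
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum GSEA on a gene-level ranking
#' (typically log2 fold changes). Genes are sorted by decreasing metric;
#' the running sum increments at set members proportionally to the
#' absolute metric (weight exponent 1, normalized to sum 1) and
#' decrements by 1/(N - set size) elsewhere; the enrichment score (ES)
#' is the extremum. The null is by gene-label permutation: set-size
#' random draws from the ranking. NES is the ES divided by the mean
#' absolute null ES of matching sign; the permutation p value is the
#' fraction of same-sign null ES at least as extreme; FDR uses the
#' standard sign-pooled NES null.
#'
#' @param ranking Named numeric vector, gene -> metric; names unique.
#' @param sets Named list of gene sets (see \code{\link{readGmt}}).
#' @param nPerm Number of permutations (a value below 100 is recorded as
#'   a warning in \code{attr(, "warnings")}).
#' @param minSize,maxSize Set-size bounds after intersection with the
#'   ranking.
#' @param seed Integer seed; results are deterministic under it.
#' @return data.frame, one row per retained set, sorted by decreasing
#'   NES: \code{set}, \code{size}, \code{es}, \code{nes}, \code{p_perm},
#'   \code{fdr}, \code{direction} (\code{activated} iff es > 0),
#'   \code{leading_edge} (semicolon-joined genes).
#' @export
gseaPreranked <- function(ranking, sets, nPerm = 1000, minSize = 10,
                          maxSize = 500, seed = 1) {
  if (is.null(names(ranking)) || anyDuplicated(names(ranking))) {
    stop("ranking must be a named vector with unique gene names")
  }
  warnings <- character()
  if (nPerm < 100) {
    warnings <- c(warnings, sprintf(
      "nPerm = %d is low; permutation p values will be coarse", nPerm))
  }
  ord <- order(-ranking, names(ranking))  # deterministic tie-break
  ranked <- ranking[ord]
  geneIndex <- stats::setNames(seq_along(ranked), names(ranked))
  absfc <- abs(unname(ranked))
  N <- length(ranked)

  idxSets <- lapply(sets, function(s) {
    sort(unname(geneIndex[stats::na.omit(match(unique(s), names(geneIndex)))]))
  })
  sizes <- lengths(idxSets)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < N
  if (!any(keep)) {
    stop("no gene set within [minSize, maxSize] after intersection ",
         "with the ranking")
  }
  idxSets <- idxSets[keep]
  sizes <- sizes[keep]

  set.seed(seed)
  res <- vector("list", length(idxSets))
  nullNesPos <- list()
  nullNesNeg <- list()
  for (s in seq_along(idxSets)) {
    pos <- idxSets[[s]]
    k <- sizes[[s]]
    obs <- .esFromPositions(pos, absfc[pos], N)
    nullEs <- vapply(seq_len(nPerm), function(b) {
      rp <- sort(sample.int(N, k))
      .esFromPositions(rp, absfc[rp], N)$es
    }, numeric(1))
    same <- if (obs$es >= 0) nullEs >= 0 else nullEs < 0
    nSame <- sum(same)
    pPerm <- (1 + sum(same & abs(nullEs) >= abs(obs$es))) / (1 + nSame)
    meanSame <- if (nSame > 0) mean(abs(nullEs[same])) else NA_real_
    nes <- if (is.na(meanSame) || meanSame == 0) NA_real_ else
      obs$es / meanSame
    mPos <- mean(abs(nullEs[nullEs >= 0]))
    mNeg <- mean(abs(nullEs[nullEs < 0]))
    nullNesPos[[s]] <- if (is.finite(mPos) && mPos > 0)
      nullEs[nullEs >= 0] / mPos else numeric()
    nullNesNeg[[s]] <- if (is.finite(mNeg) && mNeg > 0)
      nullEs[nullEs < 0] / mNeg else numeric()

    le <- if (obs$positive) pos[seq_len(obs$extremum)] else
      pos[seq(obs$extremum, k)]
    res[[s]] <- data.frame(
      set = names(idxSets)[s], size = k, es = obs$es, nes = nes,
      p_perm = pPerm,
      direction = if (obs$es > 0) "activated" else "suppressed",
      leading_edge = paste(names(ranked)[le], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)

  poolPos <- unlist(nullNesPos)
  poolNeg <- unlist(nullNesNeg)
  obsNes <- out$nes
  fdr <- rep(NA_real_, nrow(out))
  for (i in seq_len(nrow(out))) {
    v <- obsNes[i]
    if (is.na(v)) next
    if (v >= 0) {
      piNull <- if (length(poolPos)) mean(poolPos >= v) else 0
      piObs <- mean(obsNes[!is.na(obsNes) & obsNes >= 0] >= v)
    } else {
      piNull <- if (length(poolNeg)) mean(poolNeg <= v) else 0
      piObs <- mean(obsNes[!is.na(obsNes) & obsNes < 0] <= v)
    }
    fdr[i] <- if (piObs > 0) min(1, piNull / piObs) else NA_real_
  }
  out$fdr <- fdr
  out <- out[, c("set", "size", "es", "nes", "p_perm", "fdr",
                 "direction", "leading_edge")]
  out <- out[order(-out$nes, out$set, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  if (length(warnings)) attr(out, "warnings") <- warnings
  out
}
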