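# Cross-platform agreement: per-sample Pearson correlation with a linear
# model and residual ranking, per-gene detection cross-tabulation,
# expression binning from per-gene medians, per-gene inter-platform
# Spearman correlation, and bin-wise comparison of the gene correlations.

# align a probe- or gene-indexed detection mask to the matched gene set
.maskOverGenes <- function(mask, paired, side = c("A", "B")) {
  side <- match.arg(side)
  m <- detectionMask(mask)
  genes <- rownames(paired@valuesA)
  rows <- if (side == "A" && length(paired@probeMap)) {
    paired@probeMap[genes]
  } else genes
  found <- rows %in% rownames(m)
  out <- matrix(FALSE, length(genes), ncol(paired@valuesA),
                dimnames = list(genes, colnames(paired@valuesA)))
  # platform-B columns may carry their own identifiers; use the pairing
  cols <- colnames(out)
  if (side == "B" && length(paired@samplePairing)) {
    cols <- unname(paired@samplePairing[cols])
  }
  if (!all(cols %in% colnames(m))) cols <- seq_len(ncol(out))
  out[found, ] <- m[rows[found], cols, drop = FALSE]
  out
}

#' Per-sample cross-platform concordance
#'
#' For each paired sample, genes detected by both platforms in that sample
#' are kept, both sides are transformed with `log2(x + offset)`, and the
#' Pearson correlation plus an ordinary least-squares fit (platform B on
#' platform A by default) are computed. Per-gene residuals are ranked and
#' the three most negative and three most positive are reported as the most
#' divergent genes.
#'
#' @param paired a \linkS4class{PairedMatrix}.
#' @param maskA,maskB detection masks for the two platforms (probe-indexed
#'   masks are aligned through the paired probe map). `NULL` keeps all
#'   genes.
#' @param offset shift used in the log transform (default 1).
#' @param response which platform's log expression is the regression
#'   response; r and R^2 do not depend on it, residual signs do.
#' @return A \linkS4class{SampleConcordance}. Samples with fewer than 3
#'   shared detected genes are skipped with a warning.
#' @export
sampleConcordance <- function(paired, maskA = NULL, maskB = NULL,
                              offset = 1, response = c("B", "A")) {
  response <- match.arg(response)
  a <- paired@valuesA; b <- paired@valuesB
  keep <- if (is.null(maskA) && is.null(maskB)) {
    matrix(TRUE, nrow(a), ncol(a), dimnames = dimnames(a))
  } else {
    ma <- if (is.null(maskA)) TRUE else .maskOverGenes(maskA, paired, "A")
    mb <- if (is.null(maskB)) TRUE else .maskOverGenes(maskB, paired, "B")
    ma & mb
  }
  stats <- list(); resid <- list(); extremes <- list()
  for (s in colnames(a)) {
    g <- rownames(a)[keep[, s]]
    if (length(g) < 3) {
      warning("sample ", s, " skipped: fewer than 3 genes detected on ",
              "both platforms")
      next
    }
    x <- log2p(a[g, s], offset); y <- log2p(b[g, s], offset)
    if (response == "A") { tmp <- x; x <- y; y <- tmp }
    fit <- lm(y ~ x)
    r <- cor(x, y)
    stats[[s]] <- data.frame(sample = s, nGenes = length(g), pearson = r,
                             r2 = r^2, slope = unname(coef(fit)[2]),
                             intercept = unname(coef(fit)[1]))
    rs <- setNames(residuals(fit), g)
    resid[[s]] <- rs
    ord <- order(rs)
    extremes[[s]] <- data.frame(
      sample = s,
      gene = c(names(rs)[head(ord, 3)], names(rs)[tail(ord, 3)]),
      residual = c(rs[head(ord, 3)], rs[tail(ord, 3)]),
      direction = rep(c("negative", "positive"), each = 3),
      row.names = NULL)
  }
  if (!length(stats)) stop("no sample had 3 or more shared detected genes")
  new("SampleConcordance", stats = do.call(rbind, c(stats, make.row.names = FALSE)),
      residuals = resid,
      extremes = do.call(rbind, c(extremes, make.row.names = FALSE)),
      response = response, offset = offset)
}

CROSSTAB_CATEGORIES <- c("both_all", "discordant", "only_a_all",
                         "only_b_all", "neither", "concordant_partial")

#' Cross-platform detection cross-tabulation
#'
#' Classifies every matched gene by its detection pattern across samples:
#' detected by both platforms in every sample (`both_all`); detected by one
#' platform but below the limit on the other in at least one sample
#' (`discordant`); detected in every sample on one platform and in none on
#' the other (`only_a_all`, `only_b_all` — these take precedence over
#' `discordant`); never detected anywhere (`neither`); and
#' `concordant_partial` for genes detected by both platforms wherever
#' detected but not in all samples (the two platforms agree sample by
#' sample, including the samples where both are below the limit).
#'
#' @param maskA,maskB logical gene x sample matrices (or
#'   \linkS4class{DetectionMask}s) over the same matched genes and paired
#'   samples.
#' @return A \linkS4class{DetectionCrosstab}; counts sum to the number of
#'   matched genes.
#' @export
detectionCrosstab <- function(maskA, maskB) {
  if (is(maskA, "DetectionMask")) maskA <- detectionMask(maskA)
  if (is(maskB, "DetectionMask")) maskB <- detectionMask(maskB)
  if (!identical(dim(maskA), dim(maskB))) {
    stop("masks must share gene and sample indexing")
  }
  nS <- ncol(maskA)
  aAll <- rowSums(maskA) == nS; bAll <- rowSums(maskB) == nS
  aNone <- rowSums(maskA) == 0; bNone <- rowSums(maskB) == 0
  disc <- rowSums(maskA != maskB) > 0
  cat <- ifelse(aAll & bAll, "both_all",
         ifelse(aAll & bNone, "only_a_all",
         ifelse(bAll & aNone, "only_b_all",
         ifelse(aNone & bNone, "neither",
         ifelse(disc, "discordant", "concordant_partial")))))
  names(cat) <- rownames(maskA)
  counts <- table(factor(cat, CROSSTAB_CATEGORIES))
  new("DetectionCrosstab",
      categories = setNames(as.integer(counts), names(counts)),
      assignment = cat)
}

#' Assign expression bins from per-gene medians
#'
#' The per-gene median across samples of the normalized values is compared
#' to two strictly increasing boundaries: `median <= b1` is low,
#' `b1 < median <= b2` intermediate, `median > b2` high (ties at a boundary
#' go downward).
#'
#' @param values normalized gene x sample matrix.
#' @param boundaries numeric length 2, strictly increasing. Conventional
#'   defaults are `c(50, 200)` on normalized panel counts and `c(1, 3)` on
#'   geTMM values.
#' @return A \linkS4class{BinAssignment}.
#' @export
binGenes <- function(values, boundaries = c(50, 200)) {
  if (length(boundaries) != 2 || diff(boundaries) <= 0) {
    stop("boundaries must be two strictly increasing values")
  }
  med <- apply(values, 1, median)
  lab <- factor(ifelse(med <= boundaries[1], "low",
               ifelse(med <= boundaries[2], "intermediate", "high")),
               levels = c("low", "intermediate", "high"))
  new("BinAssignment", bins = setNames(lab, rownames(values)),
      boundaries = boundaries, medians = med)
}

#' Per-gene inter-platform Spearman correlation
#'
#' For each matched gene, the Spearman rank correlation (midranks, hence
#' tie-corrected) of the two platforms' values across the paired samples.
#' A gene constant on either side has an undefined correlation and is
#' flagged missing.
#'
#' @param paired a \linkS4class{PairedMatrix} with >= 3 paired samples.
#' @return data.frame with columns `gene`, `rho`, `missing`.
#' @export
geneSpearman <- function(paired) {
  a <- paired@valuesA; b <- paired@valuesB
  if (ncol(a) < 3) stop("need at least 3 paired samples")
  ra <- t(apply(a, 1, rank)); rb <- t(apply(b, 1, rank))
  ca <- ra - rowMeans(ra); cb <- rb - rowMeans(rb)
  den <- sqrt(rowSums(ca^2) * rowSums(cb^2))
  rho <- ifelse(den > 0, rowSums(ca * cb) / den, NA_real_)
  data.frame(gene = rownames(a), rho = unname(rho),
             missing = !is.finite(rho) | den == 0,
             stringsAsFactors = FALSE)
}

#' Two-sided Mann-Whitney test with an exact tied-data small-sample path
#'
#' For small samples the p-value is computed by exhaustive enumeration of
#' all group assignments of the pooled midranks (valid under ties, where
#' the classical exact distribution is not); otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exactMax largest number of enumerable splits for the exact path.
#' @return two-sided p-value.
#' @export
mannWhitney <- function(x, y, exactMax = 20000) {
  m <- length(x); k <- length(y); n <- m + k
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(m)])
  mu <- m * (n + 1) / 2
  if (choose(n, m) <= exactMax) {
    splits <- utils::combn(n, m)
    ws <- colSums(matrix(r[splits], nrow = m))
    return(mean(abs(ws - mu) >= abs(w - mu) - 1e-12))
  }
  ties <- table(r)
  sigma2 <- m * k / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  2 * stats::pnorm(-abs(w - mu) / sqrt(sigma2))
}

#' Compare per-gene correlations between expression bins
#'
#' Mean rho and gene count per bin, plus pairwise two-sided Mann-Whitney U
#' tests between the bins (exact for small samples without ties, normal
#' approximation with tie correction otherwise). Genes with missing rho are
#' excluded; their count is reported.
#'
#' @param gc data.frame from [geneSpearman()].
#' @param bins a \linkS4class{BinAssignment} over the same genes.
#' @return list with `binStats` (bin, n, meanRho), `tests` (binA, binB, p),
#'   and `nMissing`.
#' @export
compareBins <- function(gc, bins) {
  lab <- binLabels(bins)[gc$gene]
  ok <- !gc$missing & !is.na(lab)
  rho <- gc$rho[ok]; lab <- factor(lab[ok], levels(binLabels(bins)))
  binStats <- data.frame(
    bin = levels(lab),
    n = as.integer(table(lab)),
    meanRho = as.numeric(tapply(rho, lab, mean)))
  pairs <- utils::combn(levels(lab), 2)
  tests <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- rho[lab == pairs[1, i]]; y <- rho[lab == pairs[2, i]]
    if (length(x) < 2 || length(y) < 2) {
      warning("bin comparison ", pairs[1, i], " vs ", pairs[2, i],
              " skipped: fewer than 2 values in a bin")
      return(NULL)
    }
    data.frame(binA = pairs[1, i], binB = pairs[2, i],
               p = mannWhitney(x, y))
  })
  list(binStats = binStats,
       tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       nMissing = sum(!ok))
}
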