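# Independent brute-force oracles. Deliberately written as plain loops and
# textbook formulas, sharing no code path with the package implementation.

# detection: per-cell recomputation with explicit mean / sd loops
bfDetect <- function(geneCounts, negCounts) {
  mask <- matrix(NA, nrow(geneCounts), ncol(geneCounts),
                 dimnames = dimnames(geneCounts))
  for (s in seq_len(ncol(geneCounts))) {
    x <- negCounts[, s]
    thr <- mean(x) + 2 * sqrt(sum((x - mean(x))^2) / (length(x) - 1))
    for (g in seq_len(nrow(geneCounts))) {
      mask[g, s] <- geneCounts[g, s] > thr
    }
  }
  mask
}

# exhaustive per-gene crosstab classification
bfCrosstab <- function(maskA, maskB) {
  out <- character(nrow(maskA))
  for (g in seq_len(nrow(maskA))) {
    a <- maskA[g, ]; b <- maskB[g, ]
    out[g] <-
      if (all(a) && all(b)) "both_all"
      else if (all(a) && !any(b)) "only_a_all"
      else if (all(b) && !any(a)) "only_b_all"
      else if (!any(a) && !any(b)) "neither"
      else if (any(a != b)) "discordant"
      else "concordant_partial"
  }
  setNames(out, rownames(maskA))
}

# geNorm M on the full candidate set: pairwise log-ratio SDs by loops
bfGenormM <- function(mat) {
  k <- nrow(mat)
  m <- numeric(k)
  for (j in seq_len(k)) {
    acc <- 0
    for (h in seq_len(k)) {
      if (h == j) next
      acc <- acc + sd(log2(mat[j, ] / mat[h, ]))
    }
    m[j] <- acc / (k - 1)
  }
  setNames(m, rownames(mat))
}

# trimmed mean of M-values, written from the published formula: double
# rank trim on M and A, inverse asymptotic-variance weights
bfTmmPair <- function(obs, ref, trimM = 0.3, trimA = 0.05) {
  libO <- sum(obs); libR <- sum(ref)
  pos <- obs > 0 & ref > 0
  o <- obs[pos] / libO; r <- ref[pos] / libR
  M <- log2(o / r); A <- (log2(o) + log2(r)) / 2
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]
  if (!length(M) || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  w <- (libO - obs[pos][fin]) / (libO * obs[pos][fin]) +
       (libR - ref[pos][fin]) / (libR * ref[pos][fin])
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

bfTmm <- function(rpk, trimM = 0.3, trimA = 0.05) {
  lib <- colSums(rpk)
  uq <- numeric(ncol(rpk))
  for (s in seq_len(ncol(rpk))) uq[s] <- quantile(rpk[, s], 0.75) / lib[s]
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(rpk))
  for (s in seq_len(ncol(rpk))) {
    f[s] <- bfTmmPair(rpk[, s], rpk[, ref], trimM, trimA)
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(rpk))
}

# ordinary least squares through the normal equations
bfOls <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (intercept + slope * x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  list(slope = slope, intercept = intercept, resid = resid, r = r)
}

# midranks by hand, then the covariance formula (tie-corrected Spearman)
bfMidrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

bfSpearman <- function(a, b) {
  ra <- bfMidrank(a); rb <- bfMidrank(b)
  ca <- ra - mean(ra); cb <- rb - mean(rb)
  den <- sqrt(sum(ca^2) * sum(cb^2))
  if (den == 0) return(NA_real_)
  sum(ca * cb) / den
}
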