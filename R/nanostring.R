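# Panel-side processing: negative-control detection thresholds, detection
# calls, geNorm housekeeping stability ranking / selection, and
# housekeeping geometric-mean normalization.
#
# The detection rule: a count is called detected in a sample only if it is
# strictly greater than mean(negative controls) + 2 * SD(negative
# controls), computed per sample on raw counts with the sample (n - 1) SD.
# Equality is treated as undetected (the conservative reading of "below the
# limit is undetected").

#' Per-sample detection thresholds from negative-control probes
#'
#' @param panel a \linkS4class{PanelCounts} with at least two Negative
#'   probes (the SD needs n >= 2).
#' @return A \linkS4class{DetectionThresholds}.
#' @export
detectionThresholds <- function(panel) {
  neg <- probeCounts(panel, "Negative")
  if (nrow(neg) < 2) {
    stop("at least 2 negative-control probes are required for the ",
         "threshold SD")
  }
  thr <- colMeans(neg) + 2 * colSds(neg)
  new("DetectionThresholds", thresholds = thr)
}

#' Detection calls for panel genes
#'
#' Applies the per-sample thresholds to the raw counts of the endogenous
#' and housekeeping probes; detection is computed on raw counts, before any
#' normalization, with a strictly-greater comparison.
#'
#' @param panel a \linkS4class{PanelCounts}.
#' @param thr a \linkS4class{DetectionThresholds} covering all samples.
#' @return A \linkS4class{DetectionMask} tagged `"panel"`.
#' @export
detectPanel <- function(panel, thr) {
  stopifnot(is(thr, "DetectionThresholds"))
  t <- thresholds(thr)
  if (!all(colnames(panel) %in% names(t))) {
    stop("thresholds do not cover all samples")
  }
  m <- probeCounts(panel, c("Endogenous", "Housekeeping"))
  mask <- sweep(m, 2, t[colnames(m)], ">")
  new("DetectionMask", mask = mask, platform = "panel")
}

# sample SD of log2(x_j / x_k) across samples, the geNorm pairwise variation
.pairSd <- function(lx) {
  k <- nrow(lx)
  v <- matrix(0, k, k, dimnames = list(rownames(lx), rownames(lx)))
  for (j in seq_len(k - 1)) {
    d <- lx[rep(j, k - j), , drop = FALSE] -
      lx[(j + 1):k, , drop = FALSE]
    s <- apply(d, 1, sd)
    v[j, (j + 1):k] <- s
    v[(j + 1):k, j] <- s
  }
  v
}

#' geNorm stability ranking of housekeeping candidates
#'
#' For each candidate gene j, stability M_j is the mean over the other
#' candidates k of the sample SD of `log2(x_j / x_k)` across samples. The
#' least stable gene (largest M, ties broken alphabetically) is removed and
#' M recomputed until two genes remain; those two share the last rank. The
#' pairwise variation series V(n/n+1) — the SD across samples of the log2
#' ratio of geometric-mean normalization factors built from the top-n
#' versus top-(n+1) stable genes — is computed alongside for
#' [genormSelect()].
#'
#' @param hkMatrix strictly positive gene x sample matrix of housekeeping
#'   expression (pre-filter genes with zeros before calling).
#' @return A \linkS4class{GeNormResult}. `mValues` holds the full-set M of
#'   every candidate (the values quoted for the complete panel);
#'   `exclusionOrder` runs least to most stable.
#' @export
genormRank <- function(hkMatrix) {
  hkMatrix <- as.matrix(hkMatrix)
  if (nrow(hkMatrix) < 3 || ncol(hkMatrix) < 2) {
    stop("geNorm needs >= 3 candidate genes and >= 2 samples")
  }
  if (any(hkMatrix <= 0) || anyNA(hkMatrix)) {
    stop("geNorm requires strictly positive values; pre-filter genes with ",
         "zeros before ranking")
  }
  if (is.null(rownames(hkMatrix))) {
    rownames(hkMatrix) <- sprintf("gene%03d", seq_len(nrow(hkMatrix)))
  }
  lx <- log2(hkMatrix)
  v <- .pairSd(lx)
  mFull <- rowSums(v) / (nrow(v) - 1)

  remaining <- rownames(hkMatrix)
  excl <- character()
  vCur <- v
  while (length(remaining) > 2) {
    m <- rowSums(vCur[remaining, remaining]) / (length(remaining) - 1)
    worst <- names(m)[order(-m, names(m))][1]  # largest M, alphabetical tie
    excl <- c(excl, worst)
    remaining <- setdiff(remaining, worst)
  }
  lastTwo <- sort(remaining)  # the final pair shares the last rank
  stability <- c(lastTwo, rev(excl))

  # V(n/n+1): NF_n,s = geometric mean of the top-n stable genes in sample s
  K <- nrow(hkMatrix)
  nfLog <- vapply(seq_len(K), function(n) {
    colMeans(lx[stability[seq_len(n)], , drop = FALSE])
  }, numeric(ncol(hkMatrix)))
  pv <- if (K >= 3) {
    vapply(2:(K - 1), function(n) sd(nfLog[, n] - nfLog[, n + 1]),
           numeric(1))
  } else numeric()
  names(pv) <- if (length(pv)) sprintf("V%d/%d", 2:(K - 1), 3:K)
  new("GeNormResult", mValues = mFull,
      exclusionOrder = c(excl, lastTwo),
      stabilityOrder = stability, pairwiseVariation = pv)
}

#' Select the minimal stable housekeeping set
#'
#' Takes the smallest n (starting at 2) whose pairwise variation V(n/n+1)
#' falls below the cutoff; if no n qualifies, all candidates are selected
#' and the fallback is flagged.
#'
#' @param ranked a \linkS4class{GeNormResult} from [genormRank()].
#' @param vCutoff pairwise-variation cutoff; 0.15 is the value published
#'   with the geNorm method.
#' @return The input with `selected` (and `fallback`) filled in.
#' @export
genormSelect <- function(ranked, vCutoff = 0.15) {
  stopifnot(is(ranked, "GeNormResult"))
  pv <- ranked@pairwiseVariation
  hit <- which(pv < vCutoff)
  if (length(hit)) {
    n <- hit[1] + 1  # pv[1] is V(2/3)
    ranked@selected <- ranked@stabilityOrder[seq_len(n)]
    ranked@fallback <- FALSE
  } else {
    message("no V(n/n+1) below ", vCutoff,
            "; falling back to all ", length(ranked@stabilityOrder),
            " candidates")
    ranked@selected <- ranked@stabilityOrder
    ranked@fallback <- TRUE
  }
  ranked
}

# geometric-mean scale factors: factor_s = mean_s(g) / g_s
.gmScale <- function(m) {
  if (any(m <= 0)) stop("scale genes must be positive in every sample")
  g <- apply(m, 2, geomMean)
  mean(g) / g
}

#' Housekeeping geometric-mean normalization of panel counts
#'
#' Per sample, the geometric mean of the selected housekeeping raw counts
#' is computed; each sample is scaled by the across-sample arithmetic mean
#' of those geometric means divided by its own. Optionally the same scheme
#' is applied first using the positive-control probes.
#'
#' @param panel a \linkS4class{PanelCounts}.
#' @param selectedHk non-empty housekeeping gene set, positive in all
#'   samples.
#' @param posctrl apply positive-control normalization first (off by
#'   default).
#' @return A \linkS4class{NormalizedPanel} over all probes.
#' @export
normalizePanel <- function(panel, selectedHk, posctrl = FALSE) {
  if (!length(selectedHk)) stop("selectedHk must be non-empty")
  counts <- assay(panel, "counts")
  if (!all(selectedHk %in% rownames(counts))) {
    stop("selected housekeeping gene(s) absent from the panel: ",
         paste(setdiff(selectedHk, rownames(counts)), collapse = ", "))
  }
  if (posctrl) {
    pos <- probeCounts(panel, "Positive")
    if (!nrow(pos)) stop("posctrl requested but no Positive probes present")
    counts <- sweep(counts, 2, .gmScale(pos), "*")
  }
  hkm <- counts[selectedHk, , drop = FALSE]
  if (any(hkm == 0)) {
    bad <- selectedHk[apply(hkm == 0, 1, any)]
    stop("housekeeping gene(s) with a zero count in some sample: ",
         paste(bad, collapse = ", "))
  }
  sc <- .gmScale(hkm)
  new("NormalizedPanel", values = sweep(counts, 2, sc, "*"),
      scaleFactors = sc, housekeeping = as.character(selectedHk))
}

#' Panel benchmark tallies
#'
#' Convenience summary used to compare a raw panel against published
#' detection and expression-bin tallies: the number of panel genes
#' (endogenous + housekeeping) detected in at least one sample, and the
#' expression-bin sizes of the endogenous genes (optionally minus an
#' exclusion list) from their median normalized counts.
#'
#' @param panel a \linkS4class{PanelCounts}.
#' @param exclude endogenous probes to leave out of the binning (e.g. genes
#'   absent from a comparison platform).
#' @param boundaries bin boundaries on normalized counts.
#' @param vCutoff geNorm pairwise-variation cutoff for the housekeeping
#'   selection used in normalization.
#' @return list with `nDetectedAnywhere`, `binSizes`, `nHkSelected`.
#' @export
benchmarkPanelTallies <- function(panel, exclude = character(),
                                  boundaries = c(50, 200), vCutoff = 0.15) {
  thr <- detectionThresholds(panel)
  mask <- detectPanel(panel, thr)
  hkRaw <- probeCounts(panel, "Housekeeping")
  hkRaw <- hkRaw[apply(hkRaw > 0, 1, all), , drop = FALSE]
  sel <- genormSelect(genormRank(hkRaw), vCutoff)
  np <- normalizePanel(panel, selectedGenes(sel))
  endo <- setdiff(names(probeClass(panel))[probeClass(panel) == "Endogenous"],
                  exclude)
  bins <- binGenes(normValues(np)[endo, , drop = FALSE], boundaries)
  list(nDetectedAnywhere = sum(rowSums(detectionMask(mask)) > 0),
       binSizes = table(binLabels(bins)),
       nHkSelected = length(selectedGenes(sel)))
}
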