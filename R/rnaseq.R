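# Sequencing-side processing: gene-length correction (reads per kilobase),
# trimmed-mean-of-M-values factors, geTMM per-million values, and the
# sequencing detection rule (raw count >= 1; documented prominently because
# downstream detection tallies depend on it).

#' Reads per kilobase
#'
#' @param seq a \linkS4class{SeqCounts}.
#' @return gene x sample matrix `count / (length / 1000)`.
#' @export
rpkMatrix <- function(seq) {
  stopifnot(is(seq, "SeqCounts"))
  sweep(assay(seq, "counts"), 1, geneLength(seq) / 1000, "/")
}

#' TMM normalization factors on length-corrected counts
#'
#' Computes trimmed-mean-of-M-values factors on the RPK matrix (the geTMM
#' scheme) via edgeR. The reference sample is the one whose library-scaled
#' upper quartile is closest to the mean upper quartile; for each sample,
#' genes positive in both it and the reference contribute log-ratios (M)
#' and average log-abundances (A), doubly trimmed (default 30% on M, 5% on
#' A), and the factor is 2 to the precision-weighted mean of the retained M
#' values. Factors are rescaled to geometric mean 1.
#'
#' @param rpk gene x sample matrix from [rpkMatrix()] (raw counts also
#'   work; geTMM is defined on RPK).
#' @param trimLogratio,trimAbs trim fractions for M and A.
#' @return A \linkS4class{TmmFactors}.
#' @export
tmmFactors <- function(rpk, trimLogratio = 0.3, trimAbs = 0.05) {
  rpk <- as.matrix(rpk)
  if (ncol(rpk) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(rpk > 0) == 0)) stop("every sample needs >= 1 positive value")
  if (is.null(colnames(rpk))) colnames(rpk) <- sprintf("S%02d", seq_len(ncol(rpk)))
  lib <- colSums(rpk)
  # reference: upper quartile of library-scaled values closest to the mean
  uq <- apply(rpk, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))  # which.min breaks ties by order
  shared <- colSums(rpk > 0 & rpk[, ref] > 0)
  if (any(shared == 0)) {
    stop("sample(s) sharing no positive gene with the reference: ",
         paste(colnames(rpk)[shared == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(rpk, method = "TMM", refColumn = ref,
                              logratioTrim = trimLogratio,
                              sumTrim = trimAbs)
  if (anyNA(f) || any(!is.finite(f))) stop("TMM factor undefined for a sample")
  new("TmmFactors", factors = setNames(f, colnames(rpk)),
      reference = colnames(rpk)[ref])
}

#' geTMM normalized expression
#'
#' Gene-length corrected TMM values on the per-million scale:
#' `rpk[g, s] / (sum_g rpk[g, s] * factor_s) * 1e6`.
#'
#' @param seq a \linkS4class{SeqCounts}.
#' @param factors a \linkS4class{TmmFactors} computed from `rpkMatrix(seq)`
#'   (computed internally when omitted).
#' @return A \linkS4class{NormalizedSeq}.
#' @export
geTMM <- function(seq, factors = NULL) {
  rpk <- rpkMatrix(seq)
  if (is.null(factors)) factors <- tmmFactors(rpk)
  stopifnot(is(factors, "TmmFactors"))
  f <- tmmFactorValues(factors)[colnames(rpk)]
  if (anyNA(f)) stop("factors do not cover all samples")
  lib <- colSums(rpk) * f
  if (any(lib <= 0)) stop("zero effective library size in a sample")
  new("NormalizedSeq", values = sweep(rpk, 2, lib, "/") * 1e6,
      factors = factors)
}

#' Detection calls for the sequencing platform
#'
#' A gene is called detected in a sample when its raw count is at least 1.
#' (Equivalent to geTMM > 0 whenever factors are positive; the rule is
#' applied to raw counts so detection and normalization stay independent.)
#'
#' @param seq a \linkS4class{SeqCounts}.
#' @return A \linkS4class{DetectionMask} tagged `"seq"`.
#' @export
detectSeq <- function(seq) {
  stopifnot(is(seq, "SeqCounts"))
  new("DetectionMask", mask = assay(seq, "counts") >= 1, platform = "seq")
}
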