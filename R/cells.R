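# Marker-gene immune cell identification and scoring. Candidate marker
# genes are filtered by detection prevalence, selected within each cell
# type by pairwise co-expression (similarity above a strict threshold, at
# least two unique genes per cell type), and cell-type abundance per sample
# is the average transformed expression of the selected markers. A
# fixed-signature scorer (MCP-counter style) applies externally supplied
# population signatures without similarity filtering.

#' Filter candidate markers by detection prevalence
#'
#' A candidate is kept when it is above the detection limit in at least
#' `ceiling(minPrevalence * nSamples)` samples ("at least 50% of the
#' samples" by default). Candidates absent from the mask are dropped with a
#' warning; cell types losing all candidates are recorded.
#'
#' @param cands data.frame (`cellType`, `gene`) from
#'   [readCandidateMarkers()].
#' @param mask a \linkS4class{DetectionMask} covering the candidate genes.
#' @param minPrevalence required detected fraction of samples.
#' @return The filtered candidate data.frame, with attribute `"dropped"`: a
#'   data.frame of cell types removed for insufficient detection.
#' @export
filterCandidates <- function(cands, mask, minPrevalence = 0.5) {
  if (!nrow(cands)) stop("candidate table is empty")
  m <- detectionMask(mask)
  absent <- setdiff(cands$gene, rownames(m))
  if (length(absent)) {
    warning("candidate gene(s) absent from the expression matrix dropped: ",
            paste(absent, collapse = ", "))
    cands <- cands[!cands$gene %in% absent, , drop = FALSE]
  }
  need <- ceiling(minPrevalence * ncol(m))
  keep <- rowSums(m[cands$gene, , drop = FALSE]) >= need
  out <- cands[keep, , drop = FALSE]
  gone <- setdiff(unique(cands$cellType), unique(out$cellType))
  attr(out, "dropped") <- data.frame(
    cellType = gone,
    reason = rep("insufficient detection", length(gone)),
    stringsAsFactors = FALSE)
  out
}

#' Pairwise similarity of candidate genes
#'
#' Pearson (default) or Spearman correlation of `log2(x + offset)`
#' expression across samples, for every pair of the given genes. The
#' diagonal is 1; a constant gene yields missing similarities.
#'
#' @param values normalized gene x sample matrix.
#' @param genes genes to correlate (>= 2; >= 3 samples required).
#' @param method similarity metric.
#' @param offset log-transform shift.
#' @return symmetric similarity matrix.
#' @export
pairwiseSimilarity <- function(values, genes, method = c("pearson", "spearman"),
                               offset = 1) {
  method <- match.arg(method)
  if (length(genes) < 2) stop("need at least 2 genes")
  if (ncol(values) < 3) stop("need at least 3 samples")
  missing <- setdiff(genes, rownames(values))
  if (length(missing)) {
    stop("gene(s) absent from the matrix: ", paste(missing, collapse = ", "))
  }
  lx <- t(log2p(values[genes, , drop = FALSE], offset))
  s <- suppressWarnings(cor(lx, method = method))  # constant gene -> NA
  diag(s) <- 1
  s
}

#' Select marker genes by within-type co-expression
#'
#' Within each cell type's filtered candidate set, a gene is selected when
#' it belongs to at least one within-type pair whose similarity is strictly
#' above the threshold. Cell types ending with fewer than two selected
#' genes are dropped with a reason. Selection never crosses cell types.
#'
#' @param cands filtered candidate data.frame from [filterCandidates()].
#' @param values normalized gene x sample matrix.
#' @param threshold similarity threshold (strict `>`).
#' @param method,offset passed to [pairwiseSimilarity()].
#' @return A \linkS4class{SelectedMarkers}.
#' @export
selectMarkers <- function(cands, values, threshold = 0.6,
                          method = c("pearson", "spearman"), offset = 1) {
  method <- match.arg(method)
  types <- unique(cands$cellType)
  markers <- list(); best <- list()
  dropped <- attr(cands, "dropped") %||%
    data.frame(cellType = character(), reason = character())
  for (ct in types) {
    g <- sort(cands$gene[cands$cellType == ct])
    if (length(g) < 2) {
      dropped <- rbind(dropped, data.frame(cellType = ct,
                                           reason = "no qualifying pair"))
      next
    }
    s <- pairwiseSimilarity(values, g, method, offset)
    diag(s) <- NA
    qual <- apply(s > threshold, 1, any, na.rm = TRUE)
    sel <- g[qual]
    if (length(sel) < 2) {
      dropped <- rbind(dropped, data.frame(cellType = ct,
                                           reason = "no qualifying pair"))
      next
    }
    markers[[ct]] <- sel
    best[[ct]] <- apply(s[sel, , drop = FALSE], 1, max, na.rm = TRUE)
  }
  new("SelectedMarkers", markers = markers, bestSimilarity = best,
      dropped = dropped, method = method)
}

.meanExpression <- function(geneSets, values, offset, scale) {
  missing <- setdiff(unlist(geneSets), rownames(values))
  if (length(missing)) {
    stop("marker gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  tx <- if (scale == "log2") log2p(values, offset) else values
  scores <- t(vapply(geneSets, function(g) {
    colMeans(tx[g, , drop = FALSE])
  }, numeric(ncol(values))))
  dimnames(scores) <- list(names(geneSets), colnames(values))
  scores
}

#' Score immune cell abundance from selected markers
#'
#' The relative abundance of a cell type in a sample is the arithmetic
#' mean, over its selected marker genes, of the `log2(x + offset)`
#' transformed normalized expression (linear-scale averaging behind
#' `scale = "linear"`).
#'
#' @param markers a \linkS4class{SelectedMarkers}.
#' @param values normalized gene x sample matrix.
#' @param offset log shift.
#' @param scale `"log2"` (default) or `"linear"`.
#' @return A \linkS4class{CellAbundance}.
#' @export
scoreAbundance <- function(markers, values, offset = 1,
                           scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is(markers, "SelectedMarkers"))
  if (!length(markerGenes(markers))) stop("no cell types retained")
  scores <- .meanExpression(markerGenes(markers), values, offset, scale)
  new("CellAbundance", scores = scores, markers = markerGenes(markers),
      scale = scale)
}

#' Score fixed population signatures
#'
#' MCP-counter-style scoring: each population's score per sample is the
#' mean transformed expression of its signature genes that are present in
#' the matrix; absent genes are dropped with a warning and a population
#' with no present gene is dropped entirely. No similarity filtering is
#' applied — the signatures are taken as fixed.
#'
#' @param signatures named list (population -> gene vector) from
#'   [readSignatureTable()].
#' @param values normalized gene x sample matrix.
#' @param offset,scale as in [scoreAbundance()].
#' @return A \linkS4class{CellAbundance}.
#' @export
signatureScore <- function(signatures, values, offset = 1,
                           scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!length(signatures)) stop("signature table is empty")
  present <- lapply(signatures, intersect, rownames(values))
  lost <- mapply(setdiff, signatures, present, SIMPLIFY = FALSE)
  if (any(lengths(lost) > 0)) {
    warning("signature gene(s) absent from the matrix dropped: ",
            paste(unlist(lost), collapse = ", "))
  }
  empty <- names(present)[lengths(present) == 0]
  if (length(empty)) {
    warning("population(s) with no present signature gene dropped: ",
            paste(empty, collapse = ", "))
    present <- present[lengths(present) > 0]
  }
  if (!length(present)) stop("no population has a present signature gene")
  scores <- .meanExpression(present, values, offset, scale)
  new("CellAbundance", scores = scores, markers = present, scale = scale)
}
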