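#' @import methods
#' @importFrom stats cor sd median quantile rnbinom rpois rgamma rnorm rlnorm
#'   runif lm coef residuals wilcox.test setNames complete.cases
#' @importFrom utils read.csv write.csv read.delim write.table head tail
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
NULL

# Probe classes recognised on the panel side, in display order.
PROBE_CLASSES <- c("Endogenous", "Housekeeping", "Negative", "Positive")

#' PanelCounts: raw targeted-panel counts with probe annotation
#'
#' A \linkS4class{SummarizedExperiment} holding raw probe-by-sample counts
#' from an nCounter-style targeted expression panel. `rowData` carries
#' `probeClass` (one of Endogenous, Housekeeping, Negative, Positive) and
#' `hgncSymbol` (the official gene symbol, or `NA` when the probe name is a
#' platform alias that must be resolved through an alias table).
#'
#' Validity: counts are non-negative integers, probe and sample names are
#' unique, and at least one negative-control probe is present (the detection
#' threshold is defined from negative controls).
#'
#' @export
setClass("PanelCounts", contains = "SummarizedExperiment")

setValidity("PanelCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  m <- assay(object, "counts")
  v <- tryCatch({ checkCountMatrix(m); NULL }, error = function(e) conditionMessage(e))
  if (!is.null(v)) msg <- c(msg, v)
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "probe names must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample identifiers must be present and unique")
  }
  rd <- rowData(object)
  if (!all(c("probeClass", "hgncSymbol") %in% colnames(rd))) {
    msg <- c(msg, "rowData must have probeClass and hgncSymbol")
  } else {
    if (!all(rd$probeClass %in% PROBE_CLASSES)) {
      msg <- c(msg, paste("probeClass must be one of:",
                          paste(PROBE_CLASSES, collapse = ", ")))
    }
    if (!any(rd$probeClass == "Negative")) {
      msg <- c(msg, "at least one Negative control probe is required")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PanelCounts object
#'
#' @param counts non-negative integer matrix, probes x samples, with unique
#'   dimnames.
#' @param probeClass character vector, one of `"Endogenous"`,
#'   `"Housekeeping"`, `"Negative"`, `"Positive"` per probe.
#' @param hgncSymbol official gene symbols per probe; `NA` where the probe
#'   name is a platform-specific alias.
#' @return A \linkS4class{PanelCounts}.
#' @export
PanelCounts <- function(counts, probeClass,
                        hgncSymbol = rep(NA_character_, nrow(counts))) {
  counts <- as.matrix(counts)
  new("PanelCounts", SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(probeClass = as.character(probeClass),
                        hgncSymbol = as.character(hgncSymbol),
                        row.names = rownames(counts))))
}

#' SeqCounts: gene-level RNA-seq counts with gene lengths
#'
#' A \linkS4class{SummarizedExperiment} of raw gene-by-sample RNA-seq counts
#' (downstream of alignment and quantification) with per-gene exonic length
#' in bases in `rowData(x)$geneLength`. Gene symbols (rownames) are unique.
#'
#' @export
setClass("SeqCounts", contains = "SummarizedExperiment")

setValidity("SeqCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  v <- tryCatch({ checkCountMatrix(assay(object, "counts")); NULL },
                error = function(e) conditionMessage(e))
  if (!is.null(v)) msg <- c(msg, v)
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "gene symbols must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample identifiers must be present and unique")
  }
  if (!"geneLength" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must have geneLength")
  } else {
    len <- rowData(object)$geneLength
    if (anyNA(len) || any(len <= 0) || any(len != round(len))) {
      msg <- c(msg, "geneLength must be positive integers")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SeqCounts object
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param geneLength positive integer vector of gene lengths in bases.
#' @return A \linkS4class{SeqCounts}.
#' @export
SeqCounts <- function(counts, geneLength) {
  counts <- as.matrix(counts)
  new("SeqCounts", SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(geneLength = as.numeric(geneLength),
                        row.names = rownames(counts))))
}

#' DetectionThresholds: per-sample detection limits
#'
#' One threshold per sample: mean of the negative-control raw counts plus two
#' sample standard deviations. Counts at or below the threshold are treated
#' as undetected.
#'
#' @slot thresholds named numeric vector, one non-negative value per sample.
#' @export
setClass("DetectionThresholds", representation(thresholds = "numeric"))

setValidity("DetectionThresholds", function(object) {
  t <- object@thresholds
  if (is.null(names(t))) return("thresholds must be named by sample")
  if (anyNA(t) || any(t < 0)) return("thresholds must be non-negative")
  TRUE
})

#' DetectionMask: per-platform above-detection-limit calls
#'
#' @slot mask logical gene x sample matrix; `TRUE` = above the detection
#'   limit.
#' @slot platform platform tag, e.g. `"panel"` or `"seq"`.
#' @export
setClass("DetectionMask",
         representation(mask = "matrix", platform = "character"))

setValidity("DetectionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (anyNA(object@mask)) return("mask must not contain NA")
  if (is.null(rownames(object@mask)) || is.null(colnames(object@mask))) {
    return("mask must have dimnames")
  }
  if (length(object@platform) != 1L) return("platform must be length 1")
  TRUE
})

#' GeNormResult: housekeeping stability ranking and selection
#'
#' @slot mValues named numeric; per-gene stability M computed on the full
#'   candidate set (mean over partner genes of the sample SD of pairwise
#'   log2 expression ratios). Lower = more stable.
#' @slot exclusionOrder genes from least to most stable; the final,
#'   untied pair comes last (alphabetical between the two).
#' @slot stabilityOrder genes from most to least stable (reverse view used
#'   to build top-n normalization factors).
#' @slot pairwiseVariation named numeric, V(n/n+1) for n = 2..K-1: the SD
#'   across samples of log2 of the ratio of geometric-mean normalization
#'   factors built from the top-n versus top-(n+1) stable genes.
#' @slot selected the selected stable gene set (filled by
#'   [genormSelect()]; empty until then).
#' @slot fallback TRUE when no n satisfied the V cutoff and all candidates
#'   were selected.
#' @export
setClass("GeNormResult",
         representation(mValues = "numeric", exclusionOrder = "character",
                        stabilityOrder = "character",
                        pairwiseVariation = "numeric",
                        selected = "character", fallback = "logical"),
         prototype(selected = character(), fallback = FALSE))

#' NormalizedPanel: housekeeping-normalized panel counts
#'
#' @slot values gene x sample matrix of normalized counts (all probes).
#' @slot scaleFactors named per-sample scale factors applied.
#' @slot housekeeping the housekeeping genes the factors were built from.
#' @export
setClass("NormalizedPanel",
         representation(values = "matrix", scaleFactors = "numeric",
                        housekeeping = "character"))

#' TmmFactors: trimmed-mean-of-M-values normalization factors
#'
#' @slot factors named per-sample factors; geometric mean 1.
#' @slot reference identifier of the reference sample (upper-quartile rule).
#' @export
setClass("TmmFactors",
         representation(factors = "numeric", reference = "character"))

setValidity("TmmFactors", function(object) {
  f <- object@factors
  if (is.null(names(f))) return("factors must be named by sample")
  if (any(f <= 0)) return("factors must be positive")
  if (abs(mean(log(f))) > 1e-9) return("factors must have geometric mean 1")
  TRUE
})

#' NormalizedSeq: geTMM-normalized RNA-seq expression
#'
#' @slot values gene x sample matrix on the per-million scale.
#' @slot factors the \linkS4class{TmmFactors} used.
#' @export
setClass("NormalizedSeq",
         representation(values = "matrix", factors = "TmmFactors"))

#' PairedMatrix: expression matched across the two platforms
#'
#' Genes are the intersection of the panel's resolved endogenous symbols
#' with the sequencing gene symbols; samples are paired one-to-one.
#'
#' @slot valuesA,valuesB matched normalized matrices (same dimnames,
#'   `valuesB` columns renamed to the platform-A pairing).
#' @slot platformA,platformB platform tags.
#' @slot dropped probe names that could not be matched (no resolvable
#'   symbol, symbol absent from the other platform, or collision loser).
#' @slot probeMap named character: matched symbol -> source probe name on
#'   platform A (used to align probe-indexed detection masks with the
#'   matched gene set).
#' @export
#' @slot samplePairing named character: platform-A sample -> platform-B
#'   sample identifier.
setClass("PairedMatrix",
         representation(valuesA = "matrix", valuesB = "matrix",
                        platformA = "character", platformB = "character",
                        dropped = "character", probeMap = "character",
                        samplePairing = "character"))

setValidity("PairedMatrix", function(object) {
  if (!identical(dimnames(object@valuesA), dimnames(object@valuesB))) {
    return("valuesA and valuesB must share dimnames")
  }
  TRUE
})

#' SampleConcordance: per-sample cross-platform agreement
#'
#' @slot stats data.frame with one row per retained sample: `sample`,
#'   `nGenes`, `pearson`, `r2`, `slope`, `intercept`.
#' @slot residuals named list of per-gene residual vectors, one per sample.
#' @slot extremes data.frame of the three most negative and three most
#'   positive residual genes per sample.
#' @slot response which platform's log expression was the regression
#'   response (`"B"` by default; r and R^2 are direction-invariant).
#' @slot offset the shift used in the log2 transform.
#' @export
setClass("SampleConcordance",
         representation(stats = "data.frame", residuals = "list",
                        extremes = "data.frame", response = "character",
                        offset = "numeric"))

#' DetectionCrosstab: per-gene cross-platform detection categories
#'
#' @slot categories named integer counts per category; sums to the number
#'   of matched genes.
#' @slot assignment named character, the category per gene.
#' @export
setClass("DetectionCrosstab",
         representation(categories = "integer", assignment = "character"))

#' BinAssignment: expression-level bins from per-gene medians
#'
#' @slot bins named factor with levels low/intermediate/high.
#' @slot boundaries the two strictly increasing boundaries used; medians
#'   `<=` the first boundary are low, `<=` the second intermediate.
#' @slot medians the per-gene medians the bins were derived from.
#' @export
setClass("BinAssignment",
         representation(bins = "factor", boundaries = "numeric",
                        medians = "numeric"))

#' SelectedMarkers: marker genes retained per immune cell type
#'
#' @slot markers named list, cell type -> selected gene vector (>= 2 genes).
#' @slot bestSimilarity named list, per selected gene the largest
#'   within-type pairwise similarity that qualified it.
#' @slot dropped data.frame (`cellType`, `reason`) of cell types removed
#'   (insufficient detection or no qualifying pair).
#' @slot method similarity metric used ("pearson" or "spearman").
#' @export
setClass("SelectedMarkers",
         representation(markers = "list", bestSimilarity = "list",
                        dropped = "data.frame", method = "character"))

#' CellAbundance: immune cell scores per sample
#'
#' @slot scores cell type x sample matrix of relative abundance scores.
#' @slot markers named list of the genes averaged per cell type.
#' @slot scale `"log2"` or `"linear"` averaging scale.
#' @export
setClass("CellAbundance",
         representation(scores = "matrix", markers = "list",
                        scale = "character"))

#' SyntheticTruth: ground truth of a simulated paired cohort
#'
#' @slot trueLog2 gene x sample matrix of noise-free log2 expression.
#' @slot infiltration cell type x sample matrix of infiltration fractions;
#'   columns sum to 1.
#' @slot plantedMarkers named list, cell type -> marker genes (disjoint).
#' @slot plantedStableHk housekeeping genes simulated with zero biological
#'   variance.
#' @slot geneLengths named gene lengths used on the sequencing side.
#' @export
setClass("SyntheticTruth",
         representation(trueLog2 = "matrix", infiltration = "matrix",
                        plantedMarkers = "list", plantedStableHk = "character",
                        geneLengths = "numeric"))

setValidity("SyntheticTruth", function(object) {
  cs <- colSums(object@infiltration)
  if (any(abs(cs - 1) > 1e-9)) return("infiltration columns must sum to 1")
  mk <- unlist(object@plantedMarkers)
  if (anyDuplicated(mk)) return("planted markers must be disjoint")
  TRUE
})
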