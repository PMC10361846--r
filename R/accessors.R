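# Accessors and show methods. Slot access from user code should go through
# these, Bioconductor-style.

#' @describeIn PanelCounts probe class annotation per probe.
#' @param x a PanelCounts.
#' @export
probeClass <- function(x) {
  stopifnot(is(x, "PanelCounts"))
  setNames(rowData(x)$probeClass, rownames(x))
}

#' @describeIn PanelCounts HGNC symbols per probe (NA = platform alias).
#' @export
hgncSymbol <- function(x) {
  stopifnot(is(x, "PanelCounts"))
  setNames(rowData(x)$hgncSymbol, rownames(x))
}

#' Subset a PanelCounts to one probe class
#'
#' @param x a \linkS4class{PanelCounts}.
#' @param class one of `"Endogenous"`, `"Housekeeping"`, `"Negative"`,
#'   `"Positive"`.
#' @return The raw count matrix of the selected probes.
#' @export
probeCounts <- function(x, class = PROBE_CLASSES) {
  class <- match.arg(class, PROBE_CLASSES, several.ok = TRUE)
  assay(x, "counts")[probeClass(x) %in% class, , drop = FALSE]
}

#' @describeIn SeqCounts per-gene exonic length in bases.
#' @param x a SeqCounts.
#' @export
geneLength <- function(x) {
  stopifnot(is(x, "SeqCounts"))
  setNames(rowData(x)$geneLength, rownames(x))
}

#' @describeIn DetectionThresholds the named per-sample thresholds.
#' @param x a DetectionThresholds.
#' @export
thresholds <- function(x) x@thresholds

#' @describeIn DetectionMask the logical gene x sample matrix.
#' @param x a DetectionMask.
#' @export
detectionMask <- function(x) x@mask

#' @describeIn DetectionMask the platform tag.
#' @export
platform <- function(x) x@platform

#' @describeIn GeNormResult per-gene stability M on the full candidate set.
#' @param x a GeNormResult.
#' @export
mValues <- function(x) x@mValues

#' @describeIn GeNormResult V(n/n+1) pairwise variation series.
#' @export
pairwiseVariation <- function(x) x@pairwiseVariation

#' @describeIn GeNormResult the selected stable housekeeping genes.
#' @export
selectedGenes <- function(x) x@selected

#' Normalized expression values
#'
#' Extract the normalized gene x sample matrix from a
#' \linkS4class{NormalizedPanel} or \linkS4class{NormalizedSeq}.
#'
#' @param x a normalized container.
#' @return numeric matrix.
#' @export
normValues <- function(x) {
  stopifnot(is(x, "NormalizedPanel") || is(x, "NormalizedSeq"))
  x@values
}

#' @describeIn NormalizedPanel per-sample scale factors.
#' @param x a NormalizedPanel.
#' @export
scaleFactors <- function(x) x@scaleFactors

#' @describeIn TmmFactors named per-sample TMM factors.
#' @param x a TmmFactors.
#' @export
tmmFactorValues <- function(x) x@factors

#' @describeIn TmmFactors the reference sample identifier.
#' @export
referenceSample <- function(x) x@reference

#' @describeIn CellAbundance the cell type x sample score matrix.
#' @param x a CellAbundance.
#' @export
abundanceScores <- function(x) x@scores

#' @describeIn SelectedMarkers the retained cell type -> marker gene lists.
#' @param x a SelectedMarkers.
#' @export
markerGenes <- function(x) x@markers

#' @describeIn SelectedMarkers cell types dropped and why.
#' @export
droppedCellTypes <- function(x) x@dropped

#' @describeIn BinAssignment named factor of bin labels.
#' @param x a BinAssignment.
#' @export
binLabels <- function(x) x@bins

setMethod("show", "PanelCounts", function(object) {
  tab <- table(factor(probeClass(object), PROBE_CLASSES))
  cat("PanelCounts:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "SeqCounts", function(object) {
  cat("SeqCounts:", nrow(object), "genes x", ncol(object), "samples\n")
  len <- geneLength(object)
  cat("  gene length (bases): median", median(len), "\n")
})

setMethod("show", "DetectionThresholds", function(object) {
  cat("DetectionThresholds (mean negative controls + 2 SD):\n")
  print(round(object@thresholds, 3))
})

setMethod("show", "DetectionMask", function(object) {
  cat("DetectionMask [", object@platform, "]: ",
      nrow(object@mask), " genes x ", ncol(object@mask), " samples; ",
      sum(object@mask), " above-limit calls\n", sep = "")
})

setMethod("show", "GeNormResult", function(object) {
  cat("GeNormResult:", length(object@mValues), "candidate genes\n")
  cat("  most stable:",
      paste(head(object@stabilityOrder, 4), collapse = ", "), "...\n")
  if (length(object@selected)) {
    cat("  selected:", length(object@selected), "genes",
        if (object@fallback) "(fallback: no V below cutoff)" else "", "\n")
  }
})

setMethod("show", "TmmFactors", function(object) {
  cat("TmmFactors (reference:", object@reference, ")\n")
  print(round(object@factors, 4))
})

setMethod("show", "SelectedMarkers", function(object) {
  cat("SelectedMarkers:", length(object@markers), "cell types retained,",
      length(unlist(object@markers)), "marker genes;",
      nrow(object@dropped), "cell types dropped\n")
})

setMethod("show", "CellAbundance", function(object) {
  cat("CellAbundance (", object@scale, " scale): ",
      nrow(object@scores), " cell types x ", ncol(object@scores),
      " samples\n", sep = "")
})

setMethod("show", "PairedMatrix", function(object) {
  cat("PairedMatrix:", nrow(object@valuesA), "matched genes x",
      ncol(object@valuesA), "paired samples (",
      object@platformA, "vs", object@platformB, ");",
      length(object@dropped), "probes dropped\n")
})
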