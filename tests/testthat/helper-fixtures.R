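# Small in-code fixtures shared across test files.

# panel with explicit endogenous / housekeeping / negative (/ positive)
# blocks; each block a matrix or NULL
makePanel <- function(endo = NULL, hk = NULL, neg, pos = NULL,
                      hgnc = NULL) {
  blocks <- list(Endogenous = endo, Housekeeping = hk, Negative = neg,
                 Positive = pos)
  blocks <- Filter(Negate(is.null), blocks)
  counts <- do.call(rbind, blocks)
  cls <- rep(names(blocks), vapply(blocks, nrow, 0L))
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  if (is.null(hgnc)) hgnc <- rep(NA_character_, nrow(counts))
  PanelCounts(counts, probeClass = cls, hgncSymbol = hgnc)
}

# random small panel for oracle-equivalence loops
randomPanel <- function(nGenes = 12, nNeg = 4, nSamples = 4) {
  endo <- matrix(rpois(nGenes * nSamples, lambda = 60), nGenes,
                 dimnames = list(sprintf("G%02d", seq_len(nGenes)), NULL))
  neg <- matrix(rpois(nNeg * nSamples, lambda = 12), nNeg,
                dimnames = list(sprintf("N%02d", seq_len(nNeg)), NULL))
  makePanel(endo = endo, neg = neg)
}

makeSeq <- function(counts, lengths = NULL) {
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  SeqCounts(counts, geneLength = lengths)
}

# a small, fast simulation configuration for pipeline-level tests (the
# full-size default cohort is exercised in the acceptance suite)
smallConfig <- function(seed, ...) {
  args <- list(seed = seed, nEndogenous = 120, nHousekeeping = 12,
               nNegative = 6, nPositive = 4,
               cellTypes = c(T_cells = 3, B_cells = 3, NK_cells = 3),
               nDecoysPerType = 1, nStableHk = 8, nSeqMissing = 4,
               nAliasProbes = 2, nBackgroundSeq = 600, depthSeq = 5e5)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationConfig, args)
}
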