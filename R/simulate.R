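# Synthetic paired-cohort generator. Emulates a small tumor cohort measured
# twice: an nCounter-style immune panel (endogenous + housekeeping genes,
# negative/positive control probes, hybridization background) and bulk
# RNA-seq (length- and depth-dependent counts with dropout of low-abundance
# genes). Ground truth — noise-free expression, per-sample immune
# infiltration fractions, planted marker genes and planted zero-variance
# housekeeping genes — is returned so every pipeline stage can be checked
# against what was planted.

# default immune cell types and planted markers per type; together with 2
# decoy candidates per type this yields 55 candidate marker genes for 11
# cell types, the scale of a curated immune marker panel
.defaultCellTypes <- function() {
  setNames(rep(3L, 11),
           c("T_cells", "CD8_T_cells", "Cytotoxic_cells", "B_cells",
             "Plasma_B_cells", "NK_cells", "Macrophages", "Monocytes",
             "Dendritic_cells", "Neutrophils", "Treg"))
}

#' SimulationConfig: parameters of the paired-cohort generator
#'
#' @slot nSamples number of paired samples (tumors measured on both
#'   platforms).
#' @slot nEndogenous,nHousekeeping,nNegative,nPositive probe counts per
#'   class on the panel.
#' @slot cellTypes named integer vector: planted marker genes per immune
#'   cell type.
#' @slot nDecoysPerType additional candidate genes per cell type with no
#'   infiltration-driven co-expression.
#' @slot infiltrationConcentration symmetric Dirichlet concentration for
#'   per-sample cell-type fractions.
#' @slot markerEffect log2 expression added per unit centered infiltration
#'   fraction to a cell type's marker genes.
#' @slot backgroundRate Poisson mean of negative-control (hybridization
#'   background) counts.
#' @slot dispersionPanel,dispersionSeq negative-binomial size
#'   (inverse-overdispersion) of the observation model; `0` switches the
#'   platform to an exact noise-free mode (counts = rounded expectation).
#' @slot noiseKnee count level at which the panel's effective NB size is
#'   halved; makes low-expression genes noisier than the high-expression
#'   ones beyond the Poisson effect.
#' @slot depthSeq target RNA-seq library size (reads per sample).
#' @slot dropoutLow extra zero-inflation probability applied to
#'   low-expression-component genes on the sequencing side.
#' @slot nSeqMissing endogenous panel genes absent from the sequencing
#'   annotation (never planted markers or decoys).
#' @slot nStableHk housekeeping genes planted with zero biological
#'   variance; the remainder get per-sample effects of SD `hkSampleSd`.
#' @slot hkSampleSd log2 SD of the sample effects on non-stable
#'   housekeeping genes.
#' @slot nAliasProbes endogenous probes carrying a platform alias name
#'   instead of the official symbol (resolved through the alias table).
#' @slot bioSd log2 SD of the shared per-sample biological variation of
#'   endogenous non-marker genes (tumor heterogeneity seen identically by
#'   both platforms; what platform noise attenuates).
#' @slot nBackgroundSeq transcriptome background genes present only on the
#'   sequencing side, so that library composition and per-million scaling
#'   behave like whole-transcriptome data.
#' @slot seed RNG seed; required, all randomness flows from it.
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer", nEndogenous = "integer", nHousekeeping = "integer",
  nNegative = "integer", nPositive = "integer",
  cellTypes = "integer", nDecoysPerType = "integer",
  infiltrationConcentration = "numeric", markerEffect = "numeric",
  backgroundRate = "numeric", dispersionPanel = "numeric",
  dispersionSeq = "numeric", noiseKnee = "numeric", depthSeq = "numeric",
  dropoutLow = "numeric", nSeqMissing = "integer", nStableHk = "integer",
  hkSampleSd = "numeric", nAliasProbes = "integer", bioSd = "numeric",
  nBackgroundSeq = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c(nSamples = object@nSamples, nEndogenous = object@nEndogenous,
           nHousekeeping = object@nHousekeeping, nNegative = object@nNegative,
           nPositive = object@nPositive, depthSeq = object@depthSeq,
           infiltrationConcentration = object@infiltrationConcentration)
  if (any(pos <= 0)) {
    msg <- c(msg, paste("must be positive:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  nonneg <- c(markerEffect = object@markerEffect,
              backgroundRate = object@backgroundRate,
              dispersionPanel = object@dispersionPanel,
              dispersionSeq = object@dispersionSeq,
              hkSampleSd = object@hkSampleSd)
  if (any(nonneg < 0)) {
    msg <- c(msg, paste("must be non-negative:",
                        paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  }
  if (is.null(names(object@cellTypes)) || any(object@cellTypes < 2)) {
    msg <- c(msg, "cellTypes must be named with >= 2 markers per type")
  }
  nCand <- sum(object@cellTypes) +
    length(object@cellTypes) * object@nDecoysPerType
  if (nCand + object@nAliasProbes + object@nSeqMissing > object@nEndogenous) {
    msg <- c(msg, "marker + decoy + alias + missing genes exceed nEndogenous")
  }
  if (object@nStableHk > object@nHousekeeping) {
    msg <- c(msg, "nStableHk exceeds nHousekeeping")
  }
  if (object@dropoutLow < 0 || object@dropoutLow > 1) {
    msg <- c(msg, "dropoutLow must be in [0, 1]")
  }
  if (object@bioSd < 0 || object@nBackgroundSeq < 0) {
    msg <- c(msg, "bioSd and nBackgroundSeq must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults mirror the measured-cohort geometry the package targets: 6
#' paired samples on a 730-endogenous / 40-housekeeping immune panel with 8
#' negative and 6 positive control probes, 11 immune cell types with 3
#' planted markers each plus 2 decoy candidates (55 candidates total), 24
#' planted zero-variance housekeeping genes, and 8 panel genes absent from
#' the sequencing annotation.
#'
#' @param seed integer RNG seed (required; an error otherwise).
#' @param nSamples,nEndogenous,nHousekeeping,nNegative,nPositive cohort and
#'   panel geometry.
#' @param cellTypes named integer vector of planted markers per cell type.
#' @param nDecoysPerType decoy candidates per cell type.
#' @param infiltrationConcentration Dirichlet concentration (> 0).
#' @param markerEffect log2 effect per unit centered infiltration fraction.
#' @param backgroundRate mean negative-control count.
#' @param dispersionPanel,dispersionSeq NB size per platform; 0 = exact
#'   noise-free mode.
#' @param noiseKnee count scale of the expression-dependent panel noise.
#' @param depthSeq target sequencing library size.
#' @param dropoutLow extra zero probability for low-expression genes in
#'   RNA-seq.
#' @param nSeqMissing panel genes missing from the sequencing side.
#' @param nStableHk planted zero-variance housekeeping genes.
#' @param hkSampleSd log2 SD of sample effects on the other housekeeping
#'   genes.
#' @param nAliasProbes probes named by a platform alias.
#' @param bioSd log2 SD of shared per-sample biological variation of
#'   non-marker endogenous genes.
#' @param nBackgroundSeq sequencing-only transcriptome background genes.
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed,
                             nSamples = 6, nEndogenous = 730,
                             nHousekeeping = 40, nNegative = 8,
                             nPositive = 6,
                             cellTypes = .defaultCellTypes(),
                             nDecoysPerType = 2,
                             infiltrationConcentration = 1,
                             markerEffect = 20,
                             backgroundRate = 10,
                             dispersionPanel = 50, dispersionSeq = 30,
                             noiseKnee = 50, depthSeq = 5e6,
                             dropoutLow = 0.3, nSeqMissing = 8,
                             nStableHk = 24, hkSampleSd = 0.8,
                             nAliasProbes = 5, bioSd = 0.8,
                             nBackgroundSeq = 15000) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is required: the generator must be reproducible")
  }
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nEndogenous = as.integer(nEndogenous),
      nHousekeeping = as.integer(nHousekeeping),
      nNegative = as.integer(nNegative), nPositive = as.integer(nPositive),
      cellTypes = setNames(as.integer(cellTypes), names(cellTypes)),
      nDecoysPerType = as.integer(nDecoysPerType),
      infiltrationConcentration = infiltrationConcentration,
      markerEffect = markerEffect, backgroundRate = backgroundRate,
      dispersionPanel = dispersionPanel, dispersionSeq = dispersionSeq,
      noiseKnee = noiseKnee, depthSeq = depthSeq, dropoutLow = dropoutLow,
      nSeqMissing = as.integer(nSeqMissing), nStableHk = as.integer(nStableHk),
      hkSampleSd = hkSampleSd, nAliasProbes = as.integer(nAliasProbes),
      bioSd = bioSd, nBackgroundSeq = as.integer(nBackgroundSeq),
      seed = as.integer(seed))
}

# NB draw with expression-dependent size; size 0 = exact noise-free mode
.obsCounts <- function(mu, size) {
  if (all(size == 0)) return(round(mu))
  rnbinom(length(mu), mu = mu, size = pmax(size, 1e-8))
}

#' Simulate a paired panel / RNA-seq cohort with known truth
#'
#' Generative model: per-gene baseline log2 expression from a
#' low/intermediate/high mixture; per-sample cell-type fractions from a
#' symmetric Dirichlet; planted marker genes receive an additive centered
#' log2 infiltration effect (so markers of one cell type are mutually
#' co-expressed); a planted subset of housekeeping genes has zero biological
#' variance while the rest carry small sample effects. Panel counts are
#' negative binomial around `2^trueLog2` with expression-dependent size plus
#' Poisson hybridization background; negative controls are
#' `Poisson(backgroundRate)`; positive controls follow a fixed geometric
#' ladder. Sequencing counts are negative binomial with mean proportional to
#' gene length x depth x `2^trueLog2`, with extra zero-inflation for the
#' low-expression component. Identical seed, identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements `panel` (\linkS4class{PanelCounts}), `seq`
#'   (\linkS4class{SeqCounts}), `aliases` (named vector), `candidates`
#'   (data.frame `cellType`, `gene`), `signatures` (named list), `truth`
#'   (\linkS4class{SyntheticTruth}) and `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nS <- config@nSamples
  samples <- sprintf("S%02d", seq_len(nS))
  endo <- sprintf("GENE%04d", seq_len(config@nEndogenous))
  hk <- sprintf("HK%02d", seq_len(config@nHousekeeping))

  # baseline log2 expression: low / intermediate / high mixture, sized so
  # that detection-limit and expression-bin behaviour are both exercised
  comp <- sample.int(3L, config@nEndogenous, replace = TRUE,
                     prob = c(0.37, 0.17, 0.46))
  mixMean <- c(3.5, 6.6, 9.0)[comp]
  mixSd <- c(1.5, 0.6, 1.2)[comp]
  base <- setNames(rnorm(config@nEndogenous, mixMean, mixSd), endo)

  # planted markers and decoys sit at solid expression so the
  # detection-prevalence filter, not abundance, decides their fate
  types <- names(config@cellTypes)
  nMark <- sum(config@cellTypes)
  nDecoy <- length(types) * config@nDecoysPerType
  special <- sample(endo, nMark + nDecoy + config@nAliasProbes +
                      config@nSeqMissing)
  markerGenes <- special[seq_len(nMark)]
  decoyGenes <- special[nMark + seq_len(nDecoy)]
  aliasGenes <- if (config@nAliasProbes > 0)
    special[nMark + nDecoy + seq_len(config@nAliasProbes)] else character()
  seqMissing <- if (config@nSeqMissing > 0)
    special[nMark + nDecoy + config@nAliasProbes +
              seq_len(config@nSeqMissing)] else character()
  base[markerGenes] <- rnorm(nMark, mean = 7, sd = 0.8)
  comp[match(markerGenes, endo)] <- 2L
  # decoy candidates are markers of non-infiltrating populations: in an
  # immune-cold tissue their transcript signal is at or below the
  # hybridization background (the mean + 2 SD threshold needs a signal of
  # roughly twice the background SD to clear it), so the
  # detection-prevalence filter removes most of them before the
  # co-expression selection ever sees them
  base[decoyGenes] <- rnorm(nDecoy, mean = 1.5, sd = 1.5)
  comp[match(decoyGenes, endo)] <- 1L
  plantedMarkers <- split(markerGenes,
                          rep(types, times = config@cellTypes))[types]
  decoysByType <- split(decoyGenes,
                        rep(types, each = config@nDecoysPerType))[types]

  # infiltration fractions: symmetric Dirichlet per sample
  fr <- matrix(rgamma(length(types) * nS,
                      shape = config@infiltrationConcentration),
               nrow = length(types), dimnames = list(types, samples))
  fr <- sweep(fr, 2, colSums(fr), "/")

  # housekeeping: high, stable baseline; a planted subset has zero
  # biological variance, the rest small per-sample effects
  hkBase <- setNames(rnorm(config@nHousekeeping, 9, 0.8), hk)
  stableHk <- sort(sample(hk, config@nStableHk))
  unstableHk <- setdiff(hk, stableHk)

  trueLog2 <- matrix(rep(c(base, hkBase), nS),
                     ncol = nS, dimnames = list(c(endo, hk), samples))
  # shared biological inter-sample variation (tumor heterogeneity) for
  # non-marker endogenous genes; both platforms observe the same signal,
  # and platform noise attenuates it more for low-expression genes
  nonMarker <- setdiff(endo, markerGenes)
  if (config@bioSd > 0 && length(nonMarker)) {
    trueLog2[nonMarker, ] <- trueLog2[nonMarker, , drop = FALSE] +
      matrix(rnorm(length(nonMarker) * nS, 0, config@bioSd), ncol = nS)
  }
  for (ct in types) {
    eff <- config@markerEffect * (fr[ct, ] - mean(fr[ct, ]))
    trueLog2[plantedMarkers[[ct]], ] <-
      trueLog2[plantedMarkers[[ct]], , drop = FALSE] +
      rep(eff, each = length(plantedMarkers[[ct]]))
  }
  if (length(unstableHk) && config@hkSampleSd > 0) {
    trueLog2[unstableHk, ] <- trueLog2[unstableHk, , drop = FALSE] +
      matrix(rnorm(length(unstableHk) * nS, 0, config@hkSampleSd),
             ncol = nS)
  }

  # --- panel observation ---
  mu <- 2^trueLog2
  size <- if (config@dispersionPanel == 0) mu * 0 else
    config@dispersionPanel * mu / (mu + config@noiseKnee)
  panelCounts <- matrix(.obsCounts(mu, size), ncol = nS) +
    matrix(rpois(nrow(mu) * nS, config@backgroundRate), ncol = nS)
  dimnames(panelCounts) <- dimnames(mu)
  negCounts <- matrix(rpois(config@nNegative * nS, config@backgroundRate),
                      ncol = nS,
                      dimnames = list(sprintf("NEG_%02d", seq_len(config@nNegative)),
                                      samples))
  ladder <- 2^(12 - 2 * (seq_len(config@nPositive) - 1))
  posCounts <- matrix(rpois(config@nPositive * nS, rep(ladder, nS)),
                      ncol = nS,
                      dimnames = list(sprintf("POS_%02d", seq_len(config@nPositive)),
                                      samples))
  probeNames <- c(endo, hk)
  symbols <- c(endo, hk)
  aliasNames <- paste0(aliasGenes, "_PROBE")
  probeNames[match(aliasGenes, probeNames)] <- aliasNames
  symbols[match(aliasGenes, symbols)] <- NA_character_
  rownames(panelCounts) <- probeNames
  allCounts <- rbind(panelCounts, negCounts, posCounts)
  panel <- PanelCounts(
    allCounts,
    probeClass = c(rep("Endogenous", config@nEndogenous),
                   rep("Housekeeping", config@nHousekeeping),
                   rep("Negative", config@nNegative),
                   rep("Positive", config@nPositive)),
    hgncSymbol = c(symbols, rep(NA, config@nNegative + config@nPositive)))

  # --- sequencing observation ---
  # transcriptome background genes (sequencing side only) give the library
  # realistic composition so per-million values sit on the usual scale
  seqGenes <- setdiff(c(endo, hk), seqMissing)
  bgGenes <- character()
  seqLog2 <- trueLog2[seqGenes, , drop = FALSE]
  bgComp <- integer()
  if (config@nBackgroundSeq > 0) {
    bgGenes <- sprintf("BG%05d", seq_len(config@nBackgroundSeq))
    bgComp <- sample.int(3L, config@nBackgroundSeq, replace = TRUE,
                         prob = c(0.37, 0.17, 0.46))
    bgBase <- rnorm(config@nBackgroundSeq, c(3.5, 6.6, 9.0)[bgComp],
                    c(1.5, 0.6, 1.2)[bgComp])
    bgLog2 <- matrix(rep(bgBase, nS), ncol = nS,
                     dimnames = list(bgGenes, samples)) +
      matrix(rnorm(config@nBackgroundSeq * nS, 0, config@bioSd), ncol = nS)
    seqLog2 <- rbind(seqLog2, bgLog2)
    seqGenes <- c(seqGenes, bgGenes)
  }
  lengths <- setNames(pmax(200, round(rlnorm(length(seqGenes),
                                             meanlog = log(2000),
                                             sdlog = 0.8))), seqGenes)
  w <- (lengths / 1000) * 2^seqLog2
  muSeq <- sweep(w, 2, colSums(w), "/") * config@depthSeq
  sizeSeq <- if (config@dispersionSeq == 0) muSeq * 0 else
    muSeq * 0 + config@dispersionSeq
  seqCounts <- matrix(.obsCounts(muSeq, sizeSeq), ncol = nS,
                      dimnames = dimnames(muSeq))
  lowGenes <- c(intersect(seqGenes, endo[comp == 1L]),
                bgGenes[bgComp == 1L])
  if (length(lowGenes) && config@dropoutLow > 0) {
    drop <- matrix(runif(length(lowGenes) * nS) < config@dropoutLow,
                   ncol = nS)
    seqCounts[lowGenes, ][drop] <- 0
  }
  seqObj <- SeqCounts(seqCounts, geneLength = lengths)

  truth <- new("SyntheticTruth", trueLog2 = trueLog2, infiltration = fr,
               plantedMarkers = plantedMarkers, plantedStableHk = stableHk,
               geneLengths = lengths)
  candidates <- data.frame(
    cellType = rep(types, times = config@cellTypes + config@nDecoysPerType),
    gene = unlist(mapply(c, plantedMarkers, decoysByType, SIMPLIFY = FALSE)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(panel = panel, seq = seqObj,
       aliases = setNames(aliasGenes, aliasNames),
       candidates = candidates,
       signatures = plantedMarkers,
       truth = truth, config = config)
}

#' Files a written fixture directory always contains
#' @return character vector of the six pipeline input file names.
#' @export
fixtureFiles <- function() {
  c("panel.csv", "seq_counts.tsv", "gene_lengths.tsv", "aliases.tsv",
    "candidate_markers.tsv", "signatures.tsv")
}

#' Write a simulated cohort to a fixture directory
#'
#' Emits every input file the pipeline consumes (see [fixtureFiles()]), the
#' ground-truth tables, and a ready-to-run `config.yaml`, so the
#' command-line pipeline can run end-to-end from disk.
#'
#' @param dir output directory (created if needed).
#' @param cohort result of [simulateCohort()].
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(dir, cohort) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to ", dir)
  tsv <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  writePanelCounts(cohort$panel, file.path(dir, "panel.csv"))
  writeSeqCounts(cohort$seq, file.path(dir, "seq_counts.tsv"),
                 file.path(dir, "gene_lengths.tsv"))
  tsv(data.frame(probe_name = names(cohort$aliases),
                 hgnc_symbol = unname(cohort$aliases)), "aliases.tsv")
  tsv(data.frame(cell_type = cohort$candidates$cellType,
                 gene = cohort$candidates$gene), "candidate_markers.tsv")
  tsv(data.frame(population = rep(names(cohort$signatures),
                                  lengths(cohort$signatures)),
                 gene = unlist(cohort$signatures)), "signatures.tsv")
  tr <- cohort$truth
  tsv(data.frame(cell_type = rownames(tr@infiltration),
                 tr@infiltration, check.names = FALSE),
      "truth_infiltration.tsv")
  tsv(data.frame(cell_type = rep(names(tr@plantedMarkers),
                                 lengths(tr@plantedMarkers)),
                 gene = unlist(tr@plantedMarkers)), "truth_markers.tsv")
  tsv(data.frame(gene = tr@plantedStableHk), "truth_stable_hk.tsv")
  cfg <- defaultRunConfig(dir)
  cfg$seed <- cohort$config@seed
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
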