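# Pipeline orchestration: a YAML-configurable run of every stage in order
# (detection -> normalization on both platforms -> gene matching ->
# concordance -> binning -> cell scoring), with TSV outputs per stage and a
# deterministic Markdown report whose every number is recomputable from the
# stage files.

#' Default run configuration
#'
#' Parameter defaults are the conventional analysis thresholds: detection at
#' mean negative controls + 2 SD, geNorm V cutoff 0.15, similarity
#' threshold 0.6, detection prevalence 50%, expression bins (50, 200) on
#' normalized panel counts and (1, 3) on geTMM values, log2(x + 1)
#' transforms, TMM trims 0.3 / 0.05.
#'
#' @param inputDir directory holding the standard fixture files (see
#'   [fixtureFiles()]).
#' @return nested list: `inputs`, `parameters`, `seed`, `output_dir`.
#' @export
defaultRunConfig <- function(inputDir = ".") {
  list(
    inputs = list(
      panel = file.path(inputDir, "panel.csv"),
      panel_dialect = "csv",
      seq_counts = file.path(inputDir, "seq_counts.tsv"),
      gene_lengths = file.path(inputDir, "gene_lengths.tsv"),
      aliases = file.path(inputDir, "aliases.tsv"),
      candidates = file.path(inputDir, "candidate_markers.tsv"),
      signatures = file.path(inputDir, "signatures.tsv"),
      pairing = NULL),
    parameters = list(
      v_cutoff = 0.15,
      bin_boundaries_panel = c(50, 200),
      bin_boundaries_seq = c(1, 3),
      similarity_threshold = 0.6,
      similarity_method = "pearson",
      min_prevalence = 0.5,
      log_offset = 1,
      trim_logratio = 0.3,
      trim_abs = 0.05,
      posctrl = FALSE,
      response = "B"),
    seed = 1L,
    output_dir = NULL)
}

#' Read a YAML run configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file.
#' @return configuration list as in [defaultRunConfig()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (blk in c("inputs", "parameters")) {
    for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
  }
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
  if (!is.null(user$output_dir)) cfg$output_dir <- user$output_dir
  cfg
}

.logStage <- function(stage, ..., quiet = FALSE) {
  if (!quiet) message("[", stage, "] ", ...)
}

# run one stage; on error mark the run FAILED and abort naming the stage
.stage <- function(name, outDir, expr, quiet = FALSE) {
  .logStage(name, "running", quiet = quiet)
  tryCatch(expr, error = function(e) {
    if (!is.null(outDir)) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(outDir, "FAILED"))
    }
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
  })
}

.writeTsv <- function(df, outDir, name) {
  if (is.null(outDir)) return(invisible(NULL))
  write.table(df, file.path(outDir, name), sep = "\t", row.names = FALSE,
              quote = FALSE)
}

.matrixDf <- function(m, idCol = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idCol
  df
}

#' Run the full cross-platform analysis
#'
#' Executes detection, normalization of both platforms, housekeeping
#' stability on both platforms, gene matching, per-sample and per-gene
#' concordance, expression binning with bin comparisons, detection
#' cross-tabulation, and marker-gene plus fixed-signature cell scoring.
#' Identical configuration and inputs produce identical outputs; the
#' report carries no timestamps.
#'
#' @param config configuration list from [readRunConfig()] /
#'   [defaultRunConfig()].
#' @param outDir output directory for stage TSVs and `report.md`; `NULL`
#'   keeps everything in memory.
#' @param quiet suppress stage progress messages (warnings and errors
#'   still surface).
#' @return list of stage results plus `report` (the Markdown lines).
#' @export
runAll <- function(config, outDir = config$output_dir, quiet = FALSE) {
  if (!is.null(outDir) && !dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  ip <- config$inputs; pp <- config$parameters
  set.seed(config$seed %||% 1L)

  panel <- .stage("read-panel", outDir, readPanelCounts(
    ip$panel, dialect = ip$panel_dialect %||% "csv"), quiet)
  seq <- .stage("rnaseq-read", outDir,
                readSeqCounts(ip$seq_counts, ip$gene_lengths), quiet)
  aliases <- if (!is.null(ip$aliases) && file.exists(ip$aliases)) {
    readAliasTable(ip$aliases)
  } else NULL
  pairing <- if (!is.null(ip$pairing)) readPairing(ip$pairing) else NULL

  # --- detection on raw counts, both platforms ---
  det <- .stage("detect", outDir, {
    thr <- detectionThresholds(panel)
    list(thr = thr, panel = detectPanel(panel, thr), seq = detectSeq(seq))
  }, quiet)
  .writeTsv(data.frame(sample = names(thresholds(det$thr)),
                       threshold = unname(thresholds(det$thr))),
            outDir, "thresholds.tsv")
  .writeTsv(.matrixDf(detectionMask(det$panel) * 1L), outDir,
            "detection_panel.tsv")
  .writeTsv(.matrixDf(detectionMask(det$seq) * 1L), outDir,
            "detection_seq.tsv")

  # --- housekeeping stability and panel normalization ---
  norm <- .stage("normalize-panel", outDir, {
    hkRaw <- probeCounts(panel, "Housekeeping")
    hkRaw <- hkRaw[apply(hkRaw > 0, 1, all), , drop = FALSE]
    gnPanel <- genormSelect(genormRank(hkRaw), pp$v_cutoff)
    list(gnPanel = gnPanel,
         panel = normalizePanel(panel, selectedGenes(gnPanel),
                                posctrl = isTRUE(pp$posctrl)))
  }, quiet)
  seqNorm <- .stage("normalize-seq", outDir, {
    fac <- tmmFactors(rpkMatrix(seq), pp$trim_logratio, pp$trim_abs)
    list(fac = fac, seq = geTMM(seq, fac))
  }, quiet)
  gnSeq <- .stage("genorm-seq", outDir, {
    hkSyms <- intersect(names(probeClass(panel))[
      probeClass(panel) == "Housekeeping"], rownames(seq))
    hkm <- normValues(seqNorm$seq)[hkSyms, , drop = FALSE]
    hkm <- hkm[apply(hkm > 0, 1, all), , drop = FALSE]
    genormSelect(genormRank(hkm), pp$v_cutoff)
  }, quiet)
  for (side in c("panel", "seq")) {
    gn <- if (side == "panel") norm$gnPanel else gnSeq
    .writeTsv(data.frame(gene = names(mValues(gn)),
                         m_value = unname(mValues(gn)),
                         rank = match(names(mValues(gn)), gn@stabilityOrder),
                         selected = names(mValues(gn)) %in% selectedGenes(gn)),
              outDir, sprintf("genorm_%s.tsv", side))
  }
  .writeTsv(.matrixDf(normValues(norm$panel), "probe"), outDir,
            "normalized_panel.tsv")
  .writeTsv(data.frame(sample = names(tmmFactorValues(seqNorm$fac)),
                       factor = unname(tmmFactorValues(seqNorm$fac)),
                       is_reference = names(tmmFactorValues(seqNorm$fac)) ==
                         referenceSample(seqNorm$fac)),
            outDir, "factors_seq.tsv")
  .writeTsv(.matrixDf(normValues(seqNorm$seq)), outDir, "normalized_seq.tsv")

  # --- cross-platform matching and concordance ---
  paired <- .stage("match", outDir, matchGenes(
    panel, seq, normValues(norm$panel), normValues(seqNorm$seq),
    aliases = aliases, pairing = pairing), quiet)
  conc <- .stage("concord", outDir, sampleConcordance(
    paired, det$panel, det$seq, offset = pp$log_offset,
    response = pp$response), quiet)
  .writeTsv(conc@stats, outDir, "sample_concordance.tsv")
  .writeTsv(do.call(rbind, lapply(names(conc@residuals), function(s) {
    data.frame(sample = s, gene = names(conc@residuals[[s]]),
               residual = unname(conc@residuals[[s]]))
  })), outDir, "residuals.tsv")
  .writeTsv(conc@extremes, outDir, "residual_extremes.tsv")

  xtab <- .stage("crosstab", outDir, detectionCrosstab(
    .maskOverGenes(det$panel, paired, "A"),
    .maskOverGenes(det$seq, paired, "B")), quiet)
  .writeTsv(data.frame(category = names(xtab@categories),
                       n = unname(xtab@categories)),
            outDir, "crosstab.tsv")
  .writeTsv(data.frame(gene = names(xtab@assignment),
                       category = unname(xtab@assignment)),
            outDir, "crosstab_genes.tsv")

  bins <- .stage("bins", outDir, {
    list(panel = binGenes(paired@valuesA, pp$bin_boundaries_panel),
         seq = binGenes(paired@valuesB, pp$bin_boundaries_seq))
  }, quiet)
  gs <- .stage("gene-spearman", outDir, geneSpearman(paired), quiet)
  binCmp <- .stage("bin-compare", outDir, lapply(bins, compareBins, gc = gs),
                   quiet)
  for (side in c("panel", "seq")) {
    .writeTsv(data.frame(gene = names(binLabels(bins[[side]])),
                         median = unname(bins[[side]]@medians),
                         bin = as.character(binLabels(bins[[side]]))),
              outDir, sprintf("bins_%s.tsv", side))
    .writeTsv(binCmp[[side]]$binStats, outDir,
              sprintf("bin_stats_%s.tsv", side))
    .writeTsv(binCmp[[side]]$tests, outDir,
              sprintf("bin_comparison_%s.tsv", side))
  }
  .writeTsv(gs, outDir, "gene_spearman.tsv")

  # --- cell scoring on both platforms; fixed signatures on the seq side ---
  cells <- .stage("cells", outDir, {
    cands <- readCandidateMarkers(ip$candidates)
    out <- list()
    for (side in c("panel", "seq")) {
      vals <- if (side == "panel") {
        v <- normValues(norm$panel)
        # candidates are given as symbols; index panel rows through probes
        rownames(v)[match(paired@probeMap, rownames(v))] <-
          names(paired@probeMap)
        v
      } else normValues(seqNorm$seq)
      mask <- if (side == "panel") {
        new("DetectionMask",
            mask = .maskOverGenes(det$panel, paired, "A"), platform = "panel")
      } else det$seq
      filt <- filterCandidates(cands, mask, pp$min_prevalence)
      sel <- selectMarkers(filt, vals, pp$similarity_threshold,
                           pp$similarity_method, pp$log_offset)
      out[[side]] <- list(
        selected = sel,
        abundance = if (length(markerGenes(sel)))
          scoreAbundance(sel, vals, pp$log_offset) else NULL)
    }
    out$signature <- if (!is.null(ip$signatures) &&
                           file.exists(ip$signatures)) {
      signatureScore(readSignatureTable(ip$signatures),
                     normValues(seqNorm$seq), pp$log_offset)
    } else NULL
    out
  }, quiet)
  for (side in c("panel", "seq")) {
    sel <- cells[[side]]$selected
    .writeTsv(data.frame(
      cell_type = rep(names(markerGenes(sel)), lengths(markerGenes(sel))),
      gene = unlist(markerGenes(sel)),
      best_similarity = unlist(sel@bestSimilarity)),
      outDir, sprintf("selected_markers_%s.tsv", side))
    .writeTsv(droppedCellTypes(sel), outDir,
              sprintf("dropped_cell_types_%s.tsv", side))
    if (!is.null(cells[[side]]$abundance)) {
      .writeTsv(.matrixDf(abundanceScores(cells[[side]]$abundance),
                          "cell_type"),
                outDir, sprintf("abundance_%s.tsv", side))
    }
  }
  if (!is.null(cells$signature)) {
    .writeTsv(.matrixDf(abundanceScores(cells$signature), "population"),
              outDir, "signature_scores_seq.tsv")
  }

  report <- .buildReport(config, panel, seq, det, norm, gnSeq, seqNorm,
                         paired, conc, xtab, bins, gs, binCmp, cells)
  if (!is.null(outDir)) {
    writeLines(report, file.path(outDir, "report.md"))
    failed <- file.path(outDir, "FAILED")
    if (file.exists(failed)) file.remove(failed)
  }
  invisible(list(panel = panel, seq = seq, detection = det,
                 panelNorm = norm, seqNorm = seqNorm, genormSeq = gnSeq,
                 paired = paired, concordance = conc, crosstab = xtab,
                 bins = bins, geneSpearman = gs, binComparison = binCmp,
                 cells = cells, report = report))
}

.buildReport <- function(config, panel, seq, det, norm, gnSeq, seqNorm,
                         paired, conc, xtab, bins, gs, binCmp, cells) {
  pp <- config$parameters
  pmask <- detectionMask(det$panel)
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  checksums <- vapply(Filter(function(p) is.character(p) && file.exists(p),
                             config$inputs),
                      function(p) unname(tools::md5sum(p)), character(1))
  binLine <- function(side) {
    st <- binCmp[[side]]$binStats
    paste0("- ", side, ": ",
           paste(sprintf("%s n=%d mean rho=%s", st$bin, st$n,
                         fmt(st$meanRho)), collapse = "; "))
  }
  c(sprintf("# Cross-platform concordance report"),
    sprintf("immunoConcord %s",
            as.character(utils::packageVersion("immunoConcord"))),
    "",
    "## Detection",
    sprintf("- panel genes detected in >= 1 sample: %d / %d",
            sum(rowSums(pmask) > 0), nrow(pmask)),
    sprintf("- panel genes detected per sample: %s",
            paste(sprintf("%s=%d", colnames(pmask), colSums(pmask)),
                  collapse = ", ")),
    sprintf("- seq genes detected in >= 1 sample: %d / %d",
            sum(rowSums(detectionMask(det$seq)) > 0), nrow(seq)),
    "",
    "## Housekeeping stability (geNorm)",
    sprintf("- selected on panel: %d gene(s)%s",
            length(selectedGenes(norm$gnPanel)),
            if (norm$gnPanel@fallback) " [fallback]" else ""),
    sprintf("- selected on seq: %d gene(s)%s", length(selectedGenes(gnSeq)),
            if (gnSeq@fallback) " [fallback]" else ""),
    sprintf("- overlap of the two selections: %d gene(s)",
            length(intersect(selectedGenes(norm$gnPanel),
                             selectedGenes(gnSeq)))),
    "",
    "## Gene matching",
    sprintf("- matched genes: %d (dropped probes: %d)",
            nrow(paired@valuesA), length(paired@dropped)),
    "",
    "## Per-sample concordance (log2(x + %s), response platform %s)" |>
      sprintf(fmt(pp$log_offset), conc@response),
    sprintf("- mean Pearson r: %s (min %s, max %s); mean R^2: %s",
            fmt(mean(conc@stats$pearson)), fmt(min(conc@stats$pearson)),
            fmt(max(conc@stats$pearson)), fmt(mean(conc@stats$r2))),
    "",
    "## Detection cross-tabulation over matched genes",
    sprintf("- %s: %d", names(xtab@categories), unname(xtab@categories)),
    "",
    "## Expression bins and per-gene Spearman",
    sprintf("- mean Spearman rho over matched genes: %s (missing: %d)",
            fmt(mean(gs$rho[!gs$missing])), sum(gs$missing)),
    binLine("panel"),
    binLine("seq"),
    "",
    "## Cell scoring",
    sprintf("- panel: %d cell type(s) retained, %d marker gene(s)",
            length(markerGenes(cells$panel$selected)),
            length(unlist(markerGenes(cells$panel$selected)))),
    sprintf("- seq: %d cell type(s) retained, %d marker gene(s)",
            length(markerGenes(cells$seq$selected)),
            length(unlist(markerGenes(cells$seq$selected)))),
    if (!is.null(cells$signature)) {
      sprintf("- fixed signatures scored on seq: %d population(s)",
              nrow(abundanceScores(cells$signature)))
    },
    "",
    "## Parameters",
    sprintf("- %s: %s", names(pp),
            vapply(pp, function(v) paste(v, collapse = ", "), character(1))),
    sprintf("- seed: %d", config$seed %||% NA_integer_),
    "",
    "## Input checksums (md5)",
    sprintf("- %s: %s", names(checksums), unname(checksums)))
}
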