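# Readers and writers for the tabular formats the pipeline consumes, plus
# cross-platform gene-symbol matching. Panel CSV schema: one header row with
# probe_name, probe_class, hgnc_symbol, then one column per sample. RCC files
# (one per sample) are the sectioned text format emitted by the instrument;
# only the Code_Summary and Lane_Attributes sections are used.

#' Read raw panel counts
#'
#' @param path for `dialect = "csv"` a single CSV file; for
#'   `dialect = "rcc"` a directory of `.RCC` files or a character vector of
#'   RCC file paths (one per sample, merged by probe name).
#' @param dialect input format.
#' @return A \linkS4class{PanelCounts}.
#' @export
readPanelCounts <- function(path, dialect = c("csv", "rcc")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") .readPanelCsv(path) else .readPanelRcc(path)
}

.readPanelCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_name", "probe_class", "hgnc_symbol")
  if (!all(need %in% colnames(df))) {
    stop("panel CSV format error: missing column(s) ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  }
  if (anyDuplicated(df$probe_name)) {
    stop("panel CSV format error: duplicate probe_name: ",
         paste(unique(df$probe_name[duplicated(df$probe_name)]), collapse = ", "))
  }
  sampleCols <- setdiff(colnames(df), need)
  if (!length(sampleCols)) stop("panel CSV format error: no sample columns")
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)) || any(m < 0)) {
    stop("panel CSV format error: counts must be non-negative integers")
  }
  rownames(m) <- df$probe_name
  sym <- df$hgnc_symbol
  sym[!is.na(sym) & sym == ""] <- NA_character_
  PanelCounts(m, probeClass = df$probe_class, hgncSymbol = sym)
}

# Parse one RCC file into list(sample = id, probes = data.frame)
.parseRcc <- function(file) {
  lines <- readLines(file, warn = FALSE)
  sectionOf <- function(name) {
    # accept <Code_Summary> and <CodeSummary> spellings
    pat <- gsub("_", "_?", name)
    open <- grep(sprintf("^<%s>$", pat), lines)
    close <- grep(sprintf("^</%s>$", pat), lines)
    if (!length(open) || !length(close)) return(NULL)
    lines[(open[1] + 1):(close[1] - 1)]
  }
  cs <- sectionOf("Code_Summary")
  if (is.null(cs)) stop("RCC format error: no Code_Summary section in ", file)
  probes <- read.csv(text = paste(cs, collapse = "\n"),
                     stringsAsFactors = FALSE)
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% colnames(probes))) {
    stop("RCC format error: Code_Summary must have CodeClass, Name, Count")
  }
  id <- NA_character_
  for (sec in c("Lane_Attributes", "Sample_Attributes")) {
    la <- sectionOf(sec)
    if (!is.null(la)) {
      kv <- strsplit(la, ",", fixed = TRUE)
      hit <- vapply(kv, function(x) length(x) >= 2 && x[1] == "ID", logical(1))
      if (any(hit)) { id <- kv[[which(hit)[1]]][2]; break }
    }
  }
  if (is.na(id) || id == "") {
    id <- sub("\\.rcc$", "", basename(file), ignore.case = TRUE)
  }
  list(sample = id, probes = probes)
}

.readPanelRcc <- function(path) {
  files <- path
  if (length(path) == 1 && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.rcc$", ignore.case = TRUE,
                        full.names = TRUE)
  }
  if (!length(files)) stop("no RCC files found at ", paste(path, collapse = ", "))
  parsed <- lapply(sort(files), .parseRcc)
  ref <- parsed[[1]]$probes
  if (anyDuplicated(ref$Name)) {
    stop("RCC format error: duplicate probe name in ", files[1])
  }
  counts <- vapply(parsed, function(p) {
    i <- match(ref$Name, p$probes$Name)
    if (anyNA(i)) stop("RCC format error: probe sets differ across files")
    as.numeric(p$probes$Count[i])
  }, numeric(nrow(ref)))
  if (any(counts != round(counts)) || any(counts < 0)) {
    stop("RCC format error: counts must be non-negative integers")
  }
  counts <- matrix(counts, nrow = nrow(ref),
                   dimnames = list(ref$Name,
                                   vapply(parsed, `[[`, character(1), "sample")))
  # RCC CodeClass may carry plexity suffixes (e.g. Endogenous1)
  cls <- sub("[0-9]+$", "", ref$CodeClass)
  sym <- if ("Symbol" %in% colnames(ref)) ref$Symbol else rep(NA_character_, nrow(ref))
  sym[!is.na(sym) & sym == ""] <- NA_character_
  PanelCounts(counts, probeClass = cls, hgncSymbol = sym)
}

#' Write panel counts to the CSV dialect
#'
#' @param x a \linkS4class{PanelCounts}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePanelCounts <- function(x, path) {
  df <- data.frame(probe_name = rownames(x),
                   probe_class = probeClass(x),
                   hgnc_symbol = ifelse(is.na(hgncSymbol(x)), "", hgncSymbol(x)),
                   assay(x, "counts"), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read RNA-seq gene counts and gene lengths
#'
#' @param countsPath TSV with a `gene` column and one column per sample.
#' @param lengthsPath TSV with columns `gene`, `length` (bases).
#' @return A \linkS4class{SeqCounts}; genes are restricted to those with a
#'   length, and a gene with counts but no length is an error.
#' @export
readSeqCounts <- function(countsPath, lengthsPath) {
  for (p in c(countsPath, lengthsPath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  df <- read.delim(countsPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(df) || !"gene" %in% colnames(df)) {
    stop("seq counts format error: need a non-empty TSV with a 'gene' column")
  }
  if (anyDuplicated(df$gene)) stop("seq counts format error: duplicate gene symbols")
  len <- read.delim(lengthsPath, stringsAsFactors = FALSE)
  if (!all(c("gene", "length") %in% colnames(len))) {
    stop("gene lengths format error: need columns gene, length")
  }
  missing <- setdiff(df$gene, len$gene)
  if (length(missing)) {
    stop("genes with counts but no length: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(df[, setdiff(colnames(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  SeqCounts(m, geneLength = len$length[match(df$gene, len$gene)])
}

#' Write RNA-seq counts and lengths
#'
#' @param x a \linkS4class{SeqCounts}.
#' @param countsPath,lengthsPath output TSV paths.
#' @return `countsPath`, invisibly.
#' @export
writeSeqCounts <- function(x, countsPath, lengthsPath) {
  df <- data.frame(gene = rownames(x), assay(x, "counts"), check.names = FALSE)
  write.table(df, countsPath, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(gene = rownames(x), length = geneLength(x)),
              lengthsPath, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(countsPath)
}

#' Read a probe-name to HGNC-symbol alias table
#'
#' Two-column TSV (`probe_name`, `hgnc_symbol`); each probe name maps to
#' exactly one symbol (e.g. the activating KIR subgroup probes map to
#' individual KIR genes).
#'
#' @param path TSV path.
#' @return named character vector, probe name -> symbol.
#' @export
readAliasTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_name", "hgnc_symbol") %in% colnames(df))) {
    stop("alias table format error: need columns probe_name, hgnc_symbol")
  }
  if (anyDuplicated(df$probe_name)) {
    stop("alias table format error: probe_name must map to exactly one symbol")
  }
  setNames(df$hgnc_symbol, df$probe_name)
}

#' Read a cell type -> candidate marker gene table
#'
#' TSV with columns `cell_type`, `gene`. A gene may appear under one cell
#' type only.
#'
#' @param path TSV path.
#' @return data.frame with columns `cellType`, `gene`.
#' @export
readCandidateMarkers <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% colnames(df))) {
    stop("candidate table format error: need columns cell_type, gene")
  }
  if (!nrow(df)) stop("candidate table is empty")
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup)) {
    stop("candidate table format error: gene(s) under more than one cell type: ",
         paste(dup, collapse = ", "))
  }
  data.frame(cellType = df$cell_type, gene = df$gene,
             stringsAsFactors = FALSE)
}

#' Read a fixed population -> signature gene table
#'
#' @param path TSV with columns `population`, `gene`.
#' @return named list, population -> gene vector.
#' @export
readSignatureTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("population", "gene") %in% colnames(df)) || !nrow(df)) {
    stop("signature table format error: need non-empty columns population, gene")
  }
  split(df$gene, df$population)
}

#' Read an explicit cross-platform sample pairing
#'
#' @param path TSV with columns `panel_sample`, `seq_sample`.
#' @return data.frame with those two columns.
#' @export
readPairing <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("panel_sample", "seq_sample") %in% colnames(df))) {
    stop("pairing format error: need columns panel_sample, seq_sample")
  }
  df
}

# Resolve endogenous probe names to uppercase HGNC symbols. Returns a
# data.frame(probe, symbol) for resolvable probes plus the dropped log.
.resolveSymbols <- function(panel, aliases = NULL) {
  endo <- names(probeClass(panel))[probeClass(panel) == "Endogenous"]
  sym <- hgncSymbol(panel)[endo]
  unresolved <- is.na(sym)
  if (any(unresolved) && !is.null(aliases)) {
    hit <- match(endo[unresolved], names(aliases))
    sym[unresolved][!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  dropped <- endo[is.na(sym)]
  keep <- !is.na(sym)
  list(map = data.frame(probe = endo[keep], symbol = toupper(sym[keep]),
                        stringsAsFactors = FALSE),
       dropped = dropped)
}

#' Match genes across platforms through HGNC symbols
#'
#' Resolves panel endogenous probe names to official symbols (direct
#' annotation first, then the alias table), compares symbols
#' case-insensitively, and intersects with the sequencing gene set.
#' Housekeeping and control probes are excluded. When two probes resolve to
#' the same symbol the probe with the higher mean raw count is kept and the
#' other logged as dropped. Samples are paired by identical identifier
#' unless an explicit pairing table is given.
#'
#' @param panel a \linkS4class{PanelCounts} (for probe annotation and the
#'   collision rule).
#' @param seq a \linkS4class{SeqCounts}.
#' @param panelValues normalized panel matrix, rows indexed by probe name.
#' @param seqValues normalized sequencing matrix, rows indexed by symbol.
#' @param aliases optional named vector from [readAliasTable()].
#' @param pairing optional data.frame (`panel_sample`, `seq_sample`).
#' @return A \linkS4class{PairedMatrix}; platform A is the panel.
#' @export
matchGenes <- function(panel, seq, panelValues, seqValues, aliases = NULL,
                       pairing = NULL) {
  res <- .resolveSymbols(panel, aliases)
  map <- res$map
  droppedLog <- res$dropped
  if (length(droppedLog)) {
    message(length(droppedLog), " probe(s) without a resolvable symbol dropped: ",
            paste(head(droppedLog, 5), collapse = ", "),
            if (length(droppedLog) > 5) ", ...")
  }
  # collision rule: keep the probe with the higher mean raw count
  if (anyDuplicated(map$symbol)) {
    rawMeans <- rowMeans(assay(panel, "counts"))[map$probe]
    ord <- order(map$symbol, -rawMeans, map$probe)
    map <- map[ord, ]
    losers <- map$probe[duplicated(map$symbol)]
    message(length(losers), " probe(s) dropped by symbol collision: ",
            paste(losers, collapse = ", "))
    droppedLog <- c(droppedLog, losers)
    map <- map[!duplicated(map$symbol), ]
  }
  seqSyms <- toupper(rownames(seq))
  shared <- sort(intersect(map$symbol, seqSyms))
  if (!length(shared)) stop("zero overlapping genes between platforms")
  droppedLog <- c(droppedLog, map$probe[!map$symbol %in% shared])

  if (is.null(pairing)) {
    if (!setequal(colnames(panelValues), colnames(seqValues))) {
      stop("sample identifiers differ between platforms and no pairing ",
           "table was supplied")
    }
    pairing <- data.frame(panel_sample = colnames(panelValues),
                          seq_sample = colnames(panelValues))
  }
  if (!all(pairing$panel_sample %in% colnames(panelValues)) ||
      !all(pairing$seq_sample %in% colnames(seqValues))) {
    stop("pairing refers to unknown sample identifiers")
  }
  map <- map[match(shared, map$symbol), ]
  a <- panelValues[map$probe, pairing$panel_sample, drop = FALSE]
  dimnames(a) <- list(shared, pairing$panel_sample)
  b <- seqValues[match(shared, seqSyms), pairing$seq_sample, drop = FALSE]
  dimnames(b) <- list(shared, pairing$panel_sample)
  new("PairedMatrix", valuesA = a, valuesB = b,
      platformA = "panel", platformB = "seq",
      dropped = unique(droppedLog),
      probeMap = setNames(map$probe, shared),
      samplePairing = setNames(pairing$seq_sample, pairing$panel_sample))
}
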