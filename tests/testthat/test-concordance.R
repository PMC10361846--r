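# Per-sample correlation and residuals, detection cross-tabulation,
# expression bins, per-gene Spearman, and the bin comparison test.

pairedFrom <- function(a, b) {
  new("PairedMatrix", valuesA = a, valuesB = b, platformA = "panel",
      platformB = "seq", dropped = character(),
      probeMap = setNames(rownames(a), rownames(a)),
      samplePairing = setNames(colnames(a), colnames(a)))
}

test_that("identical platforms give r = 1, unit slope, zero residuals", {
  set.seed(71)
  a <- matrix(2^runif(30, 1, 10), 10, 3,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:3)))
  sc <- sampleConcordance(pairedFrom(a, a))
  expect_equal(sc@stats$pearson, rep(1, 3), tolerance = 1e-12)
  expect_equal(sc@stats$slope, rep(1, 3), tolerance = 1e-12)
  expect_equal(sc@stats$intercept, rep(0, 3), tolerance = 1e-9)
  expect_true(all(abs(unlist(sc@residuals)) < 1e-9))
  expect_equal(sc@stats$r2, sc@stats$pearson^2, tolerance = 1e-12)
})

test_that("a perfect negative log-linear relation gives r = -1", {
  x <- 2^(1:6)
  a <- matrix(x, 6, 3, dimnames = list(paste0("G", 1:6), paste0("S", 1:3)))
  # log2(b + 1) = 20 - 2 log2(a + 1)
  b <- 2^(20 - 2 * log2(a + 1)) - 1
  sc <- sampleConcordance(pairedFrom(a, b))
  expect_equal(sc@stats$pearson, rep(-1, 3), tolerance = 1e-9)
})

test_that("per-sample fit matches the normal-equations oracle", {
  set.seed(72)
  for (i in 1:10) {
    a <- matrix(2^runif(30, 0, 12), 10, 3,
                dimnames = list(paste0("G", 1:10), paste0("S", 1:3)))
    b <- matrix(2^runif(30, 0, 12), 10, 3, dimnames = dimnames(a))
    sc <- sampleConcordance(pairedFrom(a, b))
    for (s in colnames(a)) {
      o <- bfOls(log2(a[, s] + 1), log2(b[, s] + 1))
      row <- sc@stats[sc@stats$sample == s, ]
      expect_equal(row$pearson, o$r, tolerance = 1e-12)
      expect_equal(row$slope, o$slope, tolerance = 1e-9)
      expect_equal(row$intercept, o$intercept, tolerance = 1e-9)
      expect_equal(unname(sc@residuals[[s]]), unname(o$resid),
                   tolerance = 1e-9)
      expect_equal(mean(sc@residuals[[s]]), 0, tolerance = 1e-9)
    }
  }
})

test_that("with offset zero the correlation is exactly scale-invariant", {
  set.seed(73)
  a <- matrix(2^runif(24, 1, 10), 8, 3,
              dimnames = list(paste0("G", 1:8), paste0("S", 1:3)))
  b <- matrix(2^runif(24, 1, 10), 8, 3, dimnames = dimnames(a))
  r1 <- sampleConcordance(pairedFrom(a, b), offset = 0)@stats$pearson
  r2 <- sampleConcordance(pairedFrom(a * 7, b * 0.13), offset = 0)@stats$pearson
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("samples with too few shared detected genes are skipped", {
  a <- matrix(2^runif(12, 1, 10), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  maskA <- new("DetectionMask", platform = "panel",
               mask = matrix(c(rep(TRUE, 4), rep(TRUE, 4),
                               c(TRUE, TRUE, FALSE, FALSE)), 4,
                             dimnames = dimnames(a)))
  expect_warning(sc <- sampleConcordance(pairedFrom(a, a), maskA, NULL),
                 "S3 skipped")
  expect_equal(sc@stats$sample, c("S1", "S2"))
  maskNone <- new("DetectionMask", platform = "panel",
                  mask = matrix(FALSE, 4, 3, dimnames = dimnames(a)))
  expect_error(suppressWarnings(sampleConcordance(pairedFrom(a, a), maskNone,
                                                  NULL)),
               "no sample")
})

test_that("the three most divergent genes per direction are reported", {
  set.seed(74)
  a <- matrix(2^runif(30, 3, 10), 10, 3,
              dimnames = list(paste0("G", 1:10), paste0("S", 1:3)))
  b <- a * matrix(2^rnorm(30, 0, 1), 10, 3)
  sc <- sampleConcordance(pairedFrom(a, b))
  ex <- sc@extremes[sc@extremes$sample == "S1", ]
  expect_equal(nrow(ex), 6)
  r <- sort(sc@residuals[["S1"]])
  expect_equal(ex$gene[ex$direction == "negative"], names(r)[1:3])
  expect_equal(ex$gene[ex$direction == "positive"],
               names(r)[(length(r) - 2):length(r)])
})

test_that("crosstab categories follow the fielded logic", {
  mk <- function(...) {
    m <- rbind(...)
    dimnames(m) <- list(paste0("G", seq_len(nrow(m))),
                        paste0("S", seq_len(ncol(m))))
    m
  }
  maskA <- mk(rep(TRUE, 6), rep(FALSE, 6), rep(TRUE, 6),
              c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), rep(FALSE, 6))
  maskB <- mk(rep(TRUE, 6), rep(TRUE, 6), c(TRUE, rep(FALSE, 5)),
              c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), rep(FALSE, 6))
  xt <- detectionCrosstab(maskA, maskB)
  expect_equal(unname(xt@assignment),
               c("both_all", "only_b_all", "discordant",
                 "concordant_partial", "neither"))
  expect_equal(sum(xt@categories), nrow(maskA))
})

test_that("crosstab matches exhaustive classification on random masks", {
  set.seed(75)
  for (i in 1:10) {
    maskA <- matrix(runif(300) < 0.6, 50, 6,
                    dimnames = list(paste0("G", 1:50), paste0("S", 1:6)))
    maskB <- matrix(runif(300) < 0.6, 50, 6, dimnames = dimnames(maskA))
    xt <- detectionCrosstab(maskA, maskB)
    expect_identical(xt@assignment, bfCrosstab(maskA, maskB))
    expect_equal(sum(xt@categories), 50L)
  }
  expect_error(detectionCrosstab(maskA, maskB[1:10, ]), "share")
})

test_that("bin boundaries are inclusive downward", {
  v <- matrix(c(10, 100, 300, 50, 200), 5, 2,
              dimnames = list(paste0("G", 1:5), c("S1", "S2")))
  v[, 2] <- v[, 1]  # medians equal the values
  bins <- binGenes(v, c(50, 200))
  expect_equal(as.character(binLabels(bins)),
               c("low", "intermediate", "high", "low", "intermediate"))
  expect_error(binGenes(v, c(200, 50)), "increasing")
  # degenerate boundaries: every positive median is intermediate
  wide <- binGenes(v, c(0, Inf))
  expect_true(all(binLabels(wide) == "intermediate"))
})

test_that("per-gene Spearman is tie-corrected and flags constant genes", {
  a <- matrix(c(1, 2, 3, 4, 5, 6,
                5, 5, 5, 5, 5, 5,
                1, 1, 2, 3, 4, 5), 3, byrow = TRUE,
              dimnames = list(c("MONO", "CONST", "TIED"), paste0("S", 1:6)))
  b <- matrix(c(2, 4, 6, 8, 10, 12,
                1, 2, 3, 4, 5, 6,
                2, 2, 3, 3, 5, 6), 3, byrow = TRUE, dimnames = dimnames(a))
  gs <- geneSpearman(pairedFrom(a, b))
  expect_equal(gs$rho[gs$gene == "MONO"], 1, tolerance = 1e-12)
  expect_true(gs$missing[gs$gene == "CONST"])
  expect_equal(gs$rho[gs$gene == "TIED"],
               bfSpearman(a["TIED", ], b["TIED", ]), tolerance = 1e-12)
  expect_equal(gs$rho[gs$gene == "TIED"],
               cor(a["TIED", ], b["TIED", ], method = "spearman"),
               tolerance = 1e-12)
})

test_that("Mann-Whitney p-values are exact under ties for small samples", {
  # fully separated 3 vs 3: 2 of the 20 rank splits are as extreme
  expect_equal(mannWhitney(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9)), 1 / 10,
               tolerance = 1e-9)
  # untied small samples agree with the classical exact test
  set.seed(76)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mannWhitney(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  # identical samples: no evidence, p = 1
  z <- rnorm(30)
  expect_equal(mannWhitney(z, z), 1, tolerance = 1e-12)
  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(77)
  x <- sample(1:5, 200, replace = TRUE); y <- sample(2:6, 150, replace = TRUE)
  expect_equal(mannWhitney(x, y),
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("bin comparison reports means, counts and pairwise tests", {
  gc <- data.frame(gene = paste0("G", 1:9),
                   rho = c(0.1, 0.15, 0.1, 0.3, 0.35, 0.3, 0.9, 0.85, 0.9),
                   missing = FALSE)
  bins <- new("BinAssignment",
              bins = setNames(factor(rep(c("low", "intermediate", "high"),
                                         each = 3),
                                     c("low", "intermediate", "high")),
                              gc$gene),
              boundaries = c(50, 200), medians = setNames(rep(1, 9), gc$gene))
  cmp <- compareBins(gc, bins)
  expect_equal(cmp$binStats$n, rep(3L, 3))
  expect_equal(cmp$binStats$meanRho[cmp$binStats$bin == "high"],
               mean(c(0.9, 0.85, 0.9)))
  expect_equal(nrow(cmp$tests), 3)
  lowHigh <- cmp$tests$p[cmp$tests$binA == "low" & cmp$tests$binB == "high"]
  expect_equal(lowHigh, 1 / 10, tolerance = 1e-9)

  gc$missing[1:3] <- TRUE  # an empty bin skips both of its comparisons
  warns <- capture_warnings(cmp2 <- compareBins(gc, bins))
  expect_match(warns, "skipped", all = TRUE)
  expect_length(warns, 2)
  expect_equal(cmp2$nMissing, 3L)
})
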