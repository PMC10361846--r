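# Detection thresholds, detection calls, geNorm ranking / selection, and
# housekeeping normalization.

negPanel <- function(neg, endo = NULL) {
  if (is.null(endo)) {
    endo <- matrix(50, 1, ncol(neg), dimnames = list("G1", colnames(neg)))
  }
  makePanel(endo = endo, neg = neg)
}

test_that("thresholds are mean + 2 sample SD of the negative controls", {
  neg <- cbind(S1 = c(0, 0, 0, 0), S2 = c(10, 10, 10, 10),
               S3 = c(4, 6, 8, 10))
  rownames(neg) <- paste0("N", 1:4)
  thr <- thresholds(detectionThresholds(negPanel(neg)))
  expect_equal(unname(thr["S1"]), 0, tolerance = 1e-12)
  expect_equal(unname(thr["S2"]), 10, tolerance = 1e-12)
  # mean 7, deviations (-3,-1,1,3), sample variance 20/3
  expect_equal(unname(thr["S3"]), 7 + 2 * sqrt(20 / 3), tolerance = 1e-9)
  expect_equal(unname(thr["S3"]), 12.164, tolerance = 1e-3)
})

test_that("a single negative probe is rejected", {
  neg <- matrix(c(1, 2), 1, dimnames = list("N1", c("S1", "S2")))
  expect_error(detectionThresholds(negPanel(neg)), "2 negative-control")
})

test_that("detection uses a strict comparison against the threshold", {
  neg <- matrix(rep(c(4, 6, 8, 10), 3), 4,
                dimnames = list(paste0("N", 1:4), c("S1", "S2", "S3")))
  thrVal <- 7 + 2 * sqrt(20 / 3)
  endo <- matrix(c(13, 13, 13,      # just above 12.16 -> detected
                   thrVal, 12, 12,  # equality / below -> undetected
                   0, 0, 0), 3, byrow = TRUE,
                 dimnames = list(c("HIGH", "EDGE", "ZERO"),
                                 c("S1", "S2", "S3")))
  # counts must be integral; use an exact-threshold variant with zeros
  endo["EDGE", ] <- c(12, 12, 12)
  mask <- detectionMask(detectPanel(negPanel(neg, endo),
                                    detectionThresholds(negPanel(neg, endo))))
  expect_true(all(mask["HIGH", ]))
  expect_false(any(mask["EDGE", ]))
  expect_false(any(mask["ZERO", ]))
  # equality at the threshold: zero negatives give threshold 0, count 0
  neg0 <- matrix(0, 4, 2, dimnames = list(paste0("N", 1:4), c("S1", "S2")))
  endo0 <- matrix(0, 1, 2, dimnames = list("Z", c("S1", "S2")))
  m0 <- detectionMask(detectPanel(negPanel(neg0, endo0),
                                  detectionThresholds(negPanel(neg0, endo0))))
  expect_false(any(m0))
})

test_that("detection matches a brute-force recomputation", {
  set.seed(21)
  for (i in 1:10) {
    panel <- randomPanel(nGenes = 15, nNeg = 5, nSamples = 4)
    got <- detectionMask(detectPanel(panel, detectionThresholds(panel)))
    expect_identical(got, bfDetect(probeCounts(panel, "Endogenous"),
                                   probeCounts(panel, "Negative")))
  }
})

geoToy <- function() {
  rbind(A = c(2, 4, 8, 16), B = c(1, 2, 4, 8), C = c(8, 4, 2, 1))
}

test_that("geNorm M values match the hand-computed toy", {
  gn <- genormRank(geoToy())
  # SD(log2(A/B)) = 0; SD(log2(A/C)) = SD(-2,0,2,4) = sqrt(20/3)
  s <- sqrt(20 / 3)
  expect_equal(unname(mValues(gn)[c("A", "B", "C")]),
               c(s / 2, s / 2, s), tolerance = 1e-9)
  expect_equal(gn@exclusionOrder[1], "C")
  expect_equal(gn@stabilityOrder, c("A", "B", "C"))
})

test_that("geNorm matches brute force and handles degenerate input", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(rpois(6 * 5, 200) + 1, 6,
                dimnames = list(paste0("H", 1:6), paste0("S", 1:5)))
    expect_equal(mValues(genormRank(m)), bfGenormM(m), tolerance = 1e-12)
  }
  # identical genes: all M = 0, alphabetical exclusion tie-break
  eq <- matrix(5, 3, 4, dimnames = list(c("B", "A", "C"), NULL))
  gn <- genormRank(eq)
  expect_equal(unname(mValues(gn)), rep(0, 3))
  expect_equal(gn@exclusionOrder[1], "A")
  expect_error(genormRank(rbind(eq[1:2, ], D = c(0, 1, 1, 1))), "positive")
  expect_error(genormRank(eq[1:2, ]), ">= 3")
})

test_that("selection takes the smallest n with V below the cutoff", {
  # two proportional genes plus independently noisy candidates
  set.seed(41)
  noise <- matrix(round(100 * 2^rnorm(3 * 6, 0, 1)) + 1, 3,
                  dimnames = list(c("X", "Y", "Z"), NULL))
  m <- rbind(A = c(100, 110, 95, 105, 90, 120), noise)
  m <- rbind(m, B = 2 * m["A", ])
  gn <- genormRank(m)
  sel <- genormSelect(gn, 0.15)
  v <- pairwiseVariation(gn)
  if (v[1] < 0.15) {
    expect_setequal(selectedGenes(sel), c("A", "B"))
  }
  # brute-force recomputation of V(2/3) from normalization-factor ratios
  top <- gn@stabilityOrder
  nf2 <- apply(m[top[1:2], ], 2, function(x) exp(mean(log(x))))
  nf3 <- apply(m[top[1:3], ], 2, function(x) exp(mean(log(x))))
  expect_equal(unname(v[1]), sd(log2(nf2 / nf3)), tolerance = 1e-12)

  # proportional everything: every V = 0, two genes selected
  prop <- rbind(A = c(1, 2, 4), B = c(2, 4, 8), C = c(4, 8, 16))
  selProp <- genormSelect(genormRank(prop), 0.15)
  expect_length(selectedGenes(selProp), 2)
  # unreachable cutoff: fallback to all candidates, flagged
  selAll <- suppressMessages(genormSelect(genormRank(m), 0))
  expect_true(selAll@fallback)
  expect_setequal(selectedGenes(selAll), rownames(m))
})

test_that("housekeeping normalization matches hand-computed scale factors", {
  neg <- matrix(c(1, 1, 2, 2), 2, dimnames = list(c("N1", "N2"), NULL))
  hk <- matrix(c(10, 20, 40, 30), 2, byrow = FALSE,
               dimnames = list(c("HKA", "HKB"), NULL))
  # sample 2 = 2 x sample 1 for every probe
  hk[, 2] <- 2 * hk[, 1]
  endo <- matrix(c(100, 200), 1, dimnames = list("G1", NULL))
  panel <- makePanel(endo = endo, hk = hk, neg = neg)
  # geometric means (g, 2g), across-sample mean 1.5 g -> factors (1.5, 0.75)
  np <- normalizePanel(panel, c("HKA", "HKB"))
  expect_equal(unname(scaleFactors(np)), c(1.5, 0.75), tolerance = 1e-12)
  v <- normValues(np)
  expect_equal(v[, 1], v[, 2], tolerance = 1e-12)

  # identical samples: both factors 1
  panelEq <- makePanel(endo = endo[, c(1, 1), drop = FALSE],
                       hk = hk[, c(1, 1)], neg = neg)
  expect_equal(unname(scaleFactors(normalizePanel(panelEq, c("HKA", "HKB")))),
               c(1, 1))

  # single housekeeping gene (10, 40): mean geometric mean 25
  panel1 <- makePanel(endo = endo,
                      hk = matrix(c(10, 40), 1, dimnames = list("HKA", NULL)),
                      neg = neg)
  expect_equal(unname(scaleFactors(normalizePanel(panel1, "HKA"))),
               c(2.5, 0.625), tolerance = 1e-12)
})

test_that("normalization preserves within-sample expression ratios", {
  set.seed(51)
  panel <- randomPanel(nGenes = 8, nNeg = 3, nSamples = 3)
  hk <- matrix(rpois(6, 500) + 1, 2,
               dimnames = list(c("HKA", "HKB"), colnames(panel)))
  full <- makePanel(endo = SummarizedExperiment::assay(panel)[1:8, ],
                    hk = hk, neg = probeCounts(panel, "Negative"))
  np <- normalizePanel(full, c("HKA", "HKB"))
  raw <- probeCounts(full, "Endogenous")
  v <- normValues(np)[rownames(raw), ]
  expect_equal(v[1, ] / v[2, ], raw[1, ] / raw[2, ], tolerance = 1e-12)
})

test_that("zero housekeeping counts and empty selections are rejected", {
  neg <- matrix(c(1, 1, 2, 2), 2, dimnames = list(c("N1", "N2"), NULL))
  hk <- matrix(c(10, 0, 40, 30), 2, dimnames = list(c("HKA", "HKB"), NULL))
  panel <- makePanel(endo = matrix(c(5, 5), 1, dimnames = list("G1", NULL)),
                     hk = hk, neg = neg)
  expect_error(normalizePanel(panel, c("HKA", "HKB")), "HKB")
  expect_error(normalizePanel(panel, character()), "non-empty")
})

test_that("positive-control normalization composes with housekeeping", {
  neg <- matrix(1, 2, 2, dimnames = list(c("N1", "N2"), NULL))
  pos <- matrix(c(100, 200), 1, dimnames = list("P1", NULL))
  hk <- matrix(c(30, 60), 1, dimnames = list("HKA", NULL))
  endo <- matrix(c(10, 20), 1, dimnames = list("G1", NULL))
  panel <- makePanel(endo = endo, hk = hk, neg = neg, pos = pos)
  np <- normalizePanel(panel, "HKA", posctrl = TRUE)
  # positive factors (1.5, 0.75) equalize the doubling; housekeeping then
  # sees identical samples and leaves them unchanged
  expect_equal(normValues(np)["G1", 1], normValues(np)["G1", 2],
               tolerance = 1e-12)
})
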