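# Candidate filtering, pairwise similarity, marker selection and abundance
# scoring.

maskFrom <- function(m, platform = "panel") {
  new("DetectionMask", mask = m, platform = platform)
}

test_that("prevalence filtering keeps genes detected in half the samples", {
  cands <- data.frame(cellType = c("T", "T", "T", "B", "B"),
                      gene = c("G1", "G2", "G3", "G4", "G5"))
  m <- rbind(G1 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),   # 3/6 kept
             G2 = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),  # 2/6 dropped
             G3 = rep(TRUE, 6),
             G4 = rep(FALSE, 6),
             G5 = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  colnames(m) <- paste0("S", 1:6)
  out <- filterCandidates(cands, maskFrom(m))
  expect_setequal(out$gene, c("G1", "G3"))
  expect_equal(attr(out, "dropped")$cellType, "B")
  expect_equal(attr(out, "dropped")$reason, "insufficient detection")
  # odd sample counts use the ceiling: 3 of 5 required
  out5 <- filterCandidates(cands, maskFrom(m[, 1:5]))
  expect_true("G1" %in% out5$gene)
  expect_false("G2" %in% out5$gene)
  expect_warning(filterCandidates(data.frame(cellType = "T", gene = "NOPE"),
                                  maskFrom(m)), "absent")
  expect_error(filterCandidates(cands[0, ], maskFrom(m)), "empty")
})

test_that("pairwise similarity is a correlation on the log scale", {
  set.seed(81)
  g <- 2^runif(6, 2, 9)
  v <- rbind(A = g, B = 2 * g + 1,  # exact doubling after the +1 shift
             C = 2^runif(6, 2, 9), D = rep(4, 6))
  colnames(v) <- paste0("S", 1:6)
  s <- pairwiseSimilarity(v, c("A", "B", "C", "D"))
  expect_equal(s["A", "B"], 1, tolerance = 1e-12)
  expect_true(isSymmetric(s))
  expect_equal(diag(s), setNames(rep(1, 4), rownames(v)))
  expect_true(all(is.na(s["D", c("A", "B", "C")])))  # constant gene
  # covariance-formula oracle
  la <- log2(v["A", ] + 1); lc <- log2(v["C", ] + 1)
  oracle <- sum((la - mean(la)) * (lc - mean(lc))) /
    sqrt(sum((la - mean(la))^2) * sum((lc - mean(lc))^2))
  expect_equal(s["A", "C"], oracle, tolerance = 1e-12)
  expect_error(pairwiseSimilarity(v, "A"), "2 genes")
  expect_error(pairwiseSimilarity(v[, 1:2], c("A", "B")), "3 samples")
})

test_that("marker selection requires a strictly qualifying pair", {
  set.seed(82)
  base <- 2^runif(6, 4, 8)
  v <- rbind(A = round(base * 2^rnorm(6, 0, 0.05)),
             B = round(base * 2^rnorm(6, 0, 0.05)),
             C = round(base * 2^rnorm(6, 0, 0.05)),
             X = round(2^runif(6, 4, 8)))
  colnames(v) <- paste0("S", 1:6)
  cands <- data.frame(cellType = rep("T", 4), gene = c("A", "B", "C", "X"))
  sel <- selectMarkers(cands, v, threshold = 0.6)
  expect_true(all(c("A", "B", "C") %in% markerGenes(sel)$T))

  # equality at the threshold does not qualify (strict >)
  s <- pairwiseSimilarity(v, c("A", "X"))
  two <- data.frame(cellType = c("P", "P"), gene = c("A", "X"))
  selEq <- selectMarkers(two, v, threshold = s["A", "X"])
  expect_length(markerGenes(selEq), 0)
  expect_equal(droppedCellTypes(selEq)$reason, "no qualifying pair")
})

test_that("selection is invariant to candidate and sample ordering", {
  set.seed(83)
  co <- simulateCohort(smallConfig(seed = 83))
  v <- log2p(probeCounts(co$panel, "Endogenous"))
  v <- 2^v  # any positive matrix will do
  cands <- co$candidates
  sel1 <- selectMarkers(cands, v)
  sel2 <- selectMarkers(cands[rev(seq_len(nrow(cands))), ],
                        v[, rev(seq_len(ncol(v)))])
  expect_equal(markerGenes(sel1), markerGenes(sel2)[names(markerGenes(sel1))])
})

test_that("raising the threshold never enlarges a selected set", {
  set.seed(84)
  co <- simulateCohort(smallConfig(seed = 84))
  v <- probeCounts(co$panel, "Endogenous")
  sel <- lapply(c(0.3, 0.6, 0.9), function(th)
    markerGenes(selectMarkers(co$candidates, v, threshold = th)))
  for (i in 2:3) {
    for (ct in names(sel[[i]])) {
      expect_true(all(sel[[i]][[ct]] %in% sel[[i - 1]][[ct]]))
    }
  }
})

test_that("abundance is the mean transformed marker expression", {
  v <- rbind(A = c(3, 15), B = c(15, 3))
  colnames(v) <- c("S1", "S2")
  sel <- new("SelectedMarkers", markers = list(T = c("A", "B")),
             bestSimilarity = list(T = c(A = 1, B = 1)),
             dropped = data.frame(), method = "pearson")
  ab <- scoreAbundance(sel, v)
  expect_equal(unname(abundanceScores(ab)["T", ]), c(3, 3))  # (2 + 4) / 2
  one <- new("SelectedMarkers", markers = list(T = "A"),
             bestSimilarity = list(T = c(A = 1)),
             dropped = data.frame(), method = "pearson")
  expect_equal(unname(abundanceScores(scoreAbundance(one, v))["T", ]),
               unname(log2(v["A", ] + 1)))
  expect_error(scoreAbundance(sel, v[1, , drop = FALSE]), "B")
})

test_that("abundance shifts by c/|markers| when one marker shifts by c", {
  set.seed(85)
  v <- matrix(2^runif(12, 2, 8), 3, 4,
              dimnames = list(c("A", "B", "C"), paste0("S", 1:4)))
  sel <- new("SelectedMarkers", markers = list(T = c("A", "B", "C")),
             bestSimilarity = list(), dropped = data.frame(),
             method = "pearson")
  before <- abundanceScores(scoreAbundance(sel, v))
  shifted <- v
  shifted["B", ] <- 2^(log2(v["B", ] + 1) + 1.5) - 1  # +1.5 on the log scale
  after <- abundanceScores(scoreAbundance(sel, shifted))
  expect_equal(unname(after["T", ] - before["T", ]), rep(1.5 / 3, 4),
               tolerance = 1e-9)
})

test_that("fixed signatures score like selected markers and drop absences", {
  set.seed(86)
  v <- matrix(2^runif(20, 2, 8), 5, 4,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
  sel <- new("SelectedMarkers", markers = list(T = c("G1", "G2")),
             bestSimilarity = list(), dropped = data.frame(),
             method = "pearson")
  sig <- list(T = c("G1", "G2"))
  expect_equal(abundanceScores(signatureScore(sig, v)),
               abundanceScores(scoreAbundance(sel, v)))
  warns <- capture_warnings(ss <- signatureScore(list(T = c("G1", "NOPE"),
                                                      Z = "MISSING"), v))
  expect_match(warns, "dropped", all = TRUE)
  expect_length(warns, 2)
  expect_equal(rownames(abundanceScores(ss)), "T")
  expect_error(signatureScore(list(), v), "empty")
})

test_that("planted markers recover the infiltration ranking", {
  co <- simulateCohort(smallConfig(seed = 87))
  v <- probeCounts(co$panel, "Endogenous")
  sel <- new("SelectedMarkers", markers = co$truth@plantedMarkers,
             bestSimilarity = list(), dropped = data.frame(),
             method = "pearson")
  ab <- abundanceScores(scoreAbundance(sel, v))
  rho <- vapply(rownames(ab), function(ct)
    cor(ab[ct, ], co$truth@infiltration[ct, ], method = "spearman"),
    numeric(1))
  expect_gt(median(rho), 0.8)
})
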