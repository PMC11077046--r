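# build a tiny aligned table with a given value column
valueTable <- function(values, col = "v", gene = "g") {
  n <- length(values)
  dt <- data.table(chrom = "chr1", gencoor = seq_len(n), strand = "+",
                   gene = gene, txcoor = seq_len(n),
                   cov = 10L, start_5p = 0L, end_3p = 0L)
  dt[, (col) := values]
  dt
}

test_that("unification restricts to the gene intersection in stable order", {
  tAB <- rbind(valueTable(1:3, gene = "A"), valueTable(4:6, gene = "B"))
  tBC <- rbind(valueTable(7:9, gene = "B"), valueTable(1:3, gene = "C"))
  u <- unifyTxTables(list(tAB, tBC))
  expect_identical(unique(u[[1]]$gene), "B")
  expect_identical(unique(u[[2]]$gene), "B")
  expect_identical(u[[1]]$txcoor, u[[2]]$txcoor)

  same <- unifyTxTables(list(tAB, copy(tAB)))
  expect_identical(as.data.frame(same[[1]]), as.data.frame(tAB))

  expect_warning(u0 <- unifyTxTables(list(valueTable(1:3, gene = "A"),
                                          valueTable(1:3, gene = "Z"))),
                 "no genes")
  expect_identical(nrow(u0[[1]]), 0L)

  short <- rbind(valueTable(1:2, gene = "B"))
  expect_error(unifyTxTables(list(tAB[gene == "B"], short)),
               "length differs")
})

test_that("flank extraction pads windows at transcript edges", {
  t <- valueTable(as.numeric(1:10))
  t[, hit := txcoor %in% c(2L, 5L)]
  fm <- getFlanksFromLogical(t, "hit", "v", w = 2L)
  expect_identical(dim(fm), c(2L, 5L))
  expect_equal(unname(fm[1, ]), c(NA, 1, 2, 3, 4))
  expect_equal(unname(fm[2, ]), c(3, 4, 5, 6, 7))
  t2 <- copy(t)[, hit := FALSE]
  expect_identical(nrow(getFlanksFromLogical(t2, "hit", "v", 2L)), 0L)
})

test_that("metagene bins aggregate each gene's own regions", {
  m <- singleExonCdsModel("+", geneId = "g")
  t <- valueTable(as.numeric(1:100))
  mg <- getMetageneRegions(t, "v", bins = c(2L, 2L, 2L), aggregate = "mean",
                           models = list(m))
  expect_equal(unname(mg[1, ]), c(5.5, 15.5, 35.5, 65.5, 85.5, 95.5))

  # logical value + sum gives per-bin site counts
  t[, site := txcoor %in% c(5L, 15L, 95L)]
  mgs <- getMetageneRegions(t, "site", bins = c(2L, 2L, 2L),
                            aggregate = "sum", models = list(m))
  expect_equal(unname(mgs[1, ]), c(1, 1, 0, 0, 0, 1))

  # region shorter than its bin count: trailing bins are missing
  tiny <- TranscriptModel("g", "chr1", "+", IRanges(1L, 10L),
                          cds = IRanges(2L, 9L))
  t10 <- valueTable(as.numeric(1:10))
  mg10 <- getMetageneRegions(t10, "v", bins = c(2L, 2L, 2L),
                             aggregate = "mean", models = list(tiny))
  expect_equal(unname(mg10[1, 1:2]), c(1, NA))

  # noncoding genes are skipped
  nc <- TranscriptModel("g", "chr1", "+", IRanges(1L, 100L))
  expect_identical(nrow(getMetageneRegions(t, "v", bins = c(2L, 2L, 2L),
                                           models = list(nc))), 0L)
})

test_that("position frequency matrices count flank bases per offset", {
  t <- rbind(valueTable(1:4, gene = "g1"), valueTable(1:4, gene = "g2"))
  t[, refSeq := c("A", "C", "G", "T", "A", "C", "T", "A")]
  sites <- data.table(gene = c("g1", "g2"), txcoor = c(2L, 2L))
  pfm <- pfmFromSites(t, sites, w = 1L)
  expect_identical(pfm["A", "-1"], 2L)
  expect_identical(pfm["C", "0"], 2L)
  expect_identical(pfm["G", "1"], 1L)
  expect_identical(pfm["T", "1"], 1L)
  expect_equal(unname(colSums(pfm)), c(2, 2, 2))

  one <- pfmFromSites(t, sites[1L], w = 1L)
  expect_equal(unname(colSums(one)), c(1, 1, 1))
  expect_true(all(one %in% c(0L, 1L)))
})

test_that("row t-tests match the closed-form pooled and Welch oracles", {
  g1 <- lapply(c(0.8, 0.7, 0.9), valueTable, col = "v")
  g2 <- lapply(c(0.1, 0.2, 0.0), valueTable, col = "v")
  r <- rowTtests(g1, g2, "v", variance = "pooled")
  expect_equal(r$meanDiff[1], 0.7)
  expect_equal(r$statistic[1], 0.7 / sqrt(0.01 * (2 / 3)), tolerance = 1e-10)
  expect_equal(r$statistic[1], 8.5732141, tolerance = 1e-6)
  expect_identical(r$df[1], 4)

  # against stats::t.test on random data, both variance models
  set.seed(31)
  x <- matrix(rnorm(300), ncol = 3)
  y <- matrix(rnorm(400, mean = 0.2), ncol = 4)
  gx <- lapply(1:3, function(j) valueTable(x[, j], col = "v"))
  gy <- lapply(1:4, function(j) valueTable(y[, j], col = "v"))
  for (variance in c("pooled", "welch")) {
    rr <- rowTtests(gx, gy, "v", variance = variance)
    for (i in c(1L, 17L, 100L)) {
      o <- t.test(x[i, ], y[i, ], var.equal = variance == "pooled")
      expect_equal(rr$statistic[i], unname(o$statistic), tolerance = 1e-10)
      expect_equal(rr$p[i], o$p.value, tolerance = 1e-10)
      expect_equal(rr$df[i], unname(o$parameter), tolerance = 1e-10)
    }
  }

  # identical groups: t = 0, p = 1; degenerate variance: +/-Inf, p = 0
  same <- rowTtests(gx, gx, "v")
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p == 1))
  cg1 <- lapply(c(1, 1), valueTable, col = "v")
  cg2 <- lapply(c(0, 0), valueTable, col = "v")
  deg <- rowTtests(cg1, cg2, "v")
  expect_true(all(is.infinite(deg$statistic)))
  expect_true(all(deg$p == 0))
  expect_error(rowTtests(gx[1], gx, "v"), "at least 2")

  # missing replicate values give missing results
  gm <- lapply(c(0.5, NA, 0.6), valueTable, col = "v")
  rmiss <- rowTtests(gm, g2, "v")
  expect_true(all(is.na(rmiss$statistic)))
})

test_that("binomial LRT matches the log-likelihood oracle", {
  lrtOracle <- function(k1, n1, k2, n2) {
    p1 <- k1 / n1; p2 <- k2 / n2; p0 <- (k1 + k2) / (n1 + n2)
    2 * (dbinom(k1, n1, p1, log = TRUE) + dbinom(k2, n2, p2, log = TRUE) -
           dbinom(k1, n1, p0, log = TRUE) - dbinom(k2, n2, p0, log = TRUE))
  }
  mk <- function(k, n) {
    dt <- valueTable(as.integer(k), col = "k")
    set(dt, j = "n", value = as.integer(n))
    dt
  }
  g1 <- list(mk(80, 100))
  g2 <- list(mk(5, 100))
  r <- rowBinomialLRT(g1, g2, "k", "n")
  expect_equal(r$statistic[1], lrtOracle(80, 100, 5, 100), tolerance = 1e-8)
  expect_gt(r$statistic[1], 130)
  expect_lt(r$statistic[1], 135)

  # equal proportions: statistic 0
  expect_equal(rowBinomialLRT(list(mk(10, 50)), list(mk(20, 100)),
                              "k", "n")$statistic[1], 0)
  # boundary proportions stay finite
  rb <- rowBinomialLRT(list(mk(1000, 1000)), list(mk(0, 1000)), "k", "n")
  expect_true(is.finite(rb$statistic[1]))
  expect_gt(rb$statistic[1], 1000)
  # zero trials: missing
  expect_true(is.na(rowBinomialLRT(list(mk(0, 0)), list(mk(5, 10)),
                                   "k", "n")$statistic[1]))
  # random battery against the oracle
  set.seed(77)
  ks <- cbind(rbinom(200, 50, 0.3), rbinom(200, 80, 0.35))
  r2 <- rowBinomialLRT(list(valueTable(ks[, 1], col = "k")[, n := 50L]),
                       list(valueTable(ks[, 2], col = "k")[, n := 80L]),
                       "k", "n")
  expect_equal(r2$statistic,
               mapply(lrtOracle, ks[, 1], 50, ks[, 2], 80),
               tolerance = 1e-8)
  expect_true(all(r2$statistic >= 0))
})

test_that("peak calling finds, thresholds and merges local maxima", {
  t <- valueTable(c(0, 1, 5, 9, 5, 1, 0, 0), col = "cov2")
  pk <- callPeaks(t, covCol = "cov2", smoothW = 1L, minCov = 2, minGap = 3L)
  expect_identical(pk$txcoor, 4L)
  expect_equal(pk$height, 9)

  flat <- valueTable(rep(3, 20), col = "cov2")
  expect_identical(nrow(callPeaks(flat, "cov2", 1L, 1, 3L)), 0L)

  # two maxima closer than minGap merge keeping the higher
  bi <- valueTable(c(0, 5, 0, 7, 0), col = "cov2")
  pk2 <- callPeaks(bi, "cov2", 1L, 1, 5L)
  expect_identical(pk2$txcoor, 4L)
  pk3 <- callPeaks(bi, "cov2", 1L, 1, 2L)
  expect_identical(pk3$txcoor, c(2L, 4L))
  # equal heights: leftmost wins the merge
  tie <- valueTable(c(0, 6, 0, 6, 0), col = "cov2")
  expect_identical(callPeaks(tie, "cov2", 1L, 1, 5L)$txcoor, 2L)
})

test_that("gene subsampling is deterministic under a seed", {
  t <- rbindlist(lapply(sprintf("g%02d", 1:10), function(g)
    valueTable(1:5, gene = g)))
  s1 <- sampleGenes(t, 3L, seed = 99L)
  s2 <- sampleGenes(t, 3L, seed = 99L)
  expect_identical(s1, s2)
  expect_identical(length(unique(s1$gene)), 3L)
  expect_identical(nrow(sampleGenes(t, 0L)), 0L)
  all10 <- sampleGenes(t, 10L, seed = 1L)
  expect_setequal(unique(all10$gene), unique(t$gene))
  expect_error(sampleGenes(t, 11L), "exceeds")
})
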