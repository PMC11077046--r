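test_that("alignment loading excludes unmapped mates and keeps pairing", {
  sam <- samFixture(c(
    samLine("p1", 99L, "chr1", 101L, "10M", strrep("A", 10),
            rnext = "=", pnext = 131L),
    samLine("p1", 147L, "chr1", 131L, "10M", strrep("A", 10),
            rnext = "=", pnext = 101L),
    samLine("p2", 99L, "chr1", 201L, "10M", strrep("C", 10),
            rnext = "=", pnext = 231L),
    samLine("p2", 147L, "chr1", 231L, "10M", strrep("C", 10),
            rnext = "=", pnext = 201L),
    # mate unmapped: only the mapped record survives
    samLine("h1", 73L, "chr1", 141L, "10M", strrep("G", 10))
  ))
  al <- loadAlignments(sam)
  expect_identical(nrow(al), 5L)
  expect_identical(nrow(al["p1"]), 2L)
  expect_true(all(c("qname", "chrom", "strand", "pos", "cigar", "seq",
                    "isRead1", "isRead2") %in% names(al)))

  empty <- samFixture(character(0))
  expect_identical(nrow(loadAlignments(empty)), 0L)
})

test_that("loading can be restricted to one chromosome", {
  sam <- samFixture(c(
    samLine("r1", 0L, "chr1", 101L, "10M", strrep("A", 10)),
    samLine("r2", 0L, "chr2", 51L, "10M", strrep("C", 10))
  ), sq = c(chr1 = 1000L, chr2 = 1000L))
  expect_identical(loadAlignments(sam, region = "chr2")$qname, "r2")
  expect_error(loadAlignments(sam, region = "chrX"), "not in BAM header")
})

test_that("segment conversion requires exon containment and exact junctions", {
  m <- twoExonModel("+")
  r <- segmentToTx(m, 101L, "10M", "ACGTACGTAC")
  expect_identical(r$txStart, 1L)
  expect_identical(r$txEnd, 10L)
  expect_identical(r$calls$pos, 1:10)
  expect_identical(paste(r$calls$base, collapse = ""), "ACGTACGTAC")

  # junction read: 50M over exon1, 50N over the intron, 10M into exon2
  jseq <- strrep("A", 60)
  j <- segmentToTx(m, 101L, "50M50N10M", jseq)
  expect_identical(c(j$txStart, j$txEnd), c(1L, 60L))
  expect_identical(j$calls$pos, 1:60)

  # mismatched junction is filtered, not an error
  expect_null(segmentToTx(m, 101L, "50M40N10M", jseq))
  # read sticking into the intron
  expect_null(segmentToTx(m, 146L, "10M", strrep("A", 10)))

  # soft clips contribute nothing
  s <- segmentToTx(m, 101L, "5S10M", "TTTTTACGTACGTAC")
  expect_identical(s$calls$base, strsplit("ACGTACGTAC", "")[[1]])
  expect_identical(c(s$txStart, s$txEnd), c(1L, 10L))
})

test_that("deletions occupy reference positions and insertions vanish", {
  m <- twoExonModel("+")
  d <- segmentToTx(m, 101L, "4M2D4M", "ACGTACGT")
  expect_identical(d$calls$pos, 1:10)
  expect_identical(d$calls$base, c("A", "C", "G", "T", "-", "-",
                                   "A", "C", "G", "T"))
  i <- segmentToTx(m, 101L, "4M2I4M", "ACGTTTACGT")
  expect_identical(i$calls$pos, 1:8)
  expect_identical(i$calls$base, c("A", "C", "G", "T", "A", "C", "G", "T"))
})

test_that("minus-strand models complement calls into transcript orientation", {
  m <- twoExonModel("-")
  # genomic 251..260 = transcript 1..10 on the minus strand
  r <- segmentToTx(m, 251L, "10M", "ACGTACGTAC")
  expect_identical(c(r$txStart, r$txEnd), c(1L, 10L))
  # transcript pos 1 is genomic 260 -> complement of 'C' (last base)
  expect_identical(r$calls$base[1], "G")
  expect_identical(r$calls$base,
                   rev(strsplit(chartr("ACGT", "TGCA", "ACGTACGTAC"),
                                "")[[1]]))
})

test_that("mate merging bridges the insert and flags disagreements as N", {
  m <- twoExonModel("+")
  a <- list(txStart = 1L, txEnd = 40L,
            calls = data.table(pos = 1:40, base = rep("A", 40)))
  b <- list(txStart = 71L, txEnd = 110L,
            calls = data.table(pos = 71:110, base = rep("C", 40)))
  fr <- txpileup:::.mergeMates(a, b, 1000L)
  expect_identical(c(fr$txStart, fr$txEnd), c(1L, 110L))
  expect_identical(nrow(fr$calls), 80L)           # gap 41..70 has no calls
  expect_false(any(fr$calls$pos %in% 41:70))

  # overlapping and agreeing: one call per position
  b2 <- list(txStart = 21L, txEnd = 60L,
             calls = data.table(pos = 21:60, base = rep("A", 40)))
  fr2 <- txpileup:::.mergeMates(a, b2, 1000L)
  expect_identical(nrow(fr2$calls), 60L)
  expect_true(all(fr2$calls$base == "A"))

  # disagreement at position 30 -> N
  b3 <- list(txStart = 21L, txEnd = 60L,
             calls = data.table(pos = 21:60,
                                base = c(rep("A", 9), "G", rep("A", 30))))
  fr3 <- txpileup:::.mergeMates(a, b3, 1000L)
  expect_identical(fr3$calls[pos == 30L, base], "N")
  expect_true(all(fr3$calls[pos != 30L, base] == "A"))

  # span limit
  expect_null(txpileup:::.mergeMates(a, b, 100L))
})

test_that("fragmentFromPair enforces strand mode", {
  m <- twoExonModel("+")
  seg1 <- data.table(qname = "p", chrom = "chr1", strand = "+", pos = 101L,
                     cigar = "10M", seq = strrep("A", 10))
  seg2 <- data.table(qname = "p", chrom = "chr1", strand = "-", pos = 131L,
                     cigar = "10M", seq = strrep("A", 10))
  fr <- fragmentFromPair(m, seg1, seg2)
  expect_identical(c(fr$txStart, fr$txEnd), c(1L, 40L))
  # antisense read1 under strand_mode same
  seg1m <- copy(seg1)[, strand := "-"]
  expect_null(fragmentFromPair(m, seg1m, seg2))
  expect_false(is.null(fragmentFromPair(
    m, seg1m, seg2, conversionOptions(strandMode = "opposite"))))
  expect_false(is.null(fragmentFromPair(
    m, seg1m, seg2, conversionOptions(strandMode = "ignore"))))
})

test_that("assignment emits one fragment per compatible isoform", {
  iso1 <- twoExonModel("+", geneId = "iso1")
  iso2 <- TranscriptModel("iso2", "chr1", "+", IRanges(101L, 260L))
  fl <- pairFlags("+")
  sam <- samFixture(c(
    samLine("p1", fl[1], "chr1", 101L, "10M", strrep("A", 10),
            rnext = "=", pnext = 121L),
    samLine("p1", fl[2], "chr1", 121L, "10M", strrep("A", 10),
            rnext = "=", pnext = 101L)
  ))
  asg <- assignToTranscripts(loadAlignments(sam), list(iso1, iso2))
  expect_identical(sort(names(asg$fragments)), c("iso1", "iso2"))
  expect_identical(length(asg$fragments$iso1), 1L)
  expect_identical(length(asg$fragments$iso2), 1L)
  expect_identical(unname(asg$discards["assignedGroups"]), 1L)
})

test_that("discard report classifies strand, structure, span and half pairs", {
  m <- twoExonModel("+")
  # antisense pair
  flm <- pairFlags("-")
  antisense <- samFixture(c(
    samLine("a1", flm[1], "chr1", 101L, "10M", strrep("A", 10),
            rnext = "=", pnext = 121L),
    samLine("a1", flm[2], "chr1", 121L, "10M", strrep("A", 10),
            rnext = "=", pnext = 101L)
  ))
  asg <- assignToTranscripts(loadAlignments(antisense), list(m))
  expect_identical(unname(asg$discards["strand"]), 1L)
  expect_length(asg$fragments, 0L)

  # junction-incompatible pair (read1 crosses intron without N)
  fl <- pairFlags("+")
  badj <- samFixture(c(
    samLine("b1", fl[1], "chr1", 146L, "10M", strrep("A", 10),
            rnext = "=", pnext = 201L),
    samLine("b1", fl[2], "chr1", 201L, "10M", strrep("A", 10),
            rnext = "=", pnext = 146L)
  ))
  asg2 <- assignToTranscripts(loadAlignments(badj), list(m))
  expect_identical(unname(asg2$discards["structure"]), 1L)

  # span too long for maxFragment
  farApart <- samFixture(c(
    samLine("c1", fl[1], "chr1", 101L, "10M", strrep("A", 10),
            rnext = "=", pnext = 251L),
    samLine("c1", fl[2], "chr1", 251L, "10M", strrep("A", 10),
            rnext = "=", pnext = 101L)
  ))
  asg3 <- assignToTranscripts(loadAlignments(farApart), list(m),
                              conversionOptions(maxFragment = 50L))
  expect_identical(unname(asg3$discards["span"]), 1L)

  # half pair: only one mapped mate in paired mode
  half <- samFixture(samLine("h1", 73L, "chr1", 101L, "10M", strrep("A", 10)))
  asg4 <- assignToTranscripts(loadAlignments(half), list(m))
  expect_identical(unname(asg4$discards["halfPair"]), 1L)

  expect_error(assignToTranscripts(loadAlignments(half), list()), "empty")
})

test_that("simulated libraries reconstruct the truth spans exactly", {
  fx <- simFixture(seed = 5L, nGenes = 3L, fragmentsPerGene = 50L)
  asg <- assignToTranscripts(loadAlignments(fx$sam), fx$models,
                             conversionOptions(maxFragment = 400L))
  total <- sum(vapply(asg$fragments, length, integer(1)))
  expect_identical(total, nrow(fx$truth))
  expect_identical(unname(asg$discards["assignedGroups"]), nrow(fx$truth))
  for (g in names(asg$fragments)) {
    got <- fragmentSpans(asg$fragments[[g]])
    want <- fx$truth[gene == g]
    expect_identical(sort(got$txStart), sort(want$txStart))
    expect_identical(sort(got$txEnd), sort(want$txEnd))
    validObject(asg$fragments[[g]])
  }
})

test_that("single-end processing matches paired base counts when mates never overlap", {
  fx <- simFixture(seed = 6L, nGenes = 2L, fragmentsPerGene = 80L,
                   fragMin = 100L)  # fragMin >= 2 * readLength: no overlap
  al <- loadAlignments(fx$sam)
  paired <- assignToTranscripts(al, fx$models,
                                conversionOptions(maxFragment = 400L),
                                paired = TRUE)
  single <- assignToTranscripts(al, fx$models,
                                conversionOptions(maxFragment = 400L,
                                                  strandMode = "ignore"),
                                paired = FALSE)
  tabP <- makeTxTable(paired$fragments, fx$models, genome = fx$genome,
                      mode = "nucFreq")
  tabS <- makeTxTable(single$fragments, fx$models, genome = fx$genome,
                      mode = "nucFreq")
  for (col in c("A", "C", "G", "T", "N", "del"))
    expect_identical(tabP[[col]], tabS[[col]])
})
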