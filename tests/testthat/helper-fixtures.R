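library(data.table)
library(IRanges)
library(Biostrings)

# two-exon model used throughout: exons (101-150, 201-260) 1-based,
# i.e. BED blocks (100,150) and (200,260); tx length 110
twoExonModel <- function(strand = "+", geneId = "geneA", cds = NULL) {
  TranscriptModel(geneId, "chr1", strand,
                  IRanges(start = c(101L, 201L), end = c(150L, 260L)),
                  cds = cds)
}

# single-exon model on a 100-nt chromosome with CDS at BED (20, 80)
singleExonCdsModel <- function(strand = "+", geneId = "geneB") {
  TranscriptModel(geneId, "chr1", strand, IRanges(1L, 100L),
                  cds = IRanges(21L, 80L))
}

randomGenome <- function(chroms = c(chr1 = 1000L), seed = 42L) {
  set.seed(seed)
  DNAStringSet(vapply(chroms, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
}

# write a SAM file from raw alignment line fields
samFixture <- function(lines, sq = c(chr1 = 1000L),
                       path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, lines), path)
  path
}

samLine <- function(qname, flag, chrom, pos, cigar, seq,
                    rnext = "*", pnext = 0L, tlen = 0L, mapq = 60L) {
  qual <- if (identical(seq, "*")) "*" else strrep("I", nchar(seq))
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
          qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen, seq, qual)
}

# flags for a proper FR pair: read1 on `strand1`, read2 opposite
pairFlags <- function(strand1 = "+") {
  if (strand1 == "+") c(99L, 147L) else c(83L, 163L)
}

# independent per-position oracle: for every transcript position scan
# every fragment of the gene
bruteForcePileup <- function(fragments, L) {
  spans <- fragmentSpans(fragments)
  calls <- fragmentCalls(fragments)
  setkey(calls, pos)
  out <- data.table(txcoor = seq_len(L), cov = 0L, start_5p = 0L,
                    end_3p = 0L, A = 0L, C = 0L, G = 0L, T = 0L,
                    N = 0L, del = 0L)
  for (i in seq_len(L)) {
    out$cov[i] <- sum(spans$txStart <= i & spans$txEnd >= i)
    out$start_5p[i] <- sum(spans$txStart == i)
    out$end_3p[i] <- sum(spans$txEnd == i)
    b <- calls[.(i), base, nomatch = NULL]
    if (length(b)) {
      out$A[i] <- sum(b == "A"); out$C[i] <- sum(b == "C")
      out$G[i] <- sum(b == "G"); out$T[i] <- sum(b == "T")
      out$N[i] <- sum(b == "N"); out$del[i] <- sum(b == "-")
    }
  }
  out
}

# simulate genome + annotation + paired SAM in one call
simFixture <- function(seed = 11L, nGenes = 3L, fragmentsPerGene = 100L,
                       modSites = list(), errorRate = 0, paired = TRUE,
                       readLength = 40L, fragMean = 150, fragSd = 20,
                       fragMin = 100L, fragMax = 300L, exonsPerGene = c(1L, 3L),
                       ipSites = NULL, chromLength = 50000L) {
  cfg <- simConfig(seed = seed, nGenes = nGenes, chromLength = chromLength,
                   fragmentsPerGene = fragmentsPerGene,
                   errorRate = errorRate, readLength = readLength,
                   fragMean = fragMean, fragSd = fragSd, fragMin = fragMin,
                   fragMax = fragMax, exonsPerGene = exonsPerGene)
  genome <- makeGenome(cfg)
  models <- makeAnnotation(genome, cfg)
  sam <- tempfile(fileext = ".sam")
  truth <- simulateLibrary(models, genome, cfg, modSites = modSites,
                           ipSites = ipSites, paired = paired,
                           samPath = sam)
  list(cfg = cfg, genome = genome, models = models, sam = sam,
       truth = truth)
}
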