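#' Configuration for the synthetic-data simulator
#'
#' Declarative description of a synthetic genome, annotation and
#' paired-end read library. The defaults emulate a small multi-chromosome
#' genome with multi-exon genes on both strands and a short-fragment
#' paired-end sequencing library (40-nt mates, ~150-nt inserts), the
#' regime in which mate bridging matters.
#'
#' @param seed integer master seed; all simulator stages derive their RNG
#'   streams from it and restore the caller's RNG state afterwards.
#' @param nChroms,chromLength number and length (nt) of chromosomes.
#' @param nGenes number of genes to place (non-overlapping).
#' @param exonsPerGene integer range `c(min, max)` of exons per gene.
#' @param exonLength,intronLength integer ranges (nt) for exon and intron
#'   widths.
#' @param strandProb probability a gene is on the plus strand.
#' @param fragMean,fragSd,fragMin,fragMax fragment-length distribution:
#'   normal, rounded, clipped to `[fragMin, fragMax]` and to the
#'   transcript length.
#' @param readLength sequenced mate length (nt).
#' @param fragmentsPerGene fragments simulated per gene.
#' @param errorRate per-base sequencing error probability, applied after
#'   modification effects.
#' @return a `SimConfig` list.
#' @export
simConfig <- function(seed = 1L, nChroms = 2L, chromLength = 100000L,
                      nGenes = 10L, exonsPerGene = c(1L, 3L),
                      exonLength = c(100L, 400L), intronLength = c(50L, 200L),
                      strandProb = 0.5, fragMean = 150, fragSd = 20,
                      fragMin = 100L, fragMax = 300L, readLength = 40L,
                      fragmentsPerGene = 1000L, errorRate = 0.001) {
  stopifnot(nChroms >= 1L, chromLength >= 1L, nGenes >= 1L,
            length(exonsPerGene) == 2L, exonsPerGene[1] >= 1L,
            exonsPerGene[1] <= exonsPerGene[2],
            exonLength[1] >= 1L, intronLength[1] >= 1L,
            fragMin >= 1L, fragMax >= fragMin, readLength >= 1L,
            readLength <= fragMax, fragmentsPerGene >= 0L,
            errorRate >= 0, errorRate <= 1, strandProb >= 0, strandProb <= 1)
  structure(as.list(environment()), class = "SimConfig")
}

#' Specify an injected modification effect at one transcript site
#'
#' Declares the effect a (simulated) RNA modification has on sequencing
#' fragments:
#' \describe{
#'   \item{`rt_stop`}{with probability `prob`, a fragment overlapping the
#'     site is truncated so its 5' end becomes `txPos + 1` — the read-start
#'     pileup one nucleotide downstream produced by reverse-transcription
#'     blocks (CMC-marked pseudouridine, miCLIP-style crosslinks).}
#'   \item{`misinc`}{with probability `prob`, a fragment sequencing the
#'     site carries `toBase` instead of the reference `fromBase`
#'     (ac4C-seq style C-to-T conversion).}
#'   \item{`cleavage`}{with probability `prob`, a fragment spanning the
#'     site is split into two fragments ending at `txPos` and starting at
#'     `txPos + 1`.}
#' }
#'
#' @param gene gene id (must match a simulated model).
#' @param txPos 1-based transcript position of the modified base.
#' @param effect `"rt_stop"`, `"misinc"` or `"cleavage"`.
#' @param prob effect probability per fragment, in `[0, 1]`.
#' @param fromBase,toBase for `misinc`: the reference base at the site
#'   (checked against the transcript sequence) and the substituted base.
#' @return a `ModSiteSpec` list.
#' @export
modSite <- function(gene, txPos, effect = c("rt_stop", "misinc", "cleavage"),
                    prob, fromBase = NULL, toBase = NULL) {
  effect <- match.arg(effect)
  stopifnot(prob >= 0, prob <= 1, txPos >= 1L)
  if (effect == "misinc") {
    stopifnot(!is.null(fromBase), !is.null(toBase))
    if (fromBase == toBase) stop("misinc fromBase and toBase must differ")
  }
  structure(list(gene = gene, txPos = as.integer(txPos), effect = effect,
                 prob = prob, fromBase = fromBase, toBase = toBase),
            class = "ModSiteSpec")
}

#' Simulate a random genome
#'
#' Uniform random A/C/G/T sequences, deterministic under the config seed.
#'
#' @param config a [simConfig()] object.
#' @param fastaPath optional path to also write the genome as FASTA.
#' @return a [Biostrings::DNAStringSet] named `chr1..chrN`.
#' @export
makeGenome <- function(config, fastaPath = NULL) {
  genome <- .withSeed(config$seed + 101L, {
    seqs <- vapply(seq_len(config$nChroms), function(i)
      paste(sample(c("A", "C", "G", "T"), config$chromLength,
                   replace = TRUE), collapse = ""), character(1))
    DNAStringSet(setNames(seqs, paste0("chr", seq_len(config$nChroms))))
  })
  if (!is.null(fastaPath)) writeXStringSet(genome, fastaPath)
  genome
}

#' Simulate a transcriptome annotation
#'
#' Places non-overlapping genes on both strands with the configured exon
#' and intron structure, assigning a CDS with non-empty UTRs whenever the
#' transcript is long enough (>= 90 nt). The BED12 written (if requested)
#' round-trips through [loadBed()].
#'
#' @param genome a [Biostrings::DNAStringSet] from [makeGenome()].
#' @param config a [simConfig()] object.
#' @param bedPath optional path to also write the annotation as BED12.
#' @return named list of [TranscriptModel-class].
#' @export
makeAnnotation <- function(genome, config, bedPath = NULL) {
  models <- .withSeed(config$seed + 202L, {
    chromNames <- names(genome)
    cursors <- setNames(rep(100L, length(chromNames)), chromNames)
    out <- vector("list", config$nGenes)
    for (i in seq_len(config$nGenes)) {
      nEx <- sample(config$exonsPerGene[1]:config$exonsPerGene[2], 1L)
      widths <- sample(config$exonLength[1]:config$exonLength[2], nEx,
                       replace = TRUE)
      introns <- if (nEx > 1L)
        sample(config$intronLength[1]:config$intronLength[2], nEx - 1L,
               replace = TRUE) else integer(0)
      span <- sum(widths) + sum(introns)
      gap <- sample(50:300, 1L)
      placed <- FALSE
      for (ch in chromNames[order(cursors)]) {
        s0 <- cursors[[ch]] + gap
        if (s0 + span - 1L <= length(genome[[ch]]) - 10L) {
          starts <- s0 + c(0L, cumsum(widths[-nEx] + introns))
          exons <- IRanges(starts, starts + widths - 1L)
          strand <- if (runif(1) < config$strandProb) "+" else "-"
          m <- TranscriptModel(sprintf("gene%03d", i), ch, strand, exons)
          L <- txLength(m)
          if (L >= 90L) {
            u5 <- max(1L, round(L * 0.15))
            u3 <- max(1L, round(L * 0.20))
            g1 <- txToGenomic(m, u5 + 1L)
            g2 <- txToGenomic(m, L - u3)
            m <- TranscriptModel(geneId(m), ch, strand, exons,
                                 cds = IRanges(min(g1, g2), max(g1, g2)))
          }
          out[[i]] <- m
          cursors[[ch]] <- s0 + span
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("genome too small to place gene ", i)
    }
    out
  })
  names(models) <- vapply(models, geneId, character(1))
  if (!is.null(bedPath)) writeBed12(models, bedPath)
  models
}

#' Write transcript models as BED12
#'
#' @param models list of [TranscriptModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    ex <- exonRanges(m)
    chromStart <- min(start(ex)) - 1L
    chromEnd <- max(end(ex))
    cds <- cdsRange(m)
    thick <- if (length(cds)) c(start(cds) - 1L, end(cds)) else
      c(chromStart, chromStart)
    paste(txChrom(m), chromStart, chromEnd, geneId(m), 0L, txStrand(m),
          thick[1], thick[2], 0L, length(ex),
          paste(width(ex), collapse = ","),
          paste(start(ex) - 1L - chromStart, collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.applyErrors <- function(chars, errorRate) {
  if (errorRate <= 0 || !length(chars)) return(chars)
  hit <- which(runif(length(chars)) < errorRate)
  if (!length(hit)) return(chars)
  bases <- c("A", "C", "G", "T")
  for (j in hit) {
    alt <- bases[bases != chars[j]]
    if (length(alt) < 3L) alt <- bases      # non-ACGT base: any base
    chars[j] <- alt[sample.int(length(alt), 1L)]
  }
  chars
}

#' Simulate an aligned paired-end read library with injected effects
#'
#' Draws fragments per gene (uniform start over positions where the full
#' fragment fits, truncated-normal length), applies the modification
#' effects in the order cleavage, then RT-stop, then misincorporation,
#' sequences the terminal `readLength` bases of each fragment end as
#' mates, applies per-base sequencing errors, and writes the alignments
#' directly as a coordinate-sorted SAM file with correct chromosomes,
#' positions, spliced CIGARs (M/N across junctions), strands, flags and
#' mate fields. Output is byte-identical for identical inputs and seed.
#'
#' @param models named list of [TranscriptModel-class].
#' @param genome a [Biostrings::DNAStringSet].
#' @param config a [simConfig()] object.
#' @param modSites list of [modSite()] specs; a `misinc` site whose
#'   `fromBase` does not match the transcript base is an error.
#' @param ipSites optional named integer vector (gene id -> transcript
#'   position) emulating antibody immunoprecipitation: fragments spanning
#'   the site are always captured, others only with probability
#'   `ipBackground` (m6A-seq style enrichment).
#' @param ipBackground capture probability for fragments not spanning
#'   their gene's `ipSites` position.
#' @param paired `TRUE` writes mate pairs; `FALSE` writes one single-end
#'   read (the fragment 5' end) per fragment.
#' @param samPath output SAM path.
#' @param truthPath optional TSV path for the truth record.
#' @return invisibly, the truth `data.table`: one row per fragment with
#'   `gene`, `frag`, `txStart`, `txEnd` (post-effect span) and `effects`
#'   (semicolon-joined tags like `rt_stop@120`).
#' @export
simulateLibrary <- function(models, genome, config, modSites = list(),
                            ipSites = NULL, ipBackground = 0.05,
                            paired = TRUE, samPath, truthPath = NULL) {
  ids <- vapply(models, geneId, character(1))
  txSeqs <- vapply(models, transcriptSequence, character(1), genome = genome)
  for (ms in modSites) {
    i <- match(ms$gene, ids)
    if (is.na(i)) stop("modSite gene not in models: ", ms$gene)
    if (ms$txPos > txLength(models[[i]]))
      stop("modSite position ", ms$txPos, " beyond transcript of ", ms$gene)
    if (ms$effect == "misinc") {
      ref <- substr(txSeqs[i], ms$txPos, ms$txPos)
      if (ref != ms$fromBase)
        stop("misinc site ", ms$gene, ":", ms$txPos, " reference base is ",
             ref, ", not ", ms$fromBase)
    }
  }

  res <- .withSeed(config$seed + 303L, {
    recs <- list()
    truth <- list()
    for (gi in seq_along(models)) {
      m <- models[[gi]]
      gid <- geneId(m)
      L <- txLength(m)
      txSeq <- txSeqs[gi]
      n <- config$fragmentsPerGene
      if (n == 0L) next
      len <- as.integer(round(rnorm(n, config$fragMean, config$fragSd)))
      len <- pmin(pmax(len, max(config$fragMin, 1L)), config$fragMax)
      len <- pmin(len, L)
      start <- 1L + as.integer(floor(runif(n) * (L - len + 1L)))
      fr <- data.table(start = start, end = start + len - 1L,
                       effects = "")
      if (!is.null(ipSites) && gid %in% names(ipSites)) {
        s <- ipSites[[gid]]
        spanning <- fr$start <= s & fr$end >= s
        keep <- spanning | runif(nrow(fr)) < ipBackground
        fr <- fr[keep]
        if (nrow(fr) == 0L) next
      }
      siteList <- Filter(function(ms) ms$gene == gid, modSites)
      # cleavage first: split spanning fragments
      for (ms in siteList) {
        if (ms$effect != "cleavage") next
        s <- ms$txPos
        idx <- which(fr$start <= s & fr$end > s)
        hit <- idx[runif(length(idx)) < ms$prob]
        if (!length(hit)) next
        right <- fr[hit]
        right[, start := s + 1L]
        right[, effects := paste0(effects, "cleavage@", s, ";")]
        fr[hit, `:=`(end = s,
                     effects = paste0(effects, "cleavage@", s, ";"))]
        fr <- rbind(fr, right)
      }
      # RT stops: truncate the 5' end to one nucleotide downstream
      for (ms in siteList) {
        if (ms$effect != "rt_stop") next
        s <- ms$txPos
        idx <- which(fr$start <= s & fr$end > s)
        hit <- idx[runif(length(idx)) < ms$prob]
        if (!length(hit)) next
        fr[hit, `:=`(start = s + 1L,
                     effects = paste0(effects, "rt_stop@", s, ";"))]
      }
      # misincorporation decisions, one per fragment sequencing the site
      misinc <- Filter(function(ms) ms$effect == "misinc", siteList)
      misincHits <- lapply(misinc, function(ms) {
        idx <- which(fr$start <= ms$txPos & fr$end >= ms$txPos)
        idx[runif(length(idx)) < ms$prob]
      })
      for (k in seq_along(misinc)) {
        if (length(misincHits[[k]]))
          fr[misincHits[[k]],
             effects := paste0(effects, "misinc@", misinc[[k]]$txPos, ";")]
      }
      rl <- config$readLength
      for (fi in seq_len(nrow(fr))) {
        a <- fr$start[fi]; b <- fr$end[fi]
        qname <- sprintf("%s_f%05d", gid, fi)
        m1 <- c(a, min(a + rl - 1L, b))
        m2 <- c(max(b - rl + 1L, a), b)
        subs <- integer(0)
        for (k in seq_along(misinc)) {
          if (fi %in% misincHits[[k]]) subs <- c(subs, k)
        }
        mateSeq <- function(iv) {
          chars <- strsplit(substr(txSeq, iv[1], iv[2]), "", fixed = TRUE)[[1]]
          for (k in subs) {
            p <- misinc[[k]]$txPos
            if (p >= iv[1] && p <= iv[2])
              chars[p - iv[1] + 1L] <- misinc[[k]]$toBase
          }
          .applyErrors(chars, config$errorRate)
        }
        if (paired) {
          recs[[length(recs) + 1L]] <-
            .samPair(m, qname, m1, m2, mateSeq(m1), mateSeq(m2))
        } else {
          recs[[length(recs) + 1L]] <-
            .samSingle(m, qname, m1, mateSeq(m1))
        }
      }
      truth[[gid]] <- data.table(gene = gid, frag = seq_len(nrow(fr)),
                                 txStart = fr$start, txEnd = fr$end,
                                 effects = sub(";$", "", fr$effects))
    }
    recdt <- if (length(recs)) {
      fields <- names(recs[[1L]])
      as.data.table(lapply(setNames(fields, fields), function(f)
        unlist(lapply(recs, `[[`, f), use.names = FALSE)))
    } else data.table()
    list(recs = recdt, truth = rbindlist(truth))
  })

  .writeSam(res$recs, genome, samPath)
  if (!is.null(truthPath))
    fwrite(res$truth, truthPath, sep = "\t", quote = FALSE)
  invisible(res$truth)
}

# genomic blocks of a contiguous tx interval -> (pos, cigar) on the genome
.posCigar <- function(model, iv) {
  g <- sort(txToGenomic(model, iv[1]:iv[2]))
  brk <- which(diff(g) != 1L)
  starts <- g[c(1L, brk + 1L)]
  ends <- g[c(brk, length(g))]
  parts <- paste0(ends - starts + 1L, "M")
  if (length(starts) > 1L) {
    gaps <- starts[-1L] - ends[-length(ends)] - 1L
    parts <- c(rbind(parts[-length(parts)], paste0(gaps, "N")),
               parts[length(parts)])
  }
  list(pos = starts[1L], cigar = paste(parts, collapse = ""),
       gend = ends[length(ends)])
}

# SEQ on the genomic plus strand: transcript-orientation bases as-is for
# plus-strand genes, reverse complement for minus-strand genes
.plusSeq <- function(model, chars) {
  if (txStrand(model) == "-")
    paste(rev(.complementCalls(chars)), collapse = "")
  else paste(chars, collapse = "")
}

.samPair <- function(model, qname, iv1, iv2, chars1, chars2) {
  pc1 <- .posCigar(model, iv1)
  pc2 <- .posCigar(model, iv2)
  plus <- txStrand(model) == "+"
  # FR layout: read1 aligns on the gene strand, read2 on the opposite
  f1 <- 1L + 2L + 64L + (if (plus) 32L else 16L)
  f2 <- 1L + 2L + 128L + (if (plus) 16L else 32L)
  gLeft <- min(pc1$pos, pc2$pos)
  gRight <- max(pc1$gend, pc2$gend)
  tlen <- gRight - gLeft + 1L
  t1 <- if (pc1$pos <= pc2$pos) tlen else -tlen
  list(
    qname = c(qname, qname), flag = c(f1, f2),
    chrom = c(txChrom(model), txChrom(model)),
    pos = c(pc1$pos, pc2$pos), mapq = c(60L, 60L),
    cigar = c(pc1$cigar, pc2$cigar), rnext = c("=", "="),
    pnext = c(pc2$pos, pc1$pos), tlen = c(t1, -t1),
    seq = c(.plusSeq(model, chars1), .plusSeq(model, chars2)),
    qual = c(strrep("I", length(chars1)), strrep("I", length(chars2)))
  )
}

.samSingle <- function(model, qname, iv, chars) {
  pc <- .posCigar(model, iv)
  list(
    qname = qname, flag = if (txStrand(model) == "+") 0L else 16L,
    chrom = txChrom(model), pos = pc$pos, mapq = 60L, cigar = pc$cigar,
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = .plusSeq(model, chars), qual = strrep("I", length(chars))
  )
}

.writeSam <- function(recs, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), width(genome)))
  if (nrow(recs)) {
    recs <- copy(recs)
    recs[, .chromOrd := match(chrom, names(genome))]
    setorder(recs, .chromOrd, pos, qname, flag)
    body <- recs[, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                           qname, flag, chrom, pos, mapq, cigar, rnext,
                           pnext, tlen, seq, qual)]
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
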