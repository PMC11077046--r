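#' Options controlling read-to-transcript conversion
#'
#' @param strandMode how the fragment strand (alignment strand of read 1,
#'   or of the single read — an FR library layout) must relate to the
#'   model strand: `"same"` (default), `"opposite"`, or `"ignore"`.
#' @param maxFragment maximum merged (bridged) fragment span in transcript
#'   coordinates; longer spans are discarded as likely chimeric pairs.
#' @param minMapq minimum mapping quality; records below are dropped.
#' @return a `ConversionOptions` list.
#' @export
conversionOptions <- function(strandMode = c("same", "opposite", "ignore"),
                              maxFragment = 1000L, minMapq = 0L) {
  strandMode <- match.arg(strandMode)
  stopifnot(maxFragment >= 1L, minMapq >= 0L)
  structure(list(strandMode = strandMode,
                 maxFragment = as.integer(maxFragment),
                 minMapq = as.integer(minMapq)),
            class = "ConversionOptions")
}

#' Load alignments from SAM/BAM, grouped by read name
#'
#' Reads primary, mapped records (unmapped, secondary and supplementary
#' alignments are excluded) and returns them as a `data.table` with one
#' row per record, keyed by `qname`, preserving mate pairing via the
#' read-1/read-2 flags. Plain-text SAM input is converted on the fly via
#' [Rsamtools::asBam()].
#'
#' @param path path to a BAM or SAM file.
#' @param region optional chromosome name to restrict loading to.
#' @return `data.table` with columns `qname`, `chrom`, `strand`, `pos`,
#'   `cigar`, `seq`, `mapq`, `isPaired`, `isRead1`, `isRead2`.
#' @export
loadAlignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- asBam(path, destination = dest, overwrite = TRUE,
                 indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    tryCatch(Rsamtools::indexBam(path), error = function(e) NULL)
  }
  flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                      isSupplementaryAlignment = FALSE)
  which <- if (is.null(region)) GRanges() else {
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!region %in% names(hdr)) stop("region '", region, "' not in BAM header")
    GRanges(region, IRanges(1L, hdr[[region]]))
  }
  param <- if (is.null(region)) {
    ScanBamParam(flag = flag, what = c("qname", "flag", "seq", "mapq"))
  } else {
    ScanBamParam(flag = flag, what = c("qname", "flag", "seq", "mapq"),
                 which = which)
  }
  ga <- readGAlignments(bam, param = param)
  md <- mcols(ga)
  dt <- data.table(
    qname = md$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    pos = GenomicAlignments::start(ga),
    cigar = cigar(ga),
    seq = as.character(md$seq),
    mapq = as.integer(md$mapq),
    flag = md$flag
  )
  dt[, isPaired := bitwAnd(flag, 1L) > 0L]
  dt[, isRead1 := bitwAnd(flag, 64L) > 0L]
  dt[, isRead2 := bitwAnd(flag, 128L) > 0L]
  dt[, flag := NULL]
  setkey(dt, qname)
  dt
}

# Decompose CIGAR/pos of a set of records into genomic M, D and N ranges
# plus the query-space ranges of the M ops (for slicing read sequences).
.cigarBlocks <- function(cigars, pos) {
  list(
    M  = cigarRangesAlongReferenceSpace(cigars, pos = pos, ops = "M"),
    D  = cigarRangesAlongReferenceSpace(cigars, pos = pos, ops = "D"),
    N  = cigarRangesAlongReferenceSpace(cigars, pos = pos, ops = "N"),
    Mq = cigarRangesAlongQuerySpace(cigars, ops = "M")
  )
}

# TRUE for each record whose M/D blocks all fall inside the exon union and
# whose every N gap coincides exactly with an intron implied by the exons.
# Vectorized over all records at once (exons are disjoint, so a block is
# "within" at most one exon).
.structureCompatible <- function(blocks, model) {
  ex <- exonRanges(model)
  introns <- IRanges::gaps(ex)
  n <- length(blocks$M)
  okGroup <- function(rl) {
    ul <- unlist(rl, use.names = FALSE)
    grp <- rep(seq_len(n), lengths(rl))
    ov <- findOverlaps(ul, ex, type = "within")
    tabulate(grp[queryHits(ov)], n) == lengths(rl)
  }
  ok <- okGroup(blocks$M) & okGroup(blocks$D)
  ulN <- unlist(blocks$N, use.names = FALSE)
  if (length(ulN)) {
    grpN <- rep(seq_len(n), lengths(blocks$N))
    hitN <- !is.na(match(paste(start(ulN), end(ulN)),
                         paste(start(introns), end(introns))))
    ok <- ok & (tabulate(grpN[hitN], n) == lengths(blocks$N))
  }
  ok
}

#' Convert one aligned segment to transcript space
#'
#' Succeeds only when every aligned (M) and deleted (D) genomic block lies
#' inside the model's exon union and every skip (N) gap coincides exactly
#' with an annotated intron; otherwise returns `NULL` (incompatibility is
#' a filter, not an error). On success M positions carry the read base in
#' transcript orientation (complemented for minus-strand models), D
#' positions carry `"-"`; soft clips and insertions contribute no
#' transcript positions, so the resulting interval is contiguous.
#'
#' @param model a [TranscriptModel-class].
#' @param pos 1-based leftmost aligned genomic coordinate.
#' @param cigarString the CIGAR string.
#' @param seq read sequence as aligned (plus genomic strand), or `NA`.
#' @return `NULL`, or a list with `txStart`, `txEnd`, and `calls`
#'   (`data.table` of `pos`, `base`).
#' @export
segmentToTx <- function(model, pos, cigarString, seq = NA_character_) {
  res <- .segmentsToTx(model, pos, cigarString, seq)
  if (!res$ok[1]) return(NULL)
  list(txStart = res$txStart[1], txEnd = res$txEnd[1],
       calls = data.table(pos = res$callPos[[1]], base = res$callBase[[1]]))
}

# Vectorized worker: converts many segments against one model in bulk.
# Returns list(ok, txStart, txEnd, callPos, callBase) where callPos and
# callBase are per-segment lists of transcript positions (ascending) and
# base calls; non-compatible segments have NULL entries.
.segmentsToTx <- function(model, pos, cigars, seqs) {
  n <- length(pos)
  blocks <- .cigarBlocks(cigars, pos)
  ok <- .structureCompatible(blocks, model)
  txStart <- rep(NA_integer_, n)
  txEnd <- rep(NA_integer_, n)
  callPos <- vector("list", n)
  callBase <- vector("list", n)
  w <- which(ok)
  if (!length(w))
    return(list(ok = ok, txStart = txStart, txEnd = txEnd,
                callPos = callPos, callBase = callBase))
  minus <- txStrand(model) == "-"

  # expand all M blocks of compatible segments to genomic positions
  mOk <- blocks$M[w]
  ulM <- unlist(mOk, use.names = FALSE)
  grpM <- rep(rep(w, lengths(mOk)), width(ulM))
  gposM <- sequence(width(ulM), from = start(ulM))
  # read bases of the M blocks, in the same expansion order
  qOk <- blocks$Mq[w]
  ulQ <- unlist(qOk, use.names = FALSE)
  seqPerBlock <- rep(seqs[w], lengths(mOk))
  haveSeq <- !is.na(seqPerBlock)
  blockStr <- character(length(ulQ))
  blockStr[haveSeq] <- substring(seqPerBlock[haveSeq],
                                 start(ulQ)[haveSeq], end(ulQ)[haveSeq])
  blockStr[!haveSeq] <- strrep("N", width(ulQ)[!haveSeq])
  basesM <- strsplit(paste(blockStr, collapse = ""), "", fixed = TRUE)[[1]]
  if (minus) basesM <- .complementCalls(basesM)

  # deleted reference positions carry "-"
  dOk <- blocks$D[w]
  ulD <- unlist(dOk, use.names = FALSE)
  grpD <- rep(rep(w, lengths(dOk)), width(ulD))
  gposD <- sequence(width(ulD), from = start(ulD))

  grp <- c(grpM, grpD)
  tpos <- genomicToTx(model, c(gposM, gposD))
  base <- c(basesM, rep("-", length(gposD)))
  o <- order(grp, tpos)
  grp <- grp[o]; tpos <- tpos[o]; base <- base[o]
  bnd <- c(which(diff(grp) != 0L), length(grp))
  first <- c(1L, head(bnd, -1L) + 1L)
  segIdx <- grp[first]
  txStart[segIdx] <- tpos[first]
  txEnd[segIdx] <- tpos[bnd]
  posSplit <- split(tpos, grp)
  baseSplit <- split(base, grp)
  callPos[as.integer(names(posSplit))] <- posSplit
  callBase[as.integer(names(baseSplit))] <- baseSplit
  list(ok = ok, txStart = txStart, txEnd = txEnd,
       callPos = callPos, callBase = callBase)
}

#' Merge a mate pair into one bridged transcript-space fragment
#'
#' Both mates must convert cleanly via [segmentToTx()]; the fragment then
#' spans from the 5'-most to the 3'-most transcript coordinate of the two
#' mates. Calls are the union of both mates' calls; where the mates
#' overlap and agree the call is kept once, where they disagree the call
#' becomes `N`. Positions in the inter-mate gap carry no calls — they
#' count toward coverage only (mate bridging). Returns `NULL` when either
#' mate is incompatible, the fragment strand violates `strandMode`, or
#' the merged span exceeds `maxFragment`.
#'
#' @param model a [TranscriptModel-class].
#' @param seg1,seg2 one-row `data.table`s (rows of [loadAlignments()]
#'   output) for read 1 and read 2.
#' @param opts a [conversionOptions()] list.
#' @return `NULL` or a list with `txStart`, `txEnd`, `calls`.
#' @export
fragmentFromPair <- function(model, seg1, seg2, opts = conversionOptions()) {
  if (seg1$chrom != txChrom(model) || seg2$chrom != txChrom(model)) return(NULL)
  if (!.strandOk(seg1$strand, model, opts)) return(NULL)
  a <- segmentToTx(model, seg1$pos, seg1$cigar, seg1$seq)
  if (is.null(a)) return(NULL)
  b <- segmentToTx(model, seg2$pos, seg2$cigar, seg2$seq)
  if (is.null(b)) return(NULL)
  .mergeMates(a, b, opts$maxFragment)
}

.strandOk <- function(read1Strand, model, opts) {
  switch(opts$strandMode,
         same = read1Strand == txStrand(model),
         opposite = read1Strand != txStrand(model),
         ignore = TRUE)
}

# merge two mates' ascending (pos, base) call vectors; overlap agreement
# keeps one call, disagreement becomes N
.mergeCallVecs <- function(p1, b1, p2, b2) {
  pos <- c(p1, p2); base <- c(b1, b2)
  o <- order(pos)
  pos <- pos[o]; base <- base[o]
  d <- which(duplicated(pos))          # at most 2 calls per position
  if (length(d)) {
    disagree <- d[base[d] != base[d - 1L]]
    base[disagree - 1L] <- "N"
    pos <- pos[-d]; base <- base[-d]
  }
  list(pos = pos, base = base)
}

.mergeMates <- function(a, b, maxFragment) {
  txStart <- min(a$txStart, b$txStart)
  txEnd <- max(a$txEnd, b$txEnd)
  if (txEnd - txStart + 1L > maxFragment) return(NULL)
  mc <- .mergeCallVecs(a$calls$pos, a$calls$base, b$calls$pos, b$calls$base)
  list(txStart = txStart, txEnd = txEnd,
       calls = data.table(pos = mc$pos, base = mc$base))
}

#' Assign read groups to transcript models as bridged fragments
#'
#' The transcript-space read-assignment step: every read (pair) is tested
#' against every model on its chromosome, and a fragment is emitted for
#' each model it is compatible with — a pair compatible with two
#' overlapping isoforms yields two fragments, one per isoform. In paired
#' mode, groups with exactly one usable mate are discarded (not demoted
#' to single-end). The discard report counts read groups never assigned
#' to any model, by the furthest rejection stage reached: `halfPair`,
#' `offAnnotation` (no candidate model), `structure` (exon/junction
#' incompatibility), `strand`, `span` (merged span over `maxFragment`).
#'
#' @param groups `data.table` from [loadAlignments()].
#' @param models list of [TranscriptModel-class] (annotation order kept).
#' @param opts a [conversionOptions()] list.
#' @param paired logical; `TRUE` merges read1/read2 into bridged
#'   fragments, `FALSE` treats every record as an independent fragment.
#' @return list with `fragments` (named list of [TxFragments-class], one
#'   per gene with at least one fragment, in annotation order) and
#'   `discards` (named integer vector: `assignedGroups`, `halfPair`,
#'   `offAnnotation`, `structure`, `strand`, `span`).
#' @export
assignToTranscripts <- function(groups, models, opts = conversionOptions(),
                                paired = TRUE) {
  if (length(models) == 0L) stop("empty model list")
  if (paired) .assignPaired(groups, models, opts) else
    .assignSingle(groups, models, opts)
}

# stage codes: 0 none attempted, 1 structure fail, 2 strand fail,
# 3 span fail, 4 assigned
.assignPaired <- function(groups, models, opts) {
  if (opts$minMapq > 0L) groups <- groups[mapq >= opts$minMapq]
  qn <- unique(groups$qname)
  r1 <- groups[isRead1 == TRUE]
  r2 <- groups[isRead2 == TRUE]
  usable <- intersect(r1$qname, r2$qname)
  halfPair <- sum(!qn %in% usable)
  r1 <- r1[qname %in% usable][!duplicated(qname)]
  r2 <- r2[qname %in% usable][!duplicated(qname)]
  setkey(r1, qname); setkey(r2, qname)
  r2 <- r2[r1$qname]
  stage <- rep(0L, nrow(r1))
  ends1 <- r1$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(r1$cigar) - 1L
  ends2 <- r2$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(r2$cigar) - 1L

  frags <- list()
  for (m in models) {
    gid <- geneId(m)
    # candidates: both mates within the genomic span of the gene
    gmin <- min(start(exonRanges(m))); gmax <- max(end(exonRanges(m)))
    cand <- which(r1$chrom == txChrom(m) & r2$chrom == txChrom(m) &
                    r1$pos >= gmin & ends1 <= gmax &
                    r2$pos >= gmin & ends2 <= gmax)
    if (!length(cand)) next
    c1 <- .segmentsToTx(m, r1$pos[cand], r1$cigar[cand], r1$seq[cand])
    c2 <- .segmentsToTx(m, r2$pos[cand], r2$cigar[cand], r2$seq[cand])
    okBoth <- c1$ok & c2$ok
    stage[cand] <- pmax(stage[cand], 1L)              # structure attempted
    strandPass <- .strandOkVec(r1$strand[cand], m, opts)
    stage[cand[okBoth]] <- pmax(stage[cand[okBoth]], 2L)
    use <- which(okBoth & strandPass)
    stage[cand[use]] <- pmax(stage[cand[use]], 3L)
    if (!length(use)) next
    txStart <- pmin(c1$txStart[use], c2$txStart[use])
    txEnd <- pmax(c1$txEnd[use], c2$txEnd[use])
    fits <- txEnd - txStart + 1L <= opts$maxFragment
    keep <- use[fits]
    stage[cand[keep]] <- 4L
    if (!length(keep)) next
    merged <- lapply(keep, function(j)
      .mergeCallVecs(c1$callPos[[j]], c1$callBase[[j]],
                     c2$callPos[[j]], c2$callBase[[j]]))
    nf <- length(keep)
    lens <- vapply(merged, function(x) length(x$pos), integer(1))
    frags[[gid]] <- TxFragments(
      gid, txLength(m),
      data.table(frag = seq_len(nf), txStart = txStart[fits],
                 txEnd = txEnd[fits]),
      data.table(frag = rep(seq_len(nf), lens),
                 pos = unlist(lapply(merged, `[[`, "pos")),
                 base = unlist(lapply(merged, `[[`, "base"))))
  }
  discards <- c(
    assignedGroups = sum(stage == 4L),
    halfPair = halfPair,
    offAnnotation = sum(stage == 0L),
    structure = sum(stage == 1L),
    strand = sum(stage == 2L),
    span = sum(stage == 3L)
  )
  list(fragments = frags, discards = discards)
}

.strandOkVec <- function(strands, model, opts) {
  switch(opts$strandMode,
         same = strands == txStrand(model),
         opposite = strands != txStrand(model),
         ignore = rep(TRUE, length(strands)))
}

.assignSingle <- function(groups, models, opts) {
  if (opts$minMapq > 0L) groups <- groups[mapq >= opts$minMapq]
  n <- nrow(groups)
  stage <- rep(0L, n)
  ends <- groups$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(groups$cigar) - 1L
  frags <- list()
  for (m in models) {
    gid <- geneId(m)
    gmin <- min(start(exonRanges(m))); gmax <- max(end(exonRanges(m)))
    cand <- which(groups$chrom == txChrom(m) & groups$pos >= gmin & ends <= gmax)
    if (!length(cand)) next
    cc <- .segmentsToTx(m, groups$pos[cand], groups$cigar[cand], groups$seq[cand])
    stage[cand] <- pmax(stage[cand], 1L)
    strandPass <- .strandOkVec(groups$strand[cand], m, opts)
    stage[cand[cc$ok]] <- pmax(stage[cand[cc$ok]], 2L)
    use <- which(cc$ok & strandPass)
    stage[cand[use]] <- pmax(stage[cand[use]], 3L)
    if (!length(use)) next
    keep <- use[(cc$txEnd[use] - cc$txStart[use] + 1L) <= opts$maxFragment]
    stage[cand[keep]] <- 4L
    if (!length(keep)) next
    lens <- lengths(cc$callPos[keep])
    frags[[gid]] <- TxFragments(
      gid, txLength(m),
      data.table(frag = seq_along(keep),
                 txStart = cc$txStart[keep], txEnd = cc$txEnd[keep]),
      data.table(frag = rep(seq_along(keep), lens),
                 pos = unlist(cc$callPos[keep]),
                 base = unlist(cc$callBase[keep])))
  }
  discards <- c(
    assignedGroups = sum(stage == 4L),
    halfPair = 0L,
    offAnnotation = sum(stage == 0L),
    structure = sum(stage == 1L),
    strand = sum(stage == 2L),
    span = sum(stage == 3L)
  )
  list(fragments = frags, discards = discards)
}
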