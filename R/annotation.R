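#' Load a BED12/BED6 transcriptome annotation
#'
#' Reads a tab-separated BED file and returns one [TranscriptModel-class]
#' per record, in file order. BED12 records yield multi-exon models from
#' `blockSizes`/`blockStarts`; BED6 records are promoted to single-block
#' models with no CDS. `thickStart == thickEnd` means no CDS. BED
#' coordinates are 0-based half-open on disk and converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' Malformed records fail loudly with the offending line number:
#' `blockCount` disagreeing with the `blockSizes`/`blockStarts` lists,
#' `chromStart > chromEnd`, a strand outside `{+,-}`, or overlapping exon
#' blocks are all parse errors, not silent fixes.
#'
#' @param path path to a BED6 or BED12 file (tab-separated, no header).
#' @return list of [TranscriptModel-class], in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(paste(c("chr1", 100, 260, "geneA", 0, "+", 120, 230, 0, 2,
#'                    "50,60", "0,100"), collapse = "\t"), bed)
#' loadBed(bed)[[1]]
#' @export
loadBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  models <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (!length(f) %in% c(6L, 12L))
      stop(sprintf("BED line %d: expected 6 or 12 fields, got %d", ln, length(f)))
    chrom <- f[1]
    chromStart <- suppressWarnings(as.integer(f[2]))
    chromEnd <- suppressWarnings(as.integer(f[3]))
    if (is.na(chromStart) || is.na(chromEnd))
      stop(sprintf("BED line %d: non-numeric chromStart/chromEnd", ln))
    if (chromStart > chromEnd)
      stop(sprintf("BED line %d: chromStart > chromEnd", ln))
    name <- f[4]
    strand <- f[6]
    if (!strand %in% c("+", "-"))
      stop(sprintf("BED line %d: strand must be '+' or '-', got '%s'", ln, strand))
    if (length(f) == 6L) {
      exons <- IRanges(chromStart + 1L, chromEnd)
      cds <- NULL
    } else {
      thickStart <- as.integer(f[7]); thickEnd <- as.integer(f[8])
      blockCount <- as.integer(f[10])
      sizes <- suppressWarnings(as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]]))
      starts <- suppressWarnings(as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]]))
      if (anyNA(sizes) || anyNA(starts))
        stop(sprintf("BED line %d: non-numeric blockSizes/blockStarts", ln))
      if (length(sizes) != blockCount || length(starts) != blockCount)
        stop(sprintf(
          "BED line %d: blockCount %d disagrees with blockSizes (%d) / blockStarts (%d)",
          ln, blockCount, length(sizes), length(starts)))
      exStart <- chromStart + starts + 1L
      exons <- IRanges(exStart, exStart + sizes - 1L)
      if (length(exons) > 1L && any(start(exons)[-1L] <= end(exons)[-length(exons)]))
        stop(sprintf("BED line %d: overlapping exon blocks", ln))
      cds <- if (thickStart == thickEnd) NULL else IRanges(thickStart + 1L, thickEnd)
    }
    models[[k]] <- TranscriptModel(name, chrom, strand, exons, cds)
  }
  names(models) <- vapply(models, geneId, character(1))
  models
}

#' Load a genome reference from FASTA
#'
#' Sequences are uppercased and `U` is converted to `T`, so RNA references
#' are accepted. Duplicate record ids and empty files are errors.
#'
#' @param path path to a (multi-record, possibly line-wrapped) FASTA file.
#' @return a [Biostrings::DNAStringSet] named by record id.
#' @export
loadGenome <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "t", as.character(raw))
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

.checkChrom <- function(model, genome) {
  if (!txChrom(model) %in% names(genome))
    stop("chromosome '", txChrom(model), "' of gene '", geneId(model),
         "' not present in genome")
  if (max(end(exonRanges(model))) > length(genome[[txChrom(model)]]))
    stop("exon of gene '", geneId(model), "' exceeds length of chromosome '",
         txChrom(model), "'")
}

#' Extract the transcript sequence of a model
#'
#' Concatenates the exon sequences 5' to 3' in transcript orientation: for
#' minus-strand models this is the reverse complement of the ascending
#' exon concatenation, so position `i` of the result is the reference base
#' at transcript coordinate `i`.
#'
#' @param model a [TranscriptModel-class].
#' @param genome a [Biostrings::DNAStringSet] as from [loadGenome()].
#' @return character(1) of length `txLength(model)`.
#' @export
transcriptSequence <- function(model, genome) {
  .checkChrom(model, genome)
  chromSeq <- genome[[txChrom(model)]]
  ex <- exonRanges(model)
  pieces <- as.character(Biostrings::extractAt(chromSeq, ex))
  s <- paste(pieces, collapse = "")
  if (txStrand(model) == "-") s <- .revcompString(s)
  s
}

# cumulative exon widths before each exon (plus-strand transcript offsets)
.cumBefore <- function(model) {
  w <- width(exonRanges(model))
  c(0L, cumsum(w))[seq_along(w)]
}

#' Genomic to transcript coordinate conversion
#'
#' Maps 1-based genomic positions to 1-based transcript coordinates.
#' Intronic or out-of-gene positions map to `NA` (that is the contract,
#' not an error). On the minus strand transcript position 1 corresponds to
#' the highest exonic genomic coordinate.
#'
#' @param model a [TranscriptModel-class].
#' @param gpos integer vector of 1-based genomic positions.
#' @return integer vector of transcript coordinates, `NA` where not exonic.
#' @seealso [txToGenomic()] for the inverse.
#' @export
genomicToTx <- function(model, gpos) {
  ex <- exonRanges(model)
  cumb <- .cumBefore(model)
  idx <- findInterval(gpos, start(ex))
  hit <- idx >= 1L & !is.na(gpos)
  hit[hit] <- gpos[hit] <= end(ex)[idx[hit]]
  out <- rep(NA_integer_, length(gpos))
  out[hit] <- cumb[idx[hit]] + (gpos[hit] - start(ex)[idx[hit]] + 1L)
  if (txStrand(model) == "-") out <- txLength(model) - out + 1L
  out
}

#' Transcript to genomic coordinate conversion
#'
#' Inverse of [genomicToTx()] on its defined domain. Out-of-range
#' transcript coordinates are an error.
#'
#' @param model a [TranscriptModel-class].
#' @param tpos integer vector of 1-based transcript coordinates.
#' @return integer vector of 1-based genomic positions.
#' @export
txToGenomic <- function(model, tpos) {
  L <- txLength(model)
  if (any(is.na(tpos)) || any(tpos < 1L) || any(tpos > L))
    stop("transcript coordinate out of range [1, ", L, "]")
  p <- if (txStrand(model) == "-") L - as.integer(tpos) + 1L else as.integer(tpos)
  ex <- exonRanges(model)
  cumw <- cumsum(width(ex))
  idx <- findInterval(p - 1L, c(0L, cumw[-length(cumw)])) # exon index per position
  idx <- pmax(idx, 1L)
  cumb <- c(0L, cumw)[idx]
  start(ex)[idx] + (p - cumb - 1L)
}

# map a contiguous transcript interval [a, b] to ascending genomic blocks
.txIntervalToGenomicBlocks <- function(model, a, b) {
  g <- txToGenomic(model, a:b)
  g <- sort(g)
  brk <- which(diff(g) != 1L)
  starts <- g[c(1L, brk + 1L)]
  ends <- g[c(brk, length(g))]
  IRanges(starts, ends)
}

#' Transcript-space gene regions (5'UTR, CDS, 3'UTR)
#'
#' Partitions `[1, txLength]` into the three transcript-orientation
#' regions implied by the CDS span. Any of the UTRs may be empty (width
#' 0). Noncoding models are an error.
#'
#' @param model a coding [TranscriptModel-class].
#' @return named list `utr5`, `cds`, `utr3` of integer `c(start, end)`
#'   transcript intervals; an empty region has `start > end`.
#' @export
txRegions <- function(model) {
  cds <- cdsRange(model)
  if (length(cds) == 0L)
    stop("gene '", geneId(model), "' is noncoding (no CDS)")
  t1 <- genomicToTx(model, start(cds))
  t2 <- genomicToTx(model, end(cds))
  if (is.na(t1) || is.na(t2))
    stop("CDS endpoints of gene '", geneId(model), "' are not exonic")
  cdsTx <- sort(c(t1, t2))
  L <- txLength(model)
  list(
    utr5 = c(1L, cdsTx[1] - 1L),
    cds  = c(cdsTx[1], cdsTx[2]),
    utr3 = c(cdsTx[2] + 1L, L)
  )
}
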