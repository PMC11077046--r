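#' TranscriptModel: one gene/isoform record
#'
#' A `TranscriptModel` holds the exon-block structure of one annotation
#' record (one gene or isoform): chromosome, strand, ordered exon blocks
#' and an optional CDS span. It is the unit of genomic-to-transcriptomic
#' coordinate conversion. All stored coordinates are 1-based inclusive
#' genomic positions (BED input is converted on load); transcript
#' coordinates run 1..`txLength()` from the transcript 5' end.
#'
#' @slot geneId character(1), the BED name column, used verbatim in tables.
#' @slot chrom character(1) chromosome/sequence name.
#' @slot strand character(1), `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon blocks, ascending genomic order,
#'   pairwise disjoint.
#' @slot cds [IRanges::IRanges] of length 0 (noncoding) or 1; endpoints
#'   must fall on exonic positions.
#'
#' @examples
#' m <- TranscriptModel("geneA", "chr1", "+",
#'                      IRanges::IRanges(start = c(101, 201), end = c(150, 260)),
#'                      cds = IRanges::IRanges(121, 230))
#' txLength(m)
#' @export
setClass("TranscriptModel",
  representation(
    geneId = "character",
    chrom  = "character",
    strand = "character",
    exons  = "IRanges",
    cds    = "IRanges"
  )
)

setValidity("TranscriptModel", function(object) {
  msg <- character(0)
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be \"+\" or \"-\"")
  ex <- object@exons
  if (length(ex) == 0L)
    msg <- c(msg, "exons must be non-empty")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be in ascending genomic order")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be pairwise disjoint and non-adjacent-overlapping")
  }
  if (any(start(ex) < 1L))
    msg <- c(msg, "exon coordinates must be >= 1")
  if (length(object@cds) > 1L)
    msg <- c(msg, "cds must contain at most one range")
  if (length(object@cds) == 1L) {
    cs <- start(object@cds); ce <- end(object@cds)
    if (cs > ce) msg <- c(msg, "cds start must not exceed cds end")
    onExon <- function(p) any(p >= start(ex) & p <= end(ex))
    if (!onExon(cs) || !onExon(ce))
      msg <- c(msg, "cds endpoints must fall on exonic positions")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param geneId gene/isoform name (BED name column).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons [IRanges::IRanges] of exon blocks (1-based inclusive
#'   genomic coordinates, ascending, disjoint).
#' @param cds optional [IRanges::IRanges] of length 1 with the CDS span,
#'   or `NULL` for a noncoding model.
#' @return A [TranscriptModel-class] object.
#' @export
TranscriptModel <- function(geneId, chrom, strand, exons, cds = NULL) {
  if (is.null(cds)) cds <- IRanges()
  new("TranscriptModel", geneId = as.character(geneId),
      chrom = as.character(chrom), strand = as.character(strand),
      exons = exons, cds = cds)
}

#' @describeIn TranscriptModel gene/isoform identifier.
#' @param object,x a `TranscriptModel`.
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname TranscriptModel-class
#' @export
setMethod("geneId", "TranscriptModel", function(x) x@geneId)

#' @rdname TranscriptModel-class
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))

#' @rdname TranscriptModel-class
#' @export
setMethod("txLength", "TranscriptModel", function(x) sum(width(x@exons)))

#' @rdname TranscriptModel-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname TranscriptModel-class
#' @export
setMethod("exonRanges", "TranscriptModel", function(x) x@exons)

#' @rdname TranscriptModel-class
#' @export
setGeneric("cdsRange", function(x) standardGeneric("cdsRange"))

#' @rdname TranscriptModel-class
#' @export
setMethod("cdsRange", "TranscriptModel", function(x) x@cds)

#' @rdname TranscriptModel-class
#' @export
setGeneric("txChrom", function(x) standardGeneric("txChrom"))

#' @rdname TranscriptModel-class
#' @export
setMethod("txChrom", "TranscriptModel", function(x) x@chrom)

#' @rdname TranscriptModel-class
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))

#' @rdname TranscriptModel-class
#' @export
setMethod("txStrand", "TranscriptModel", function(x) x@strand)

setMethod("show", "TranscriptModel", function(object) {
  cds <- if (length(object@cds)) {
    sprintf("CDS %d-%d", start(object@cds), end(object@cds))
  } else "noncoding"
  cat(sprintf("TranscriptModel %s | %s:%s | %d exon(s), %d nt | %s\n",
              object@geneId, object@chrom, object@strand,
              length(object@exons), txLength(object), cds))
})

#' TxFragments: transcript-space fragments of one gene
#'
#' Compact container for all fragments assigned to one transcript model.
#' Spans are the full (mate-bridged) fragment extents in transcript
#' coordinates; `calls` holds one row per sequenced (or deleted) position
#' per fragment, so bridged inter-mate gaps carry no rows. Base calls are
#' in transcript orientation (minus-strand models store the complement of
#' the genomic plus-strand base) and use `-` for deletions.
#'
#' @slot gene character(1) gene id (matches a `TranscriptModel`).
#' @slot txLength integer(1) transcript length.
#' @slot spans `data.table` with columns `frag`, `txStart`, `txEnd`.
#' @slot calls `data.table` with columns `frag`, `pos`, `base`.
#' @export
setClass("TxFragments",
  representation(
    gene = "character",
    txLength = "integer",
    spans = "data.table",
    calls = "data.table"
  )
)

setValidity("TxFragments", function(object) {
  msg <- character(0)
  sp <- object@spans
  if (!all(c("frag", "txStart", "txEnd") %in% names(sp)))
    msg <- c(msg, "spans must have columns frag, txStart, txEnd")
  if (!all(c("frag", "pos", "base") %in% names(object@calls)))
    msg <- c(msg, "calls must have columns frag, pos, base")
  if (nrow(sp)) {
    if (any(sp$txStart < 1L) || any(sp$txEnd > object@txLength) ||
        any(sp$txStart > sp$txEnd))
      msg <- c(msg, "fragment spans must satisfy 1 <= txStart <= txEnd <= txLength")
  }
  if (length(msg)) msg else TRUE
})

TxFragments <- function(gene, txLength, spans, calls) {
  new("TxFragments", gene = gene, txLength = as.integer(txLength),
      spans = spans, calls = calls)
}

#' @rdname TxFragments-class
#' @param object a `TxFragments`.
#' @export
setMethod("length", "TxFragments", function(x) nrow(x@spans))

setMethod("show", "TxFragments", function(object) {
  cat(sprintf("TxFragments %s | %d fragment(s) on %d nt | %d base call(s)\n",
              object@gene, nrow(object@spans), object@txLength,
              nrow(object@calls)))
})

#' @rdname TxFragments-class
#' @export
setGeneric("fragmentSpans", function(x) standardGeneric("fragmentSpans"))

#' @rdname TxFragments-class
#' @export
setMethod("fragmentSpans", "TxFragments", function(x) copy(x@spans))

#' @rdname TxFragments-class
#' @export
setGeneric("fragmentCalls", function(x) standardGeneric("fragmentCalls"))

#' @rdname TxFragments-class
#' @export
setMethod("fragmentCalls", "TxFragments", function(x) copy(x@calls))
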