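.COORD_COLS <- c("chrom", "gencoor", "strand", "gene", "txcoor")
.COV_COLS <- c("cov", "start_5p", "end_3p")
.NUC_COLS <- c("A", "C", "G", "T", "N", "del")
.BASE_LEVELS <- c("A", "C", "G", "T", "N", "-")

#' Summarize transcript-space fragments into a per-nucleotide table
#'
#' Builds the central per-base table: one row per transcript nucleotide of
#' each gene with assigned fragments, carrying both coordinate systems and
#' the four read-outs. Coverage counts every position of a fragment's full
#' (mate-bridged) span; `start_5p`/`end_3p` count fragment 5' and 3'
#' termini; `A`,`C`,`G`,`T`,`N`,`del` count base calls on sequenced (or
#' deleted) positions only, so bridged inter-mate gaps contribute to
#' coverage but never to base counts.
#'
#' @param fragments named list of [TxFragments-class] (as returned in
#'   `assignToTranscripts()$fragments`).
#' @param models list of [TranscriptModel-class]; every fragment gene must
#'   be present. Output gene order follows this list.
#' @param genome optional [Biostrings::DNAStringSet]; when given, a
#'   `refSeq` column reports the reference base at each transcript
#'   position (transcript orientation).
#' @param mode `"cov"` (coverage/starts/ends), `"nucFreq"` (base and
#'   deletion counts), or `"covNuc"` (both).
#' @param includeEmpty emit all-zero rows for genes with no fragments.
#' @return a `data.table`; see Details for the column set per mode.
#' @details Columns: always `chrom`, `gencoor`, `strand`, `gene`,
#'   `txcoor`, then `refSeq` when a genome is supplied, then per mode
#'   `cov`, `start_5p`, `end_3p` and/or `A`, `C`, `G`, `T`, `N`, `del`.
#' @export
makeTxTable <- function(fragments, models, genome = NULL,
                        mode = c("cov", "nucFreq", "covNuc"),
                        includeEmpty = FALSE) {
  mode <- match.arg(mode)
  modelIds <- vapply(models, geneId, character(1))
  unknown <- setdiff(names(fragments), modelIds)
  if (length(unknown))
    stop("fragments reference unknown gene(s): ", paste(unknown, collapse = ", "))
  keep <- if (includeEmpty) modelIds else modelIds[modelIds %in% names(fragments)]
  if (length(keep) == 0L) return(.emptyTxTable(genome, mode))
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    m <- models[[match(keep[k], modelIds)]]
    fr <- fragments[[keep[k]]]
    out[[k]] <- .pileupGene(m, fr, genome, mode)
  }
  rbindlist(out)
}

# zero-row table with the schema the mode/genome combination implies
.emptyTxTable <- function(genome, mode) {
  dt <- data.table(chrom = character(0), gencoor = integer(0),
                   strand = character(0), gene = character(0),
                   txcoor = integer(0))
  if (!is.null(genome)) dt[, refSeq := character(0)]
  if (mode %in% c("cov", "covNuc"))
    dt[, c("cov", "start_5p", "end_3p") := integer(0)]
  if (mode %in% c("nucFreq", "covNuc"))
    dt[, (.NUC_COLS) := integer(0)]
  dt[]
}

.pileupGene <- function(model, fr, genome, mode) {
  L <- txLength(model)
  dt <- data.table(
    chrom = txChrom(model),
    gencoor = txToGenomic(model, seq_len(L)),
    strand = txStrand(model),
    gene = geneId(model),
    txcoor = seq_len(L)
  )
  if (!is.null(genome))
    dt[, refSeq := strsplit(transcriptSequence(model, genome), "",
                            fixed = TRUE)[[1]]]
  if (mode %in% c("cov", "covNuc")) {
    if (is.null(fr) || length(fr) == 0L) {
      dt[, c("cov", "start_5p", "end_3p") := 0L]
    } else {
      sp <- fr@spans
      starts <- tabulate(sp$txStart, nbins = L)
      ends <- tabulate(sp$txEnd, nbins = L)
      dt[, start_5p := starts]
      dt[, end_3p := ends]
      dt[, cov := as.integer(cumsum(starts) - c(0L, cumsum(ends)[-L]))]
      setcolorder(dt, c(setdiff(names(dt), .COV_COLS), .COV_COLS))
    }
  }
  if (mode %in% c("nucFreq", "covNuc")) {
    counts <- matrix(0L, nrow = L, ncol = 6L,
                     dimnames = list(NULL, .NUC_COLS))
    if (!is.null(fr) && nrow(fr@calls)) {
      calls <- fr@calls
      bi <- match(calls$base, .BASE_LEVELS)
      okc <- !is.na(bi)
      idx <- calls$pos[okc] + (bi[okc] - 1L) * L
      tab <- tabulate(idx, nbins = 6L * L)
      counts[] <- tab
    }
    dt[, (.NUC_COLS) := as.data.table(counts)]
  }
  dt[]
}

#' Write a per-base table to TSV
#'
#' Tab-separated, header row with the canonical column names, no quoting;
#' missing `refSeq` is serialized as `"."` and other missing values as
#' `"NA"`. The round-trip through [readTxTable()] is lossless.
#'
#' @param table a per-base `data.table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTxTable <- function(table, path) {
  t2 <- copy(table)
  if ("refSeq" %in% names(t2)) t2[is.na(refSeq), refSeq := "."]
  fwrite(t2, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

.KNOWN_EXTRA_PATTERNS <- c(
  "^startRatio$", "^startRatio_1bpDS$", "^endRatio$", "^misincRate$",
  "^MR_[ACGT]to[ACGT]$", "^SRD_", "^MRD_", "_diff$", "^region$",
  "_motif$", "^putative", "_site$"
)

#' Read a per-base table from TSV
#'
#' Accepts shuffled column order (normalized to canonical order on read).
#' Columns that are neither canonical nor recognizable metric columns are
#' an error unless named in `extraCols`.
#'
#' @param path TSV written by [writeTxTable()].
#' @param extraCols character vector of additional column names to accept.
#' @return a `data.table`.
#' @export
readTxTable <- function(path, extraCols = character(0)) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA",
              colClasses = list(character = "chrom"))
  canonical <- c(.COORD_COLS, "refSeq", .COV_COLS, .NUC_COLS)
  known <- names(dt) %in% c(canonical, extraCols) |
    Reduce(`|`, lapply(.KNOWN_EXTRA_PATTERNS, grepl, x = names(dt)))
  if (any(!known))
    stop("unknown column(s) in per-base table: ",
         paste(names(dt)[!known], collapse = ", "))
  core <- canonical[canonical %in% names(dt)]
  setcolorder(dt, c(core, setdiff(names(dt), core)))
  if ("refSeq" %in% names(dt)) {
    dt[, refSeq := as.character(refSeq)]
    dt[refSeq == ".", refSeq := NA_character_]
  }
  for (cl in intersect(c(.COV_COLS, .NUC_COLS, "gencoor", "txcoor"), names(dt)))
    set(dt, j = cl, value = as.integer(dt[[cl]]))
  dt[]
}

#' Concatenate per-base tables of disjoint gene sets
#'
#' @param tables list of per-base `data.table`s built from disjoint gene
#'   sets (a gene appearing twice is an error).
#' @return the row-wise concatenation, preserving per-gene contiguity.
#' @export
concatTxTables <- function(tables) {
  tables <- tables[vapply(tables, nrow, integer(1)) > 0L]
  if (length(tables) == 0L) return(data.table())
  genes <- lapply(tables, function(t) unique(t$gene))
  all <- unlist(genes)
  if (anyDuplicated(all))
    stop("gene(s) present in more than one table: ",
         paste(unique(all[duplicated(all)]), collapse = ", "))
  rbindlist(tables, use.names = TRUE)
}

#' Validate the structural invariants of a per-base table
#'
#' Checks per-gene row contiguity (`txcoor` = 1..L ascending), the
#' coverage bookkeeping identity
#' `cov(i) == cov(i-1) + start_5p(i) - end_3p(i-1)` with
#' `cov(1) == start_5p(1)`, the start/end balance
#' `sum(start_5p) == sum(end_3p)`, and `A+C+G+T+N+del <= cov` when both
#' column groups are present.
#'
#' @param table a per-base `data.table`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validateTxTable <- function(table) {
  for (g in unique(table$gene)) {
    t <- table[gene == g]
    if (!identical(t$txcoor, seq_len(nrow(t))))
      stop("gene ", g, ": txcoor is not 1..L ascending")
    if (all(.COV_COLS %in% names(t))) {
      expectCov <- cumsum(t$start_5p) - c(0L, cumsum(t$end_3p)[-nrow(t)])
      if (!all(t$cov == expectCov))
        stop("gene ", g, ": coverage bookkeeping identity violated")
      if (sum(t$start_5p) != sum(t$end_3p))
        stop("gene ", g, ": sum(start_5p) != sum(end_3p)")
      if (all(.NUC_COLS %in% names(t))) {
        nsum <- rowSums(as.matrix(t[, .NUC_COLS, with = FALSE]))
        if (any(nsum > t$cov))
          stop("gene ", g, ": base-call counts exceed coverage")
      }
    }
  }
  invisible(TRUE)
}
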