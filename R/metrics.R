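.requireCols <- function(table, cols, what) {
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop(what, " requires column(s): ", paste(miss, collapse = ", "))
}

#' Add the start-to-coverage ratio (startRatio)
#'
#' `startRatio(i) = start_5p(i) / cov(i)`; `NA` where coverage is zero.
#' The read-start pileup ratio underlying reverse-transcription-stop
#' based modification detection.
#'
#' @param table a per-base `data.table` with `cov` and `start_5p`.
#' @return a copy of `table` with the `startRatio` column appended.
#' @export
addStartRatio <- function(table) {
  .requireCols(table, c("cov", "start_5p"), "addStartRatio")
  t2 <- copy(table)
  t2[, startRatio := ifelse(cov > 0L, start_5p / cov, NA_real_)]
  t2[]
}

#' Add the start ratio one position downstream (startRatio_1bpDS)
#'
#' The value at position `i` is `startRatio` at position `i + 1` of the
#' same gene (`start_5p(i+1)/cov(i+1)`); the last position of each gene is
#' `NA`. Chemistries that block reverse transcription (CMC-marked
#' pseudouridine, antibody crosslinks at m6A) pile read starts up one
#' nucleotide downstream of the modified base, so this shifted ratio peaks
#' at the modification itself.
#'
#' @inheritParams addStartRatio
#' @return a copy of `table` with the `startRatio_1bpDS` column appended.
#' @export
addStartRatio1bpDS <- function(table) {
  .requireCols(table, c("cov", "start_5p"), "addStartRatio1bpDS")
  t2 <- copy(table)
  t2[, startRatio_1bpDS := shift(ifelse(cov > 0L, start_5p / cov, NA_real_),
                                 n = 1L, type = "lead"), by = gene]
  t2[]
}

#' Add the overall misincorporation rate (misincRate)
#'
#' At each position, the fraction of unambiguous base calls (`A,C,G,T`)
#' that differ from the reference base. `N` and deletions are excluded
#' from numerator and denominator; `NA` where no unambiguous calls exist
#' or where the reference base is not `A/C/G/T`.
#'
#' @param table a per-base `data.table` with `refSeq` and base counts.
#' @param includeDeletions also count deletions as misincorporations
#'   (added to numerator and denominator, for cleavage-style chemistries).
#' @return a copy of `table` with the `misincRate` column appended.
#' @export
addMisincRate <- function(table, includeDeletions = FALSE) {
  .requireCols(table, c("refSeq", .NUC_COLS[1:4]), "addMisincRate")
  t2 <- copy(table)
  m <- as.matrix(t2[, c("A", "C", "G", "T"), with = FALSE])
  denom <- rowSums(m)
  ri <- match(t2$refSeq, c("A", "C", "G", "T"))
  matched <- rep(NA_real_, nrow(t2))
  okr <- !is.na(ri)
  matched[okr] <- m[cbind(which(okr), ri[okr])]
  if (includeDeletions) {
    mis <- (denom - matched) + t2$del
    denom <- denom + t2$del
  } else {
    mis <- denom - matched
  }
  t2[, misincRate := ifelse(okr & denom > 0, mis / denom, NA_real_)]
  t2[]
}

#' Add a base-specific misincorporation rate (e.g. MR_CtoT)
#'
#' At positions whose reference base is `from`: the fraction of
#' unambiguous calls that read `to` (`count(to) / (A+C+G+T)`); `NA`
#' elsewhere. `MR_CtoT` is the detection statistic for chemistries that
#' convert a modified base during reverse transcription (ac4C-seq style
#' C-to-T conversion).
#'
#' @param table a per-base `data.table` with `refSeq` and base counts.
#' @param from,to single reference/read bases in `A,C,G,T`; must differ.
#' @return a copy of `table` with the `MR_<from>to<to>` column appended.
#' @export
addMisincRateSpecific <- function(table, from = "C", to = "T") {
  stopifnot(from %in% c("A", "C", "G", "T"), to %in% c("A", "C", "G", "T"))
  if (from == to) stop("'from' and 'to' bases must differ")
  .requireCols(table, c("refSeq", .NUC_COLS[1:4]), "addMisincRateSpecific")
  t2 <- copy(table)
  denom <- rowSums(as.matrix(t2[, c("A", "C", "G", "T"), with = FALSE]))
  val <- ifelse(t2$refSeq == from & denom > 0, t2[[to]] / denom, NA_real_)
  val[is.na(t2$refSeq) | t2$refSeq != from] <- NA_real_
  t2[, (paste0("MR_", from, "to", to)) := val]
  t2[]
}

#' Add a between-sample difference column (e.g. SRD_1bpDS, MRD_CtoT)
#'
#' Computes `tableA[[column]] - tableB[[column]]` row by row — the
#' treated-minus-control difference metric. The two tables must be
#' row-aligned (same genes in the same order with the same transcript
#' coordinates; unify first if needed). Missing values propagate.
#'
#' @param tableA,tableB row-aligned per-base `data.table`s (e.g. treated
#'   and control samples).
#' @param column name of the numeric column to subtract.
#' @param outName name of the resulting column (e.g. `"SRD_1bpDS"`).
#' @return a copy of `tableA` with `outName` appended.
#' @export
addDiff <- function(tableA, tableB, column, outName) {
  .requireCols(tableA, column, "addDiff")
  .requireCols(tableB, column, "addDiff")
  if (nrow(tableA) != nrow(tableB) ||
      !identical(tableA$gene, tableB$gene) ||
      !identical(tableA$txcoor, tableB$txcoor))
    stop("tables are not row-aligned (unify them first)")
  t2 <- copy(tableA)
  t2[, (outName) := tableA[[column]] - tableB[[column]]]
  t2[]
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

# transcript sequences for every gene of a table, as a named character
# vector: from the refSeq column when complete, else from genome + models
.tableSequences <- function(table, genome = NULL, models = NULL) {
  genes <- unique(table$gene)
  if ("refSeq" %in% names(table) && !anyNA(table$refSeq)) {
    return(vapply(genes, function(g)
      paste(table[gene == g, refSeq], collapse = ""), character(1)))
  }
  if (is.null(genome) || is.null(models))
    stop("transcript sequences unavailable: supply 'genome' and 'models' ",
         "or a table with a complete refSeq column")
  ids <- vapply(models, geneId, character(1))
  miss <- setdiff(genes, ids)
  if (length(miss))
    stop("no model for gene(s): ", paste(miss, collapse = ", "))
  vapply(genes, function(g)
    transcriptSequence(models[[match(g, ids)]], genome), character(1))
}

#' Annotate IUPAC motif presence along transcripts
#'
#' Scans each gene's transcript sequence for a degenerate IUPAC motif
#' (e.g. `"DRACH"` for m6A contexts) and marks positions where the motif,
#' anchored so that its `centerOffset`-th letter sits at the position,
#' matches. Scanning is per transcript and never crosses gene boundaries.
#'
#' @param table a per-base `data.table`.
#' @param motif IUPAC motif string (15-letter DNA alphabet; `U` accepted
#'   and read as `T`).
#' @param genome,models required when the table has no complete `refSeq`.
#' @param centerOffset which motif position is reported as the hit
#'   (default `ceiling(nchar(motif)/2)`, the central letter).
#' @param colName output column name (default `<motif>_motif`).
#' @return a copy of `table` with a logical motif column appended.
#' @export
addMotifPresence <- function(table, motif, genome = NULL, models = NULL,
                             centerOffset = NULL,
                             colName = paste0(motif, "_motif")) {
  letters <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(letters, names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  motif <- chartr("U", "T", toupper(motif))
  len <- nchar(motif)
  if (is.null(centerOffset)) centerOffset <- ceiling(len / 2)
  stopifnot(centerOffset >= 1L, centerOffset <= len)
  seqs <- .tableSequences(table, genome, models)
  t2 <- copy(table)
  t2[, (colName) := FALSE]
  scan <- nchar(seqs) >= len   # motif longer than the transcript: no match
  if (!any(scan)) return(t2[])
  hits <- vector("list", length(seqs))
  hits[scan] <- as.list(vmatchPattern(motif, DNAStringSet(seqs[scan]),
                                      fixed = "subject"))
  for (k in seq_along(seqs)) {
    st <- if (is.null(hits[[k]])) integer(0) else start(hits[[k]])
    if (!length(st)) next
    centers <- st + centerOffset - 1L
    g <- names(seqs)[k]
    t2[gene == g & txcoor %in% centers, (colName) := TRUE]
  }
  t2[]
}

#' Add the transcript region (5'UTR / CDS / 3'UTR) of each position
#'
#' Labels every row of a coding gene with the region its transcript
#' coordinate falls in; rows of noncoding genes get `NA`.
#'
#' @param table a per-base `data.table`.
#' @param models list of [TranscriptModel-class] covering the table genes.
#' @return a copy of `table` with a `region` column appended.
#' @export
addGeneRegion <- function(table, models) {
  ids <- vapply(models, geneId, character(1))
  t2 <- copy(table)
  t2[, region := NA_character_]
  for (g in unique(t2$gene)) {
    i <- match(g, ids)
    if (is.na(i)) stop("no model for gene: ", g)
    m <- models[[i]]
    if (length(cdsRange(m)) == 0L) next
    r <- txRegions(m)
    if (r$utr5[2] >= r$utr5[1])
      t2[gene == g & txcoor >= r$utr5[1] & txcoor <= r$utr5[2],
         region := "5'UTR"]
    t2[gene == g & txcoor >= r$cds[1] & txcoor <= r$cds[2], region := "CDS"]
    if (r$utr3[2] >= r$utr3[1])
      t2[gene == g & txcoor >= r$utr3[1] & txcoor <= r$utr3[2],
         region := "3'UTR"]
  }
  t2[]
}

#' Threshold metric columns into putative sites
#'
#' Evaluates a conjunction of simple predicates over table columns and
#' stores the result as a logical column. Missing values fail every
#' predicate (a position with no data is never called); an empty predicate
#' list marks every row `TRUE`.
#'
#' @param table a per-base `data.table`.
#' @param predicates list of `list(column, op, value)` with `op` one of
#'   `">", ">=", "<", "<=", "==", "!="`; e.g.
#'   `list(list("MRD_CtoT", ">", 0.005))`.
#' @param colName output column name.
#' @return a copy of `table` with the logical site column appended.
#' @export
callSites <- function(table, predicates, colName = "putativeSite") {
  t2 <- copy(table)
  keep <- rep(TRUE, nrow(t2))
  for (p in predicates) {
    col <- p[[1]]; op <- p[[2]]; val <- p[[3]]
    .requireCols(t2, col, "callSites")
    if (!op %in% c(">", ">=", "<", "<=", "==", "!="))
      stop("unsupported comparator: ", op)
    res <- do.call(op, list(t2[[col]], val))
    res[is.na(res)] <- FALSE
    keep <- keep & res
  }
  t2[, (colName) := keep]
  t2[]
}
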