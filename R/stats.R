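#' Restrict a list of per-base tables to their common genes
#'
#' Multi-sample analyses need all tables on identical rows. This keeps
#' the intersection of the gene sets, in the gene order of the first
#' table, so that every output table has identical `gene`/`txcoor` rows.
#' A gene whose transcript length differs between tables indicates an
#' annotation mismatch and is an error.
#'
#' @param tables list of per-base `data.table`s built from the same
#'   annotation.
#' @return list of row-aligned `data.table`s (same length as input).
#' @export
unifyTxTables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  geneSets <- lapply(tables, function(t) unique(t$gene))
  common <- Reduce(intersect, geneSets)
  if (length(common) == 0L) {
    warning("no genes shared by all tables; returning empty tables")
    return(lapply(tables, function(t) t[0L]))
  }
  lens <- lapply(tables, function(t)
    t[gene %in% common, .N, by = gene][order(gene)])
  for (k in seq_along(tables)[-1L]) {
    if (!identical(lens[[1L]]$N, lens[[k]]$N))
      stop("transcript length differs between tables for gene(s): ",
           paste(lens[[1L]]$gene[lens[[1L]]$N != lens[[k]]$N], collapse = ", "))
  }
  ord <- geneSets[[1L]][geneSets[[1L]] %in% common]
  lapply(tables, function(t) {
    t2 <- t[gene %in% common]
    t2[, .ord := match(gene, ord)]
    setorder(t2, .ord, txcoor)
    t2[, .ord := NULL]
    t2[]
  })
}

#' Extract value windows around logically annotated sites
#'
#' For every `TRUE` position of `logicalCol`, takes the values of
#' `valueCol` in the window of half-width `w` centered there. Windows
#' never cross gene boundaries: offsets falling outside the transcript
#' are `NA`.
#'
#' @param table a per-base `data.table`.
#' @param logicalCol name of a logical column marking sites.
#' @param valueCol name of the numeric column to extract.
#' @param w window half-width; the result has `2*w + 1` columns.
#' @return numeric matrix, one row per site (rownames `gene:txcoor`),
#'   columns named by offset `-w..+w`; attribute `sites` holds a
#'   `data.table` of the site coordinates.
#' @export
getFlanksFromLogical <- function(table, logicalCol, valueCol, w) {
  .requireCols(table, c(logicalCol, valueCol), "getFlanksFromLogical")
  sites <- table[table[[logicalCol]] %in% TRUE, .(gene, txcoor)]
  offs <- -w:w
  mat <- matrix(NA_real_, nrow = nrow(sites), ncol = 2L * w + 1L,
                dimnames = list(
                  if (nrow(sites)) paste0(sites$gene, ":", sites$txcoor),
                  offs))
  if (nrow(sites) == 0L) {
    attr(mat, "sites") <- sites
    return(mat)
  }
  vals <- split(table[[valueCol]], table$gene)
  for (i in seq_len(nrow(sites))) {
    v <- vals[[sites$gene[i]]]
    idx <- sites$txcoor[i] + offs
    ok <- idx >= 1L & idx <= length(v)
    mat[i, ok] <- v[idx[ok]]
  }
  attr(mat, "sites") <- sites
  mat
}

# bin index of positions 1..L split into b equal-width intervals
.binIndex <- function(L, b) floor((seq_len(L) - 1L) * b / L) + 1L

#' Metagene matrix over gene regions
#'
#' Bins each coding gene's 5'UTR, CDS and 3'UTR into `bins[1]`, `bins[2]`
#' and `bins[3]` equal-width position intervals (computed per gene from
#' its own region boundaries) and aggregates `valueCol` within each bin.
#' Genes without a CDS are skipped; a bin with no positions (region
#' shorter than its bin count) is `NA`. With a logical/0-1 `valueCol` and
#' `aggregate = "sum"`, cells are per-bin site counts — the data behind
#' metagene site-density profiles.
#'
#' @param table a per-base `data.table` with a `region` column (see
#'   [addGeneRegion()]) or `models` to derive it.
#' @param valueCol name of the column to aggregate (logicals are used as
#'   0/1).
#' @param bins integer triple: bins for 5'UTR, CDS, 3'UTR.
#' @param aggregate `"mean"` or `"sum"`.
#' @param models optional list of [TranscriptModel-class], used to add
#'   the `region` column if absent.
#' @return numeric matrix, one row per coding gene, `sum(bins)` columns
#'   named `utr5_*`, `cds_*`, `utr3_*`.
#' @export
getMetageneRegions <- function(table, valueCol, bins = c(10L, 40L, 25L),
                               aggregate = c("mean", "sum"), models = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(bins) == 3L, all(bins >= 1L))
  if (!"region" %in% names(table)) {
    if (is.null(models))
      stop("table has no 'region' column; supply 'models'")
    table <- addGeneRegion(table, models)
  }
  .requireCols(table, valueCol, "getMetageneRegions")
  agg <- if (aggregate == "mean") {
    function(x) mean(x)
  } else function(x) sum(x)
  regions <- c("5'UTR", "CDS", "3'UTR")
  colNames <- c(paste0("utr5_", seq_len(bins[1])),
                paste0("cds_", seq_len(bins[2])),
                paste0("utr3_", seq_len(bins[3])))
  genes <- unique(table$gene)
  rows <- list()
  for (g in genes) {
    t <- table[gene == g]
    if (!any(t$region %in% "CDS")) next
    row <- numeric(0)
    for (r in seq_along(regions)) {
      v <- as.numeric(t[region %in% regions[r]][[valueCol]])
      b <- bins[r]
      cell <- rep(NA_real_, b)
      if (length(v)) {
        bi <- .binIndex(length(v), b)
        for (j in unique(bi)) cell[j] <- agg(v[bi == j])
      }
      row <- c(row, cell)
    }
    rows[[g]] <- row
  }
  mat <- do.call(rbind, rows)
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = 0L, ncol = sum(bins))
  colnames(mat) <- colNames
  mat
}

#' Position frequency matrix around annotated sites
#'
#' Counts the reference base at each offset in a window around each site,
#' over all sites — the data behind a sequence logo. Offsets that leave
#' the transcript contribute nothing, so each column sums to the number
#' of sites whose window covers that offset.
#'
#' @param table a per-base `data.table`.
#' @param sites either the name of a logical column of `table`, or a
#'   `data.frame`/`data.table` with columns `gene` and `txcoor`.
#' @param w window half-width.
#' @param genome,models required when the table has no complete `refSeq`.
#' @return integer matrix with rows `A,C,G,T` and columns `-w..+w`.
#' @export
pfmFromSites <- function(table, sites, w, genome = NULL, models = NULL) {
  if (is.character(sites) && length(sites) == 1L) {
    .requireCols(table, sites, "pfmFromSites")
    sites <- table[table[[sites]] %in% TRUE, .(gene, txcoor)]
  } else {
    sites <- as.data.table(sites)[, .(gene, txcoor)]
  }
  seqs <- .tableSequences(table, genome, models)
  offs <- -w:w
  pfm <- matrix(0L, nrow = 4L, ncol = 2L * w + 1L,
                dimnames = list(c("A", "C", "G", "T"), offs))
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$gene[i]]]
    idx <- sites$txcoor[i] + offs
    ok <- idx >= 1L & idx <= nchar(s)
    b <- substring(s, idx[ok], idx[ok])
    ri <- match(b, rownames(pfm))
    use <- !is.na(ri)
    ci <- which(ok)[use]
    for (k in seq_along(ci)) pfm[ri[use][k], ci[k]] <- pfm[ri[use][k], ci[k]] + 1L
  }
  pfm
}

#' Row-wise two-sample t-tests across replicate tables
#'
#' Tests, at every transcript position, whether the mean of `valueCol`
#' differs between two groups of replicate tables (e.g. wild-type vs
#' knockout `startRatio_1bpDS`). All tables must be row-aligned (see
#' [unifyTxTables()]). Rows where any replicate is missing give missing
#' results. With zero within-group variance and a nonzero difference the
#' statistic is `+/-Inf` with p = 0; a zero difference always gives
#' statistic 0, p = 1.
#'
#' @param tablesGroup1,tablesGroup2 lists of at least two row-aligned
#'   per-base `data.table`s each.
#' @param valueCol name of the numeric column to test.
#' @param variance `"pooled"` (default) or `"welch"`.
#' @return `data.table` with `gene`, `txcoor`, `meanDiff` (group1 -
#'   group2), `statistic`, `df`, `p`, `n1`, `n2`.
#' @export
rowTtests <- function(tablesGroup1, tablesGroup2, valueCol,
                      variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  n1 <- length(tablesGroup1); n2 <- length(tablesGroup2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 replicate tables")
  .checkAligned(c(tablesGroup1, tablesGroup2))
  nr <- nrow(tablesGroup1[[1]])
  x <- matrix(vapply(tablesGroup1, function(t) as.numeric(t[[valueCol]]),
                     numeric(nr)), nrow = nr)
  y <- matrix(vapply(tablesGroup2, function(t) as.numeric(t[[valueCol]]),
                     numeric(nr)), nrow = nr)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- .rowVar(x, m1); v2 <- .rowVar(y, m2)
  d <- m1 - m2
  if (variance == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- d / se
  stat[d == 0] <- 0
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  p[d == 0] <- 1
  p[is.infinite(stat)] <- 0
  bad <- is.na(d)
  stat[bad] <- NA_real_; p[bad] <- NA_real_; df[bad] <- NA_real_
  data.table(gene = tablesGroup1[[1]]$gene,
             txcoor = tablesGroup1[[1]]$txcoor,
             meanDiff = d, statistic = stat, df = df, p = p,
             n1 = n1, n2 = n2)
}

.rowVar <- function(m, mu) rowSums((m - mu)^2) / (ncol(m) - 1)

.checkAligned <- function(tables) {
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (nrow(t) != nrow(ref) || !identical(t$gene, ref$gene) ||
        !identical(t$txcoor, ref$txcoor))
      stop("tables are not row-aligned; run unifyTxTables() first")
  }
}

# binomial log-likelihood with the 0*log(0) = 0 convention
.llBinom <- function(k, n, p) {
  t1 <- ifelse(k > 0, k * log(p), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log1p(-p), 0)
  t1 + t2
}

#' Row-wise binomial likelihood-ratio tests on count ratios
#'
#' Compares a per-position proportion (e.g. read-starts over coverage, or
#' converted-base calls over total calls) between two groups of replicate
#' tables. Counts are summed within each group; the test is a one-degree
#' likelihood ratio of per-group binomial proportions against the pooled
#' proportion, with p-values from the chi-square distribution. Rows with
#' zero trials in either group are missing. Boundary proportions (0 or 1)
#' use the `0*log(0) = 0` convention, so the statistic is always finite
#' and non-negative.
#'
#' @param tablesGroup1,tablesGroup2 lists of row-aligned per-base tables.
#' @param successesCol,trialsCol names of the count columns, with
#'   successes <= trials row-wise.
#' @return `data.table` with `gene`, `txcoor`, `propDiff` (group1 -
#'   group2 proportion), `statistic`, `df`, `p`, `n1`, `n2` (summed
#'   trials per group).
#' @export
rowBinomialLRT <- function(tablesGroup1, tablesGroup2,
                           successesCol, trialsCol) {
  .checkAligned(c(tablesGroup1, tablesGroup2))
  sumCol <- function(tabs, col)
    Reduce(`+`, lapply(tabs, function(t) as.numeric(t[[col]])))
  k1 <- sumCol(tablesGroup1, successesCol)
  t1 <- sumCol(tablesGroup1, trialsCol)
  k2 <- sumCol(tablesGroup2, successesCol)
  t2 <- sumCol(tablesGroup2, trialsCol)
  if (any(k1 > t1, na.rm = TRUE) || any(k2 > t2, na.rm = TRUE))
    stop("successes exceed trials at some positions")
  ok <- !is.na(t1) & !is.na(t2) & t1 > 0 & t2 > 0
  p1 <- ifelse(ok, k1 / t1, NA_real_)
  p2 <- ifelse(ok, k2 / t2, NA_real_)
  p0 <- ifelse(ok, (k1 + k2) / (t1 + t2), NA_real_)
  stat <- 2 * (.llBinom(k1, t1, p1) + .llBinom(k2, t2, p2) -
                 .llBinom(k1, t1, p0) - .llBinom(k2, t2, p0))
  stat <- pmax(stat, 0)
  stat[!ok] <- NA_real_
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  data.table(gene = tablesGroup1[[1]]$gene,
             txcoor = tablesGroup1[[1]]$txcoor,
             propDiff = p1 - p2, statistic = stat, df = 1L, p = p,
             n1 = t1, n2 = t2)
}

# centered moving average of width w (odd), truncated at the edges
.smoothMA <- function(x, w) {
  if (w <= 1L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call coverage peaks per gene
#'
#' Smooths the chosen coverage column with a centered, edge-truncated
#' moving average, takes strict local maxima at or above `minCov`, and
#' merges candidates closer than `minGap` keeping the highest (ties go to
#' the leftmost). Used to contrast peak centering between bridged
#' (paired) and single-end processing of the same library.
#'
#' @param table a per-base `data.table`.
#' @param covCol name of the numeric column to scan (default `"cov"`).
#' @param smoothW moving-average width in nucleotides (1 = no smoothing).
#' @param minCov minimum smoothed height for a candidate peak.
#' @param minGap candidates closer than this many nucleotides are merged.
#' @return `data.table` with `gene`, `txcoor` (peak center), `height`
#'   (smoothed value at the center).
#' @export
callPeaks <- function(table, covCol = "cov", smoothW = 5L, minCov = 10,
                      minGap = 20L) {
  .requireCols(table, covCol, "callPeaks")
  out <- list()
  for (g in unique(table$gene)) {
    x <- as.numeric(table[gene == g][[covCol]])
    s <- .smoothMA(x, smoothW)
    n <- length(s)
    if (n == 0L) next
    left <- c(-Inf, s[-n])
    right <- c(s[-1L], -Inf)
    cand <- which(s > left & s > right & s >= minCov)
    if (!length(cand)) next
    # greedy accept by height (ties leftmost), enforcing the gap
    o <- order(-s[cand], cand)
    accepted <- integer(0)
    for (i in cand[o]) {
      if (!length(accepted) || all(abs(accepted - i) >= minGap))
        accepted <- c(accepted, i)
    }
    accepted <- sort(accepted)
    out[[g]] <- data.table(gene = g, txcoor = accepted, height = s[accepted])
  }
  if (!length(out))
    return(data.table(gene = character(0), txcoor = integer(0),
                      height = numeric(0)))
  rbindlist(out)
}

#' Subsample a per-base table by gene
#'
#' Keeps the rows of `n` genes drawn without replacement, deterministic
#' under `seed`; useful for prototyping a pipeline on a transcriptome
#' subset. The caller's RNG state is left untouched.
#'
#' @param table a per-base `data.table`.
#' @param n number of genes to keep (`0 <= n <=` number of genes).
#' @param seed integer seed for reproducible draws.
#' @return the subsetted `data.table` (gene order as in `table`).
#' @export
sampleGenes <- function(table, n, seed = 1L) {
  genes <- unique(table$gene)
  if (n > length(genes)) stop("n exceeds the number of genes (", length(genes), ")")
  if (n == 0L) return(table[0L])
  pick <- .withSeed(seed, sample(genes, n))
  table[gene %in% pick]
}
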