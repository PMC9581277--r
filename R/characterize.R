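#' @importFrom Biostrings letterFrequency
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom stats quantile wilcox.test cor median setNames
NULL

#' GC content of a DNA sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the
#' denominator. GC content is strand-symmetric, so the plus-strand
#' extraction suffices.
#'
#' @param seq a character vector, `DNAString`, or `DNAStringSet`.
#' @return numeric fraction(s) in `[0, 1]`; `NA` for all-`N` sequences.
#' @examples
#' gcContent("ANGC")  # 2/3
#' @export
gcContent <- function(seq) {
  if (!is(seq, "DNAStringSet")) {
    seq <- Biostrings::DNAStringSet(as.character(seq))
  }
  f <- Biostrings::letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- rowSums(f)
  out <- ifelse(denom == 0, NA_real_, (f[, "G"] + f[, "C"]) / denom)
  stats::setNames(as.numeric(out), names(seq))
}

# TMM factor of one library against the reference (trimmed, precision-
# weighted mean of log2 ratios)
tmmPairFactor <- function(obs, ref, nO, nR,
                          logratioTrim = 0.30, sumTrim = 0.05) {
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / nO / obs + (nR - ref) / nR / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR)) {
    warning("no genes expressed in both libraries; TMM factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
          (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample normalization factors following Robinson & Oshlack:
#' the reference library is the sample whose library-size-normalized
#' upper quartile is closest to the mean upper quartile; for every sample,
#' log2 ratios (M) and average log abundances (A) against the reference
#' are computed over genes expressed in both, the most extreme 30% of M
#' and 5% of A are trimmed two-sided, and the factor is two to the
#' precision-weighted mean of the remaining M values. Factors are rescaled
#' to geometric mean 1. All-zero rows are dropped before computation.
#'
#' @param counts raw count matrix (genes x samples, >= 2 samples).
#' @param logratioTrim,sumTrim two-sided trim fractions for M and A
#'   (defaults 0.30 and 0.05, the standard parameterization).
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmmFactors <- function(counts, logratioTrim = 0.30, sumTrim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  libSize <- colSums(counts)
  if (any(libSize == 0)) stop("empty library (all-zero sample)")
  keep <- rowSums(counts > 0) > 0
  x <- counts[keep, , drop = FALSE]
  f75 <- apply(x, 2, function(col) stats::quantile(col, 0.75)) / libSize
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    tmmPairFactor(x[, j], x[, ref], libSize[j], libSize[ref],
                  logratioTrim = logratioTrim, sumTrim = sumTrim)
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' FPKM from raw counts
#'
#' `FPKM(i, j) = counts(i, j) * 1e9 / (length_i * libsize_j * factor_j)`,
#' i.e. fragments per kilobase of transcript per million reads of the
#' TMM-adjusted (effective) library.
#'
#' @param counts raw count matrix.
#' @param lengths named transcript lengths in nt (> 0), covering all rows.
#' @param factors per-sample normalization factors (default: TMM via
#'   [tmmFactors()]).
#' @param libSize per-sample library sizes (default: column sums of
#'   `counts`).
#' @return numeric FPKM matrix, same dimnames as `counts`.
#' @examples
#' fpkmMatrix(matrix(10, 1, 2, dimnames = list("t", c("a", "b"))),
#'   lengths = c(t = 1000), factors = c(a = 1, b = 1),
#'   libSize = c(a = 1e6, b = 1e6))  # 10
#' @export
fpkmMatrix <- function(counts, lengths, factors = tmmFactors(counts),
                       libSize = colSums(counts)) {
  counts <- as.matrix(counts)
  len <- lengths[rownames(counts)]
  if (anyNA(len)) {
    stop("missing length for: ",
         paste(utils::head(rownames(counts)[is.na(len)], 5), collapse = ", "))
  }
  if (any(len <= 0)) stop("transcript lengths must be > 0")
  if (any(factors <= 0)) stop("normalization factors must be > 0")
  eff <- libSize * factors[colnames(counts)]
  t(t(counts) / eff) / (len / 1e3) * 1e6
}

#' Build an expression container (counts + TMM-normalized FPKM)
#'
#' Bundles counts, TMM factors, FPKM, transcript lengths and the tissue
#' design into a [SummarizedExperiment::SummarizedExperiment].
#'
#' @param counts raw count matrix.
#' @param design data.frame with `sample_id`, `tissue` covering the count
#'   columns.
#' @param lengths named transcript lengths in nt.
#' @return a `SummarizedExperiment` with assays `counts` and `fpkm`,
#'   `colData` columns `sample_id`, `tissue`, `lib_size`, `tmm_factor`,
#'   and `rowData` column `length`.
#' @export
buildExpression <- function(counts, design, lengths) {
  counts <- as.matrix(counts)
  miss <- setdiff(colnames(counts), design$sample_id)
  if (length(miss)) stop("samples in counts missing from design: ",
                         paste(miss, collapse = ", "))
  design <- design[match(colnames(counts), design$sample_id), ]
  fac <- tmmFactors(counts)
  libSize <- colSums(counts)
  fpkm <- fpkmMatrix(counts, lengths, factors = fac, libSize = libSize)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, fpkm = fpkm),
    colData = S4Vectors::DataFrame(
      sample_id = design$sample_id, tissue = design$tissue,
      lib_size = libSize, tmm_factor = fac, row.names = design$sample_id),
    rowData = S4Vectors::DataFrame(length = lengths[rownames(counts)])
  )
}

#' Tissue-level FPKM (replicate means)
#'
#' @param se expression `SummarizedExperiment` from [buildExpression()].
#' @param stat `"mean"` (default) or `"median"` across a tissue's
#'   replicates.
#' @return matrix transcripts x tissues.
#' @export
tissueMeanFpkm <- function(se, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- SummarizedExperiment::assay(se, "fpkm")
  tissue <- SummarizedExperiment::colData(se)$tissue
  agg <- vapply(unique(tissue), function(t) {
    m <- f[, tissue == t, drop = FALSE]
    if (stat == "mean") rowMeans(m) else apply(m, 1, stats::median)
  }, numeric(nrow(f)))
  colnames(agg) <- unique(tissue)
  agg
}

#' Per-transcript feature table
#'
#' Computes, for every transcript, the features compared between lncRNAs
#' and mRNAs: spliced length, exon count, exon and intron lengths, GC
#' content of the spliced sequence, and mean FPKM.
#'
#' @param ts a [TranscriptSet-class].
#' @param seqs genome `DNAStringSet`.
#' @param fpkm optional FPKM matrix; mean over samples is reported.
#' @return a data.frame with scalar columns (`transcript_id`, `length`,
#'   `n_exons`, `gc`, `mean_fpkm`) and list columns `exon_lengths`,
#'   `intron_lengths`.
#' @export
featureTable <- function(ts, seqs, fpkm = NULL) {
  ex <- txExons(ts)
  exLen <- lapply(seq_along(ex), function(k) GenomicRanges::width(ex[[k]]))
  inLen <- lapply(seq_along(ex), function(k) {
    st <- GenomicRanges::start(ex[[k]]); en <- GenomicRanges::end(ex[[k]])
    if (length(st) < 2L) integer(0) else st[-1] - en[-length(en)] - 1L
  })
  # GC is strand-symmetric: force plus-strand extraction so unknown-strand
  # transcripts are still measurable
  plus <- ts
  ex0 <- plus@exons
  strand(ex0) <- "+"
  plus@exons <- ex0
  gc <- gcContent(spliceTranscriptSeq(plus, seqs))
  mf <- rep(NA_real_, length(ts))
  if (!is.null(fpkm)) {
    row <- match(txIds(ts), rownames(fpkm))
    mf[!is.na(row)] <- rowMeans(fpkm[row[!is.na(row)], , drop = FALSE])
  }
  out <- data.frame(
    transcript_id = txIds(ts),
    length = unname(txLengths(ts)),
    n_exons = S4Vectors::elementNROWS(ex),
    gc = unname(gc),
    mean_fpkm = mf,
    stringsAsFactors = FALSE
  )
  out$exon_lengths <- I(exLen)
  out$intron_lengths <- I(inLen)
  out
}

#' Compare feature distributions between two transcript groups
#'
#' For each feature (transcript length, exon count, pooled exon length,
#' pooled intron length, GC content, log2 FPKM with pseudocount) reports
#' deciles and means per group and a two-sample Wilcoxon rank-sum p-value.
#'
#' @param lncTab,mrnaTab feature tables from [featureTable()].
#' @param pseudocount added to FPKM before log2 (default 0.01).
#' @return a long data.frame: `feature`, `group`, `mean`, `q10`..`q90`
#'   deciles and `wilcox_p` (repeated within feature).
#' @export
compareGroups <- function(lncTab, mrnaTab, pseudocount = 0.01) {
  if (!nrow(lncTab) || !nrow(mrnaTab)) stop("both groups must be non-empty")
  pull <- function(tab, feat) {
    switch(feat,
      length = tab$length,
      n_exons = tab$n_exons,
      exon_length = unlist(tab$exon_lengths),
      intron_length = unlist(tab$intron_lengths),
      gc = tab$gc[!is.na(tab$gc)],
      log2_fpkm = log2(tab$mean_fpkm[!is.na(tab$mean_fpkm)] + pseudocount))
  }
  feats <- c("length", "n_exons", "exon_length", "intron_length", "gc",
             "log2_fpkm")
  rows <- list()
  for (f in feats) {
    a <- pull(lncTab, f); b <- pull(mrnaTab, f)
    if (!length(a) || !length(b)) next
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    qs <- seq(0.1, 0.9, by = 0.1)
    for (g in c("lncRNA", "mRNA")) {
      v <- if (g == "lncRNA") a else b
      row <- data.frame(feature = f, group = g, n = length(v),
                        mean = mean(v), wilcox_p = p,
                        stringsAsFactors = FALSE)
      qv <- stats::quantile(v, qs)
      row[paste0("q", qs * 100)] <- as.list(qv)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Genome-bin distribution of lncRNAs and mRNAs
#'
#' Splits every scaffold into fixed-size bins from position 1 and counts
#' transcripts per bin; a transcript is assigned to the bin containing its
#' leftmost genomic coordinate, so bin 1 is `[1, binSize]`. Pooled and
#' per-strand counts are reported.
#'
#' @param lnc,coding [TranscriptSet-class] objects.
#' @param binSize bin width in nt (default 50000).
#' @param seqLengths optional named scaffold lengths; when given, empty
#'   trailing bins up to the scaffold end are included.
#' @return a data.frame with `seqid`, `bin`, `lnc_count`, `mrna_count`,
#'   `lnc_plus`, `lnc_minus`, `mrna_plus`, `mrna_minus`.
#' @export
binDistribution <- function(lnc, coding, binSize = 50000L,
                            seqLengths = NULL) {
  stopifnot(binSize > 0)
  binOf <- function(ts) {
    sp <- txSpans(ts)
    data.frame(seqid = as.character(GenomicRanges::seqnames(sp)),
               bin = (GenomicRanges::start(sp) - 1L) %/% binSize + 1L,
               strand = unname(txStrand(ts)),
               stringsAsFactors = FALSE)
  }
  a <- binOf(lnc); b <- binOf(coding)
  seqids <- sort(unique(c(a$seqid, b$seqid, names(seqLengths))))
  grid <- do.call(rbind, lapply(seqids, function(s) {
    hi <- max(1L, a$bin[a$seqid == s], b$bin[b$seqid == s])
    if (!is.null(seqLengths) && s %in% names(seqLengths)) {
      hi <- max(hi, (seqLengths[[s]] - 1L) %/% binSize + 1L)
    }
    data.frame(seqid = s, bin = seq_len(hi), stringsAsFactors = FALSE)
  }))
  cnt <- function(d, sel = TRUE) {
    d <- d[sel, , drop = FALSE]
    key <- paste(d$seqid, d$bin)
    as.integer(table(factor(key, levels = paste(grid$seqid, grid$bin))))
  }
  grid$lnc_count <- cnt(a)
  grid$mrna_count <- cnt(b)
  grid$lnc_plus <- cnt(a, a$strand == "+")
  grid$lnc_minus <- cnt(a, a$strand == "-")
  grid$mrna_plus <- cnt(b, b$strand == "+")
  grid$mrna_minus <- cnt(b, b$strand == "-")
  grid
}

#' Correlation of lncRNA and mRNA genome-bin densities
#'
#' @param profile data.frame from [binDistribution()].
#' @return a data.frame with one row per scaffold plus a pooled `"all"`
#'   row: `seqid`, `n_bins`, `pearson_r` (`NA` where a count vector is
#'   constant).
#' @export
binCorrelation <- function(profile) {
  one <- function(d, label) {
    r <- if (stats::sd(d$lnc_count) == 0 || stats::sd(d$mrna_count) == 0) {
      NA_real_
    } else {
      stats::cor(d$lnc_count, d$mrna_count)
    }
    data.frame(seqid = label, n_bins = nrow(d), pearson_r = r,
               stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, lapply(split(profile, profile$seqid), function(d) {
    one(d, d$seqid[1])
  }))
  rbind(per[order(per$seqid), ], one(profile, "all"))
}
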