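#' Longest complete open reading frame
#'
#' Scans the three forward frames of a spliced, strand-resolved transcript
#' sequence for complete ORFs (an `ATG` followed by an in-frame stop codon
#' `TAA`/`TAG`/`TGA` with no earlier in-frame stop) and returns the length
#' in amino acids of the longest one, counting the start codon and
#' excluding the stop. Codons containing `N` match neither start nor stop.
#' Only forward frames are scanned because [spliceTranscriptSeq()] already
#' resolves the strand.
#'
#' @param seq a DNA string (character or [Biostrings::DNAString]) over
#'   `A,C,G,T,N`.
#' @return integer amino-acid length; `0` if the sequence contains no
#'   complete ORF (including the empty sequence).
#' @examples
#' longestOrf("ATGAAATAG")  # 2 (Met, Lys, stop)
#' longestOrf("CCCCCCCCC")  # 0
#' @export
longestOrf <- function(seq) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (is.na(L) || L < 6L) return(0L)
  best <- 0L
  for (off in 0:2) {
    ncod <- (L - off) %/% 3L
    if (ncod < 2L) next
    at <- off + 3L * (seq_len(ncod) - 1L) + 1L
    cod <- substring(seq, at, at + 2L)
    si <- which(cod == "ATG")
    if (!length(si)) next
    pi <- which(cod == "TAA" | cod == "TAG" | cod == "TGA")
    if (!length(pi)) next
    # first in-frame stop strictly after each start
    idx <- findInterval(si, pi) + 1L
    ok <- idx <= length(pi)
    if (!any(ok)) next
    aa <- pi[idx[ok]] - si[ok]
    best <- max(best, max(aa))
  }
  as.integer(best)
}

#' Built-in coding-potential score
#'
#' A simple ORF-coverage heuristic standing in for external coding-potential
#' classifiers when no imported evidence is available: the fraction of the
#' transcript covered by its longest complete ORF (stop codon included),
#' `(3 * aa + 3) / length`, clipped to `[0, 1]`; `0` when no ORF exists.
#' Transcripts scoring above the threshold (default 0.5 in
#' [filterCoding()]) are flagged coding. Imported evidence tables, when
#' provided, always take precedence.
#'
#' @param seq a DNA string.
#' @return a score in `[0, 1]`.
#' @examples
#' builtinCodingScore(paste0("ATG", strrep("GCA", 99), "TAA"))  # 1.0
#' @export
builtinCodingScore <- function(seq) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L == 0L) return(0)
  aa <- longestOrf(seq)
  if (aa == 0L) return(0)
  min(1, (3 * aa + 3) / L)
}

#' Assemble a per-transcript coding-evidence table
#'
#' Computes the longest-ORF length and built-in coding score from spliced
#' sequences and merges imported external verdicts (blastx, Pfam, CPC2,
#' RNAplonc) where available.
#'
#' @param ts a [TranscriptSet-class] (known strands).
#' @param seqs genome `DNAStringSet`.
#' @param imported optional evidence data.frame from [readEvidenceTsv()].
#' @return a data.frame with columns `transcript_id`, `longest_orf_aa`,
#'   `builtin_score`, and one column per source with values
#'   `coding`/`noncoding`/`absent`.
#' @export
codingEvidenceTable <- function(ts, seqs, imported = NULL) {
  sp <- spliceTranscriptSeq(ts, seqs)
  sc <- as.character(sp)
  orf <- vapply(sc, longestOrf, integer(1), USE.NAMES = FALSE)
  len <- nchar(sc)
  score <- ifelse(orf == 0L, 0, pmin(1, (3 * orf + 3) / len))
  n <- length(ts)
  ev <- data.frame(
    transcript_id = txIds(ts),
    longest_orf_aa = orf,
    builtin_score = score,
    blastx = rep("absent", n), pfam = rep("absent", n),
    cpc2 = rep("absent", n), rnaplonc = rep("absent", n),
    stringsAsFactors = FALSE
  )
  if (!is.null(imported) && nrow(imported)) {
    for (src in c("blastx", "pfam", "cpc2", "rnaplonc")) {
      rows <- imported[imported$source == src, ]
      hit <- match(ev$transcript_id, rows$transcript_id)
      ev[[src]][!is.na(hit)] <- rows$verdict[hit[!is.na(hit)]]
    }
  }
  ev
}

newFunnelStep <- function(step, survivors, removed, reasons) {
  list(step = step, survivors = survivors,
       removed = removed, reasons = reasons)
}

#' Structural filter: length, exon count, strand
#'
#' First step of the identification cascade: keeps multi-exon transcripts
#' at least `minLen` nt long (inclusive) with known strand; removes the
#' rest, recording a reason per removed transcript (`short`,
#' `single_exon`, `no_strand`; the first violated rule is recorded).
#'
#' @param ts candidate [TranscriptSet-class].
#' @param minLen minimum spliced length in nt (default 200, inclusive).
#' @param minExons minimum exon count (default 2).
#' @return a funnel step: list with `step`, `survivors` (a `TranscriptSet`),
#'   `removed` (character ids), `reasons` (named character).
#' @export
filterStructure <- function(ts, minLen = 200L, minExons = 2L) {
  len <- txLengths(ts)
  nex <- S4Vectors::elementNROWS(txExons(ts))
  str <- txStrand(ts)
  reason <- rep(NA_character_, length(ts))
  reason[str == "*"] <- "no_strand"
  reason[is.na(reason) & nex < minExons] <- "single_exon"
  reason[is.na(reason) & len < minLen] <- "short"
  drop <- !is.na(reason)
  newFunnelStep("structure", ts[!drop], txIds(ts)[drop],
                stats::setNames(reason[drop], txIds(ts)[drop]))
}

#' Exonic-overlap filter against coding genes
#'
#' Removes candidates with at least 1 bp of exonic overlap with any
#' coding-gene exon on the same strand (default). Opposite-strand exonic
#' overlaps are retained — they feed the antisense class downstream. Set
#' `strandMode = "both"` to remove overlaps regardless of strand.
#'
#' @param ts candidate [TranscriptSet-class].
#' @param coding [TranscriptSet-class] of coding transcripts.
#' @param strandMode `"same"` (default) or `"both"`.
#' @return a funnel step (see [filterStructure()]).
#' @export
filterExonOverlap <- function(ts, coding, strandMode = c("same", "both")) {
  strandMode <- match.arg(strandMode)
  codEx <- BiocGenerics::unlist(txExons(coding), use.names = FALSE)
  nex <- S4Vectors::elementNROWS(txExons(ts))
  u <- BiocGenerics::unlist(txExons(ts), use.names = FALSE)
  hits <- GenomicRanges::findOverlaps(
    u, codEx, minoverlap = 1L,
    ignore.strand = identical(strandMode, "both"))
  hitTx <- unique(rep(txIds(ts), nex)[S4Vectors::queryHits(hits)])
  drop <- txIds(ts) %in% hitTx
  newFunnelStep("exon_overlap", ts[!drop], txIds(ts)[drop],
                stats::setNames(rep("coding_exon_overlap", sum(drop)),
                                txIds(ts)[drop]))
}

#' Coding-potential filter
#'
#' Removes candidates whose longest complete ORF is `>= maxOrfAa` amino
#' acids (strict `< 100 aa` retained at the default), then candidates any
#' of whose imported tool verdicts is `coding`; candidates with no imported
#' evidence fall back to the built-in coding score flag
#' (`builtin_score > builtinThreshold`).
#'
#' @param ts candidate [TranscriptSet-class].
#' @param evidence data.frame from [codingEvidenceTable()]; must cover
#'   every candidate.
#' @param maxOrfAa ORF cutoff in aa (default 100; transcripts with
#'   `longest_orf_aa >= maxOrfAa` are removed).
#' @param builtinThreshold built-in score above which a candidate with no
#'   imported evidence is flagged coding (default 0.5).
#' @param fallback use the built-in score when imported evidence is absent
#'   (default `TRUE`); with `fallback = FALSE`, a candidate with no
#'   evidence row at all is an error.
#' @return a funnel step; removal reasons are `orf`, one of the source
#'   names, or `builtin_score`.
#' @export
filterCoding <- function(ts, evidence, maxOrfAa = 100L,
                         builtinThreshold = 0.5, fallback = TRUE) {
  ids <- txIds(ts)
  row <- match(ids, evidence$transcript_id)
  if (anyNA(row)) {
    stop("missing coding evidence for: ",
         paste(utils::head(ids[is.na(row)], 5), collapse = ", "))
  }
  ev <- evidence[row, ]
  reason <- rep(NA_character_, length(ids))
  reason[ev$longest_orf_aa >= maxOrfAa] <- "orf"
  srcs <- c("blastx", "pfam", "cpc2", "rnaplonc")
  hasImported <- Reduce(`|`, lapply(srcs, function(s) ev[[s]] != "absent"))
  for (s in srcs) {
    sel <- is.na(reason) & ev[[s]] == "coding"
    reason[sel] <- s
  }
  noEv <- !hasImported
  if (any(noEv) && !fallback) {
    stop("no imported evidence and fallback disabled for: ",
         paste(utils::head(ids[noEv], 5), collapse = ", "))
  }
  if (fallback) {
    sel <- is.na(reason) & noEv & ev$builtin_score > builtinThreshold
    reason[sel] <- "builtin_score"
  }
  drop <- !is.na(reason)
  newFunnelStep("coding_potential", ts[!drop], ids[drop],
                stats::setNames(reason[drop], ids[drop]))
}

#' Read-support filter
#'
#' Keeps candidates supported by at least `minReads` raw reads summed over
#' all samples (inclusive: a total of exactly `minReads` is kept).
#'
#' @param ts candidate [TranscriptSet-class].
#' @param counts raw count matrix (rows = transcripts); every candidate
#'   must have a row.
#' @param minReads minimum total raw count (default 6).
#' @return a funnel step; survivors carry their totals in `readSupport()`.
#' @export
filterReadSupport <- function(ts, counts, minReads = 6L) {
  ids <- txIds(ts)
  row <- match(ids, rownames(counts))
  if (anyNA(row)) {
    stop("candidates absent from count matrix: ",
         paste(utils::head(ids[is.na(row)], 5), collapse = ", "))
  }
  tot <- rowSums(counts[row, , drop = FALSE])
  keep <- tot >= minReads
  surv <- ts[keep]
  readSupport(surv) <- as.integer(tot[keep])
  newFunnelStep("read_support", surv, ids[!keep],
                stats::setNames(rep("low_support", sum(!keep)), ids[!keep]))
}

#' Run the full lncRNA identification cascade
#'
#' Applies the filters in order — structure (length/exons/strand), exonic
#' overlap with coding genes, coding potential (longest ORF, imported
#' evidence or built-in score), read support — and returns the surviving
#' transcripts relabeled `biotype = "lncRNA"` together with the audit
#' funnel. All transcripts of `ts` enter the funnel; transcripts labeled
#' `"coding"` in `ts` serve as the coding reference for the overlap filter
#' (and, overlapping their own exons, never survive it).
#'
#' @param ts input [TranscriptSet-class] (assembled transcriptome; coding
#'   reference transcripts carry `biotype == "coding"`).
#' @param seqs genome `DNAStringSet`.
#' @param counts raw count matrix.
#' @param evidence optional imported evidence data.frame
#'   ([readEvidenceTsv()]).
#' @param minLen,minExons,maxOrfAa,minReads,builtinThreshold,strandMode
#'   filter parameters; defaults are the pipeline's standard thresholds
#'   (200 nt, 2 exons, 100 aa, 6 reads, 0.5, same-strand overlap).
#' @return a list with `lncrna` (surviving `TranscriptSet`, biotype
#'   `"lncRNA"`), `funnel` (data.frame with `step`, `n_in`, `n_out` and a
#'   list-column `removed`), and `reasons` (named character over all
#'   removed transcripts).
#' @export
runIdentification <- function(ts, seqs, counts, evidence = NULL,
                              minLen = 200L, minExons = 2L,
                              maxOrfAa = 100L, minReads = 6L,
                              builtinThreshold = 0.5,
                              strandMode = c("same", "both")) {
  strandMode <- match.arg(strandMode)
  coding <- ts[txBiotype(ts) == "coding"]
  steps <- list()
  s1 <- filterStructure(ts, minLen = minLen, minExons = minExons)
  steps <- c(steps, list(s1))
  s2 <- filterExonOverlap(s1$survivors, coding, strandMode = strandMode)
  steps <- c(steps, list(s2))
  evTab <- codingEvidenceTable(s2$survivors, seqs, imported = evidence)
  s3 <- filterCoding(s2$survivors, evTab, maxOrfAa = maxOrfAa,
                     builtinThreshold = builtinThreshold)
  steps <- c(steps, list(s3))
  s4 <- filterReadSupport(s3$survivors, counts, minReads = minReads)
  steps <- c(steps, list(s4))
  lnc <- s4$survivors
  if (length(lnc)) txBiotype(lnc) <- "lncRNA"
  nIn <- c(length(ts), vapply(steps[-4], function(s) length(s$survivors), 0L))
  funnel <- data.frame(
    step = vapply(steps, `[[`, "", "step"),
    n_in = nIn,
    n_out = vapply(steps, function(s) length(s$survivors), 0L),
    stringsAsFactors = FALSE
  )
  funnel$removed <- I(lapply(steps, `[[`, "removed"))
  reasons <- do.call(c, lapply(steps, `[[`, "reasons"))
  list(lncrna = lnc, funnel = funnel, reasons = reasons)
}
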