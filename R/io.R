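#' @importFrom Biostrings DNAStringSet reverseComplement subseq readDNAStringSet writeXStringSet
#' @importFrom utils read.delim write.table
NULL

#' Read transcript models from a GTF file
#'
#' Parses exon features from a GTF (2.2 dialect) file into a
#' [TranscriptSet-class]. Exon lines are grouped by `transcript_id`; strand
#' `"."` maps to unknown (`"*"`); the biotype is taken from a
#' `transcript_biotype` or `gene_biotype` attribute when present, otherwise
#' every transcript is labeled `"candidate"`.
#'
#' @param path path to a GTF file.
#' @return a [TranscriptSet-class].
#' @seealso [writeTranscriptGtf()]
#' @export
readTranscriptGtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    stop("malformed GTF line ", which(body)[which(nf < 9L)[1]],
         " in ", path, ": expected 9 tab-separated fields")
  }
  if (!any(body)) {
    return(TranscriptSet(GRangesList()))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) {
    return(TranscriptSet(GRangesList()))
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id) ||
      is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("every exon feature must carry gene_id and transcript_id")
  }
  bio <- rep("candidate", length(gr))
  if (!is.null(gr$transcript_biotype)) {
    bio <- ifelse(is.na(gr$transcript_biotype), bio, gr$transcript_biotype)
  } else if (!is.null(gr$gene_biotype)) {
    bio <- ifelse(is.na(gr$gene_biotype), bio, gr$gene_biotype)
  }
  tx <- as.character(gr$transcript_id)
  first <- !duplicated(tx)
  ts <- TranscriptSet(
    S4Vectors::split(GenomicRanges::granges(gr), factor(tx, levels = tx[first])),
    geneId = as.character(gr$gene_id)[first],
    biotype = bio[first]
  )
  ts
}

#' Write a TranscriptSet to GTF
#'
#' Emits one exon feature line per exon in GTF 2.2 format (1-based closed
#' coordinates, attributes `gene_id` then `transcript_id`, plus
#' `transcript_biotype`). Transcripts are ordered deterministically by
#' (scaffold, span start, transcript id); exons ascending within each
#' transcript. Unknown strand is written as `"."`.
#'
#' @param ts a [TranscriptSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTranscriptGtf <- function(ts, path) {
  stopifnot(is(ts, "TranscriptSet"))
  if (!length(ts)) {
    writeLines("#gtf produced by lncScout", path)
    return(invisible(path))
  }
  sp <- txSpans(ts)
  ord <- order(as.character(GenomicRanges::seqnames(sp)),
               GenomicRanges::start(sp), txIds(ts))
  ts <- ts[ord]
  ex <- txExons(ts)
  nex <- S4Vectors::elementNROWS(ex)
  u <- BiocGenerics::unlist(ex, use.names = FALSE)
  tx <- rep(txIds(ts), nex)
  gid <- rep(unname(geneIds(ts)), nex)
  bio <- rep(unname(txBiotype(ts)), nex)
  strand <- as.character(GenomicRanges::strand(u))
  strand[strand == "*"] <- "."
  lines <- sprintf(
    '%s\tlncScout\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
    as.character(GenomicRanges::seqnames(u)),
    GenomicRanges::start(u), GenomicRanges::end(u), strand, gid, tx, bio)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Assemble spliced transcript sequences
#'
#' Concatenates each transcript's exon substrings 5' to 3' from the genome;
#' minus-strand transcripts are reverse-complemented. The strand must be
#' known (`filterStructure()` removes unknown-strand transcripts upstream).
#'
#' @param ts a [TranscriptSet-class] with known strands.
#' @param seqs a named [Biostrings::DNAStringSet] (one entry per scaffold).
#' @return a `DNAStringSet` named by transcript id; widths equal
#'   `txLengths(ts)`.
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(s1 = "ATGCATGCAT"))
#' gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 4), strand = "-",
#'   transcript_id = "t1", gene_id = "g1")
#' as.character(spliceTranscriptSeq(TranscriptSet(gr), seqs))  # "GCAT"
#' @export
spliceTranscriptSeq <- function(ts, seqs) {
  stopifnot(is(ts, "TranscriptSet"), is(seqs, "DNAStringSet"))
  str <- txStrand(ts)
  if (any(str == "*")) {
    stop("cannot splice transcripts with unknown strand: ",
         paste(utils::head(names(str)[str == "*"], 5), collapse = ", "))
  }
  ex <- txExons(ts)
  chr <- as.character(BiocGenerics::unlist(
    unique(GenomicRanges::seqnames(ex)), use.names = FALSE))
  miss <- setdiff(unique(chr), names(seqs))
  if (length(miss)) stop("scaffold(s) missing from sequence store: ",
                         paste(miss, collapse = ", "))
  slen <- stats::setNames(BiocGenerics::width(seqs), names(seqs))
  out <- character(length(ts))
  for (k in seq_along(ts)) {
    e <- ex[[k]]
    if (max(GenomicRanges::end(e)) > slen[chr[k]] ||
        min(GenomicRanges::start(e)) < 1L) {
      stop("exon out of scaffold bounds for transcript ", txIds(ts)[k])
    }
    pieces <- as.character(Biostrings::subseq(
      rep(seqs[chr[k]], length(e)),
      start = GenomicRanges::start(e), end = GenomicRanges::end(e)))
    out[k] <- paste(pieces, collapse = "")
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- txIds(ts)
  minus <- str == "-"
  if (any(minus)) res[minus] <- Biostrings::reverseComplement(res[minus])
  res
}

#' Read a raw read-count matrix
#'
#' Reads a TSV with a `transcript_id` column followed by one integer column
#' per sample. Counts must be non-negative integers; duplicate transcript
#' ids are an error.
#'
#' @param path TSV path.
#' @return an integer matrix, rows named by transcript id, columns by sample.
#' @export
readCountsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs transcript_id plus >= 1 sample column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate transcript ids in count table")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) stop("counts must be numeric and complete")
  if (any(m < 0)) stop("negative counts are not allowed")
  if (any(m != round(m))) stop("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Read a sample-to-tissue design table
#'
#' @param path TSV path with columns `sample_id` and `tissue`.
#' @param counts optional count matrix; when given, every count column must
#'   appear in the design.
#' @return a data.frame with columns `sample_id`, `tissue`.
#' @export
readDesignTsv <- function(path, counts = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(df))) {
    stop("design table needs columns sample_id and tissue")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in design")
  if (!is.null(counts)) {
    miss <- setdiff(colnames(counts), df$sample_id)
    if (length(miss)) stop("samples in counts missing from design: ",
                           paste(miss, collapse = ", "))
  }
  df[, c("sample_id", "tissue")]
}

#' Read a gene-to-term annotation map
#'
#' @param path TSV path with columns `gene_id`, `term_id`, `term_name`,
#'   `namespace` (`"BP"` or `"KEGG"`).
#' @return a data.frame of the four columns.
#' @export
readTermMapTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "term_id", "term_name", "namespace")
  if (!all(need %in% names(df))) {
    stop("term map needs columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$namespace), c("BP", "KEGG"))
  if (length(bad)) stop("unknown namespace: ", paste(bad, collapse = ", "))
  if (any(!nzchar(df$term_id))) stop("empty term ids are not allowed")
  df[, need]
}

#' Read an external coding-evidence table
#'
#' Verdicts from external coding-potential or homology tools (one row per
#' transcript and tool), importable in place of running the tools.
#'
#' @param path TSV path with columns `transcript_id`, `source` (one of
#'   `blastx`, `pfam`, `cpc2`, `rnaplonc`), `verdict` (`coding` or
#'   `noncoding`).
#' @return a data.frame of the three columns.
#' @export
readEvidenceTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "source", "verdict")
  if (!all(need %in% names(df))) {
    stop("evidence table needs columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$source), c("blastx", "pfam", "cpc2", "rnaplonc"))
  if (length(bad)) stop("unknown evidence source: ", paste(bad, collapse = ", "))
  badv <- setdiff(unique(df$verdict), c("coding", "noncoding"))
  if (length(badv)) stop("unknown verdict: ", paste(badv, collapse = ", "))
  df[, need]
}
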