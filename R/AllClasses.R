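#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList granges strand "strand<-" seqnames start end width
#' @importFrom BiocGenerics unlist
NULL

#' TranscriptSet: a collection of exon-resolved transcript models
#'
#' `TranscriptSet` holds one transcript model per element: an ordered set of
#' exons (1-based, closed coordinates) on a scaffold, a strand (`"+"`, `"-"`,
#' or `"*"` for transcripts assembled without strand information), a parent
#' gene, and a biotype label (`"coding"`, `"candidate"`, or `"lncRNA"`).
#' It is the container passed between all pipeline stages: GTF I/O,
#' identification, classification and characterization.
#'
#' @slot exons a [GenomicRanges::GRangesList], one element per transcript,
#'   named by transcript id; each element's exons are sorted by start and
#'   non-overlapping, all on one scaffold and one strand.
#' @slot txData a [S4Vectors::DataFrame] with one row per transcript
#'   (same order and names as `exons`), columns `transcript_id`, `gene_id`,
#'   `biotype`, and `read_support` (total raw counts, `NA` until attached).
#'
#' @section Validity:
#' Transcript ids are unique; every transcript has at least one exon;
#' exons are sorted ascending and disjoint; biotypes come from the
#' enumerated set.
#'
#' @seealso [TranscriptSet()] for construction, [readTranscriptGtf()].
#' @export
setClass("TranscriptSet",
  slots = c(exons = "GRangesList", txData = "DataFrame")
)

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  msgs <- character()
  if (length(ex) != nrow(td)) {
    msgs <- c(msgs, "exons and txData must have the same length")
  }
  if (length(ex)) {
    if (is.null(names(ex)) || anyDuplicated(names(ex))) {
      msgs <- c(msgs, "transcript ids must be present and unique")
    }
    if (!identical(names(ex), as.character(td$transcript_id))) {
      msgs <- c(msgs, "names(exons) must match txData$transcript_id")
    }
    nex <- S4Vectors::elementNROWS(ex)
    if (any(nex == 0L)) msgs <- c(msgs, "every transcript needs >= 1 exon")
    u <- BiocGenerics::unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), nex)
    st <- GenomicRanges::start(u)
    en <- GenomicRanges::end(u)
    # sorted ascending and non-overlapping within each transcript
    prev_end <- c(-Inf, en[-length(en)])
    same_tx <- c(FALSE, grp[-1] == grp[-length(grp)])
    if (any(same_tx & st <= prev_end)) {
      msgs <- c(msgs, "exons must be sorted ascending and non-overlapping")
    }
    ns <- lengths(unique(GenomicRanges::seqnames(ex)))
    if (any(ns != 1L)) msgs <- c(msgs, "one scaffold per transcript")
    nstr <- lengths(unique(GenomicRanges::strand(ex)))
    if (any(nstr != 1L)) msgs <- c(msgs, "one strand per transcript")
  }
  bad <- setdiff(unique(as.character(td$biotype)),
                 c("coding", "candidate", "lncRNA"))
  if (length(bad)) {
    msgs <- c(msgs, paste0("unknown biotype: ", paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptSet
#'
#' Builds a validated [TranscriptSet-class] from per-exon coordinates.
#' Exons are sorted by start within each transcript; exons that overlap or
#' touch within one transcript are merged with a warning (tolerant of
#' assembler artifacts).
#'
#' @param exons a `GRangesList` (one element per transcript, named), or a
#'   `GRanges` of exons carrying `transcript_id` metadata.
#' @param geneId character vector of gene ids, one per transcript (recycled
#'   from exon metadata `gene_id` when `exons` is a `GRanges`).
#' @param biotype character vector of biotypes (`"coding"`, `"candidate"`,
#'   `"lncRNA"`), one per transcript; default `"candidate"`.
#' @param readSupport integer vector of total raw read counts per
#'   transcript, or `NA`.
#' @return a `TranscriptSet`.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), c(50, 150)),
#'   strand = "+", transcript_id = "t1", gene_id = "g1")
#' TranscriptSet(gr)
#' @export
TranscriptSet <- function(exons, geneId = NULL, biotype = "candidate",
                          readSupport = NA_integer_) {
  if (is(exons, "GRanges")) {
    if (is.null(exons$transcript_id)) {
      stop("exon GRanges must carry a transcript_id column")
    }
    tx <- as.character(exons$transcript_id)
    if (is.null(geneId) && !is.null(exons$gene_id)) {
      gmap <- tapply(as.character(exons$gene_id), tx, `[`, 1L)
    } else {
      gmap <- NULL
    }
    grl <- S4Vectors::split(GenomicRanges::granges(exons),
                            factor(tx, levels = unique(tx)))
    if (!is.null(gmap)) geneId <- as.character(gmap[names(grl)])
    exons <- grl
  }
  if (is.null(names(exons))) {
    if (length(exons) == 0L) names(exons) <- character(0)
    else stop("exons must be named by transcript id")
  }
  exons <- sortAndMergeExons(exons)
  n <- length(exons)
  if (is.null(geneId)) geneId <- names(exons)
  td <- S4Vectors::DataFrame(
    transcript_id = names(exons),
    gene_id = rep_len(as.character(geneId), n),
    biotype = rep_len(as.character(biotype), n),
    read_support = rep_len(as.integer(readSupport), n),
    row.names = names(exons)
  )
  methods::new("TranscriptSet", exons = exons, txData = td)
}

# sort exons by start per transcript and merge any overlapping/adjacent pairs
sortAndMergeExons <- function(grl) {
  u <- BiocGenerics::unlist(grl, use.names = FALSE)
  n0 <- length(u)
  red <- GenomicRanges::reduce(grl, min.gapwidth = 0L)
  if (sum(S4Vectors::elementNROWS(red)) != n0) {
    warning("overlapping exons within a transcript were merged")
  }
  red
}

#' @describeIn TranscriptSet-class number of transcripts
#' @param x a `TranscriptSet`
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @export
setGeneric("txExons", function(x) standardGeneric("txExons"))
#' @export
setGeneric("txData", function(x) standardGeneric("txData"))
#' @export
setGeneric("txLengths", function(x) standardGeneric("txLengths"))
#' @export
setGeneric("txStrand", function(x) standardGeneric("txStrand"))
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))
#' @export
setGeneric("txBiotype", function(x) standardGeneric("txBiotype"))
#' @export
setGeneric("txBiotype<-", function(x, value) standardGeneric("txBiotype<-"))
#' @export
setGeneric("readSupport", function(x) standardGeneric("readSupport"))
#' @export
setGeneric("readSupport<-", function(x, value) standardGeneric("readSupport<-"))

#' @describeIn TranscriptSet-class transcript ids
#' @export
setMethod("txIds", "TranscriptSet", function(x) names(x@exons))

#' @describeIn TranscriptSet-class gene id per transcript
#' @export
setMethod("geneIds", "TranscriptSet", function(x) {
  stats::setNames(as.character(x@txData$gene_id), txIds(x))
})

#' @describeIn TranscriptSet-class exon `GRangesList`
#' @export
setMethod("txExons", "TranscriptSet", function(x) x@exons)

#' @describeIn TranscriptSet-class per-transcript metadata `DataFrame`
#' @export
setMethod("txData", "TranscriptSet", function(x) x@txData)

#' @describeIn TranscriptSet-class spliced length (sum of exon widths)
#' @export
setMethod("txLengths", "TranscriptSet", function(x) {
  stats::setNames(sum(GenomicRanges::width(x@exons)), txIds(x))
})

#' @describeIn TranscriptSet-class strand per transcript (`"*"` = unknown)
#' @export
setMethod("txStrand", "TranscriptSet", function(x) {
  s <- as.character(BiocGenerics::unlist(
    unique(GenomicRanges::strand(x@exons)), use.names = FALSE))
  stats::setNames(s, txIds(x))
})

#' @describeIn TranscriptSet-class genomic span (first exon start to last
#'   exon end) as a `GRanges`
#' @export
setMethod("txSpans", "TranscriptSet", function(x) {
  sp <- BiocGenerics::unlist(range(x@exons), use.names = TRUE)
  sp
})

#' @describeIn TranscriptSet-class biotype per transcript
#' @export
setMethod("txBiotype", "TranscriptSet", function(x) {
  stats::setNames(as.character(x@txData$biotype), txIds(x))
})

#' @describeIn TranscriptSet-class replace biotypes
#' @param value replacement vector
#' @export
setMethod("txBiotype<-", "TranscriptSet", function(x, value) {
  x@txData$biotype <- rep_len(as.character(value), length(x))
  methods::validObject(x)
  x
})

#' @describeIn TranscriptSet-class total raw read counts per transcript
#' @export
setMethod("readSupport", "TranscriptSet", function(x) {
  stats::setNames(as.integer(x@txData$read_support), txIds(x))
})

#' @describeIn TranscriptSet-class attach read support
#' @export
setMethod("readSupport<-", "TranscriptSet", function(x, value) {
  x@txData$read_support <- rep_len(as.integer(value), length(x))
  x
})

#' @describeIn TranscriptSet-class subset by index, logical, or transcript id
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, txIds(x))
    if (length(miss)) {
      stop("unknown transcript id(s): ", paste(utils::head(miss, 5), collapse = ", "))
    }
    i <- match(i, txIds(x))
  }
  methods::new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

#' @describeIn TranscriptSet-class display a summary
#' @param object a `TranscriptSet`
#' @export
setMethod("show", "TranscriptSet", function(object) {
  n <- length(object)
  cat("TranscriptSet with", n, "transcripts\n")
  if (n) {
    bt <- table(txBiotype(object))
    cat("  biotypes:", paste(names(bt), as.integer(bt), sep = ":", collapse = ", "), "\n")
    cat("  scaffolds:", length(unique(as.character(
      GenomicRanges::seqnames(txSpans(object))))), "\n")
    ln <- txLengths(object)
    cat(sprintf("  spliced length: %d-%d nt (median %.0f)\n",
                min(ln), max(ln), stats::median(ln)))
  }
  invisible(object)
})
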