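#' @importFrom GenomicRanges reduce findOverlaps pintersect setdiff
NULL

# Per-gene structures derived from a coding TranscriptSet: span (range over
# all exons of the gene's transcripts), reduced exons, and introns
# (span minus exons).
codingGeneModel <- function(coding) {
  gid <- geneIds(coding)
  exByGene <- S4Vectors::split(
    BiocGenerics::unlist(txExons(coding), use.names = FALSE),
    factor(rep(unname(gid), S4Vectors::elementNROWS(txExons(coding))),
           levels = unique(unname(gid))))
  exByGene <- GenomicRanges::reduce(exByGene)
  spans <- BiocGenerics::unlist(range(exByGene), use.names = TRUE)
  introns <- GenomicRanges::psetdiff(spans, exByGene)
  list(gene_id = names(exByGene), spans = spans,
       exons = exByGene, introns = introns)
}

#' Positional classification of lncRNAs against coding genes
#'
#' Assigns each lncRNA one of four positional classes by an explicit
#' decision order: (1) no overlap of the lncRNA's genomic span with any
#' coding-gene span (either strand) — intergenic; (2) exonic overlap with
#' the exons of an opposite-strand coding gene — antisense; (3) entirely
#' contained within a single intron of a same-strand coding gene —
#' intronic; (4) anything else — other (this absorbs same-strand
#' intron-overlapping-but-not-contained and opposite-strand intron-contained
#' cases). The partner gene is the gene with maximal overlap within the
#' deciding rule, ties broken by smallest gene id; intergenic lncRNAs have
#' no partner.
#'
#' @param lnc [TranscriptSet-class] of lncRNAs (known strands).
#' @param coding [TranscriptSet-class] of coding transcripts.
#' @return a data.frame with columns `transcript_id`, `lnc_class`
#'   (`intergenic`/`antisense`/`intronic`/`other`), `partner_gene_id`
#'   (`NA` for intergenic).
#' @export
classifyLncRNA <- function(lnc, coding) {
  str <- txStrand(lnc)
  if (any(str == "*")) {
    stop("cannot classify transcripts with unknown strand: ",
         paste(utils::head(names(str)[str == "*"], 5), collapse = ", "))
  }
  gm <- codingGeneModel(coding)
  geneStrand <- as.character(GenomicRanges::strand(gm$spans))
  spans <- txSpans(lnc)
  ex <- txExons(lnc)
  n <- length(lnc)
  cls <- character(n)
  partner <- rep(NA_character_, n)

  # rule 1: span overlap with any gene span, strand-blind
  spanHits <- GenomicRanges::findOverlaps(spans, gm$spans, ignore.strand = TRUE)
  hasSpan <- seq_len(n) %in% S4Vectors::queryHits(spanHits)
  cls[!hasSpan] <- "intergenic"

  pickPartner <- function(genes, ov) {
    genes[order(-ov, genes)][1]
  }

  # rule 2: exonic overlap with opposite-strand gene exons
  exHits <- GenomicRanges::findOverlaps(ex, gm$exons, ignore.strand = TRUE)
  if (length(exHits)) {
    q <- S4Vectors::queryHits(exHits)
    s <- S4Vectors::subjectHits(exHits)
    opp <- str[q] != geneStrand[s]
    exHitsOv <- vapply(which(opp), function(k) {
      sum(GenomicRanges::width(GenomicRanges::intersect(
        ex[[q[k]]], gm$exons[[s[k]]], ignore.strand = TRUE)))
    }, 0L)
    for (i in unique(q[opp])) {
      if (cls[i] != "") next
      sel <- which(opp & q == i)
      cls[i] <- "antisense"
      partner[i] <- pickPartner(gm$gene_id[s[sel]],
                                exHitsOv[match(sel, which(opp))])
    }
  }

  # rule 3: containment within a single intron, same strand
  undecided <- which(cls == "")
  if (length(undecided)) {
    intrU <- BiocGenerics::unlist(gm$introns, use.names = FALSE)
    intrGene <- rep(seq_along(gm$introns), S4Vectors::elementNROWS(gm$introns))
    within <- GenomicRanges::findOverlaps(spans[undecided], intrU,
                                          type = "within", ignore.strand = TRUE)
    if (length(within)) {
      q <- S4Vectors::queryHits(within)
      g <- intrGene[S4Vectors::subjectHits(within)]
      same <- str[undecided][q] == geneStrand[g]
      for (k in unique(q[same])) {
        i <- undecided[k]
        sel <- which(same & q == k)
        gs <- gm$gene_id[g[sel]]
        # overlap with the containing gene span is the whole lncRNA span;
        # ties (nested genes) resolved by gene id
        cls[i] <- "intronic"
        partner[i] <- sort(gs)[1]
      }
    }
  }

  # rule 4: everything else overlapping a gene span
  rest <- which(cls == "")
  if (length(rest)) {
    cls[rest] <- "other"
    q <- S4Vectors::queryHits(spanHits)
    s <- S4Vectors::subjectHits(spanHits)
    ovW <- GenomicRanges::width(GenomicRanges::pintersect(
      spans[q], gm$spans[s], ignore.strand = TRUE))
    for (i in rest) {
      sel <- which(q == i)
      partner[i] <- pickPartner(gm$gene_id[s[sel]], ovW[sel])
    }
  }

  data.frame(transcript_id = txIds(lnc), lnc_class = cls,
             partner_gene_id = partner, stringsAsFactors = FALSE)
}

#' Summarise positional classes
#'
#' @param records data.frame from [classifyLncRNA()].
#' @return a data.frame with `lnc_class`, `n`, `fraction` (fractions sum
#'   to 1); all four classes are listed, empty ones with zero.
#' @export
classSummary <- function(records) {
  if (!nrow(records)) stop("no classification records")
  lv <- c("intergenic", "antisense", "intronic", "other")
  tab <- table(factor(records$lnc_class, levels = lv))
  data.frame(lnc_class = lv, n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(records),
             stringsAsFactors = FALSE)
}
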