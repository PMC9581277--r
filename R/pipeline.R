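#' Pipeline parameters
#'
#' All thresholds of the cascade in one validated object. The defaults are
#' the pipeline's standard parameterization: multi-exon transcripts of at
#' least 200 nt with known strand, no same-strand exonic overlap with
#' coding genes, longest ORF strictly below 100 aa, at least 6 supporting
#' reads, 50 kb genome bins, tissue-specificity cutoff 0.6 (strict),
#' co-expression screen r > 0.8 with BH-adjusted p < 0.05, enrichment
#' cutoff adjusted p < 0.1.
#'
#' @param minLen,minExons,maxOrfAa,minReads identification thresholds.
#' @param builtinThreshold built-in coding-score flag threshold.
#' @param overlapStrand `"same"` or `"both"` for the exonic-overlap filter.
#' @param binSize genome bin width in nt.
#' @param specificityCutoff tissue-specificity score cutoff (strict `>`).
#' @param rCut,qEdge co-expression screen thresholds.
#' @param qEnrich enrichment significance cutoff (strict `<`).
#' @param edgeFamily BH family for co-expression (`"per_lnc"`/`"global"`).
#' @param tissueStat replicate aggregation (`"mean"`/`"median"`).
#' @param pseudocount log2 pseudocount for expression summaries.
#' @param seed seed echoed into the run manifest.
#' @return a list of class `lncPipelineParams`.
#' @export
pipelineParams <- function(minLen = 200L, minExons = 2L, maxOrfAa = 100L,
                           minReads = 6L, builtinThreshold = 0.5,
                           overlapStrand = c("same", "both"),
                           binSize = 50000L, specificityCutoff = 0.6,
                           rCut = 0.8, qEdge = 0.05, qEnrich = 0.1,
                           edgeFamily = c("per_lnc", "global"),
                           tissueStat = c("mean", "median"),
                           pseudocount = 0.01, seed = 1L) {
  p <- as.list(environment())
  p$overlapStrand <- match.arg(overlapStrand)
  p$edgeFamily <- match.arg(edgeFamily)
  p$tissueStat <- match.arg(tissueStat)
  stopifnot(p$minLen > 0, p$minExons >= 1, p$maxOrfAa > 0, p$minReads >= 0,
            p$binSize > 0, p$specificityCutoff >= 0, p$specificityCutoff <= 1,
            p$rCut >= -1, p$rCut <= 1, p$qEdge > 0, p$qEdge <= 1,
            p$qEnrich > 0, p$qEnrich <= 1)
  class(p) <- "lncPipelineParams"
  p
}

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis end-to-end
#'
#' Orchestrates identification, classification, characterization,
#' tissue-specificity scoring and function inference on one dataset, and
#' writes every stage's tables plus a machine-readable run manifest
#' (config echo, per-stage counts, output checksums). Identical inputs
#' and parameters yield byte-identical outputs.
#'
#' @param annotation [TranscriptSet-class] of assembled transcripts
#'   (coding reference transcripts labeled `biotype = "coding"`).
#' @param seqs genome `DNAStringSet`.
#' @param counts raw count matrix covering all transcripts.
#' @param design data.frame `sample_id`, `tissue`.
#' @param termMap optional annotation map ([readTermMapTsv()]); function
#'   inference is skipped when absent.
#' @param evidence optional imported coding evidence ([readEvidenceTsv()]).
#' @param outDir optional output directory; when given, all result tables
#'   and `manifest.json` are written there.
#' @param params an `lncPipelineParams` (default [pipelineParams()]).
#' @return a list with `lncrna`, `funnel`, `classes`, `classSummary`,
#'   `features`, `bins`, `binCor`, `expression` (`SummarizedExperiment`),
#'   `specificity` (lncRNA screen), `specificityMrna`, `sweep`, `edges`,
#'   `enrichment`, `profile`, `manifest`.
#' @export
runPipeline <- function(annotation, seqs, counts, design, termMap = NULL,
                        evidence = NULL, outDir = NULL,
                        params = pipelineParams()) {
  stopifnot(inherits(params, "lncPipelineParams"))
  manifest <- list(tool = "lncScout",
                   version = as.character(utils::packageVersion("lncScout")),
                   params = params[setdiff(names(params), "")],
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ident <- stageTry("identification", runIdentification(
    annotation, seqs, counts, evidence = evidence,
    minLen = params$minLen, minExons = params$minExons,
    maxOrfAa = params$maxOrfAa, minReads = params$minReads,
    builtinThreshold = params$builtinThreshold,
    strandMode = params$overlapStrand))
  lnc <- ident$lncrna
  note("identification", n_in = length(annotation), n_lncrna = length(lnc),
       funnel = stats::setNames(as.list(ident$funnel$n_out),
                                ident$funnel$step))

  coding <- annotation[txBiotype(annotation) == "coding"]
  classes <- stageTry("classification", classifyLncRNA(lnc, coding))
  clsSum <- classSummary(classes)
  note("classification",
       counts = stats::setNames(as.list(clsSum$n), clsSum$lnc_class))

  se <- stageTry("characterization/normalization",
                 buildExpression(counts, design, txLengths(annotation)))
  fpkm <- SummarizedExperiment::assay(se, "fpkm")
  featLnc <- stageTry("characterization/features",
                      featureTable(lnc, seqs, fpkm))
  featMrna <- stageTry("characterization/features",
                       featureTable(coding, seqs, fpkm))
  feat <- rbind(cbind(featLnc, group = "lncRNA"),
                cbind(featMrna, group = "mRNA"))
  cmp <- if (length(lnc) && length(coding)) {
    compareGroups(featLnc, featMrna, pseudocount = params$pseudocount)
  } else NULL
  bins <- stageTry("characterization/bins", binDistribution(
    lnc, coding, binSize = params$binSize,
    seqLengths = stats::setNames(BiocGenerics::width(seqs), names(seqs))))
  binCor <- binCorrelation(bins)
  note("characterization", n_features = nrow(feat), n_bins = nrow(bins))

  tiss <- tissueMeanFpkm(se, stat = params$tissueStat)
  specLnc <- stageTry("specificity", screenSpecific(
    specificityScores(tiss[txIds(lnc), , drop = FALSE]),
    cutoff = params$specificityCutoff))
  specMrna <- stageTry("specificity", screenSpecific(
    specificityScores(tiss[txIds(coding), , drop = FALSE]),
    cutoff = params$specificityCutoff))
  sweep <- if (length(lnc) && length(coding)) {
    specificityComparison(specLnc$records, specMrna$records)
  } else NULL
  note("specificity", n_specific_lnc = sum(specLnc$records$specific),
       n_specific_mrna = sum(specMrna$records$specific))

  edges <- enrichment <- profile <- NULL
  if (!is.null(termMap) && length(lnc) && length(coding)) {
    edges <- stageTry("function/coexpression", coexpressionEdges(
      fpkm[txIds(lnc), , drop = FALSE],
      fpkm[txIds(coding), , drop = FALSE],
      rCut = params$rCut, qCut = params$qEdge,
      family = params$edgeFamily))
    # background: expressed mRNAs (gene ids) annotated in the namespace
    g2t <- stats::setNames(unname(geneIds(coding)), txIds(coding))
    edgesG <- edges
    edgesG$mrna_id <- unname(g2t[edges$mrna_id])
    enrichment <- stageTry("function/enrichment", enrichTerms(
      edgesG, termMap, background = unique(unname(g2t)),
      qCut = params$qEnrich))
    groups <- data.frame(
      transcript_id = specLnc$records$transcript_id,
      group = ifelse(specLnc$records$specific,
                     specLnc$records$top_tissue, "non_specific"),
      stringsAsFactors = FALSE)
    profile <- profileReport(enrichment, groups)
    note("function", n_edges = sum(edges$selected),
         n_significant = if (nrow(enrichment)) sum(enrichment$significant) else 0L)
  }

  res <- list(lncrna = lnc, funnel = ident$funnel, reasons = ident$reasons,
              classes = classes, classSummary = clsSum, features = feat,
              comparison = cmp, bins = bins, binCor = binCor,
              expression = se, specificity = specLnc,
              specificityMrna = specMrna, sweep = sweep, edges = edges,
              enrichment = enrichment, profile = profile)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    wtsv <- function(d, f) {
      if (is.null(d)) return(invisible(NULL))
      utils::write.table(d, file.path(outDir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    writeTranscriptGtf(lnc, file.path(outDir, "lncrna.gtf"))
    fun <- res$funnel[, c("step", "n_in", "n_out")]
    wtsv(fun, "funnel.tsv")
    wtsv(classes, "classes.tsv")
    wtsv(clsSum, "class_summary.tsv")
    wtsv(feat[, setdiff(names(feat), c("exon_lengths", "intron_lengths"))],
         "features.tsv")
    wtsv(cmp, "feature_comparison.tsv")
    wtsv(bins, "bins.tsv")
    wtsv(binCor, "bin_correlation.tsv")
    wtsv(data.frame(transcript_id = rownames(fpkm),
                    round(fpkm, 4), check.names = FALSE), "fpkm.tsv")
    wtsv(specLnc$records, "specificity_lnc.tsv")
    wtsv(specLnc$counts, "tissue_counts.tsv")
    wtsv(sweep, "specificity_sweep.tsv")
    wtsv(if (!is.null(edges)) edges[edges$selected, ] else NULL, "edges.tsv")
    wtsv(enrichment, "enrichment.tsv")
    wtsv(profile, "profile_report.tsv")
    outs <- list.files(outDir, full.names = TRUE)
    outs <- outs[basename(outs) != "manifest.json"]
    manifest$outputs <- as.list(tools::md5sum(sort(outs)))
    names(manifest$outputs) <- basename(names(manifest$outputs))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res$manifest <- manifest
  res
}
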