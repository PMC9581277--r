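#' @importFrom stats p.adjust phyper pt cor sd
NULL

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation with the usual t transform:
#' `t = r * sqrt(m - 2) / sqrt(1 - r^2)` on `m - 2` degrees of freedom,
#' two-sided. `|r| = 1` yields `p = 0`; a zero-variance vector yields an
#' undefined correlation (`NA`, excluded from downstream screening).
#'
#' @param x,y numeric vectors of equal length `m >= 3` with finite values.
#' @return a list with `r` and `p`.
#' @examples
#' pearsonWithP(1:10, (1:10)^2)
#' @export
pearsonWithP <- function(x, y) {
  m <- length(x)
  if (length(y) != m) stop("x and y must have equal length")
  if (m < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt(m - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = m - 2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `p_adj(i) = min_{j : p(j) >= p(i)} m * p(j) / rank(j)`, clipped at 1.
#' A thin validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes
#' without replacement from a background of `N` genes of which `K` carry
#' the term, the probability of seeing at least `k` carriers. Computed in
#' stable log space via `stats::phyper`.
#'
#' @param N background size; `K` background genes with the term; `n` drawn
#'   genes; `k` drawn genes with the term.
#' @param K,n,k see above.
#' @return the upper-tail probability.
#' @examples
#' hypergeomUpper(10, 4, 5, 3)  # 66/252
#' @export
hypergeomUpper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || K > N || n > N) {
    stop("invalid hypergeometric parameters")
  }
  if (k > min(K, n)) stop("infeasible k > min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Co-expression edges between lncRNAs and mRNAs
#'
#' Pearson correlation of every lncRNA against every mRNA across shared
#' samples (per-sample FPKM), with p-values from the t transform adjusted
#' by Benjamini-Hochberg. The adjustment family is, by default, all mRNAs
#' tested against one lncRNA (`family = "per_lnc"`); `family = "global"`
#' adjusts across all pairs at once. An edge is selected when `r` strictly
#' exceeds `rCut` and the adjusted p is strictly below `qCut`.
#' Zero-variance profiles have undefined correlations and are excluded
#' (reported via the `n_dropped` attribute).
#'
#' @param lncExpr,mrnaExpr expression matrices (rows = transcripts,
#'   columns = the same samples in the same order, `m >= 3`).
#' @param rCut correlation cutoff (default 0.8, strict `>`).
#' @param qCut adjusted-p cutoff (default 0.05, strict `<`).
#' @param family multiple-testing family, `"per_lnc"` (default) or
#'   `"global"`.
#' @return a data.frame of all tested pairs: `lnc_id`, `mrna_id`, `r`,
#'   `p`, `p_adj`, `selected`.
#' @export
coexpressionEdges <- function(lncExpr, mrnaExpr, rCut = 0.8, qCut = 0.05,
                              family = c("per_lnc", "global")) {
  family <- match.arg(family)
  if (ncol(lncExpr) != ncol(mrnaExpr)) stop("matrices must share sample columns")
  if (!is.null(colnames(lncExpr)) && !is.null(colnames(mrnaExpr)) &&
      !identical(colnames(lncExpr), colnames(mrnaExpr))) {
    stop("matrices must share sample columns (same order)")
  }
  m <- ncol(lncExpr)
  if (m < 3L) stop("need at least 3 shared samples")
  sdL <- apply(lncExpr, 1, stats::sd)
  sdM <- apply(mrnaExpr, 1, stats::sd)
  keepL <- sdL > 0; keepM <- sdM > 0
  nDropped <- sum(!keepL) + sum(!keepM)
  L <- lncExpr[keepL, , drop = FALSE]
  M <- mrnaExpr[keepM, , drop = FALSE]
  if (!nrow(L) || !nrow(M)) stop("no variable profiles to correlate")
  r <- stats::cor(t(L), t(M))
  r2 <- pmin(r^2, 1)
  tstat <- abs(r) * sqrt(m - 2) / sqrt(pmax(1 - r2, 0))
  p <- 2 * stats::pt(-tstat, df = m - 2)
  p[abs(r) >= 1] <- 0
  padj <- p
  if (family == "per_lnc") {
    for (i in seq_len(nrow(p))) padj[i, ] <- bhAdjust(p[i, ])
  } else {
    padj[] <- bhAdjust(as.vector(p))
  }
  out <- data.frame(
    lnc_id = rep(rownames(L), times = ncol(r)),
    mrna_id = rep(colnames(r), each = nrow(r)),
    r = as.vector(r), p = as.vector(p), p_adj = as.vector(padj),
    stringsAsFactors = FALSE)
  out$selected <- out$r > rCut & out$p_adj < qCut
  attr(out, "n_dropped") <- nDropped
  out
}

#' Per-lncRNA term enrichment of co-expressed mRNAs
#'
#' Guilt-by-association enrichment: for each lncRNA, its selected
#' co-expressed mRNAs are tested for over-representation of every
#' annotation term by the upper-tail hypergeometric test against the
#' background of expressed, annotated mRNAs in the same namespace,
#' adjusted by Benjamini-Hochberg across terms within the lncRNA and
#' namespace; significant means adjusted p strictly below `qCut`
#' (default 0.1).
#'
#' @param edges data.frame from [coexpressionEdges()] (`selected` edges
#'   are used).
#' @param termMap data.frame `gene_id`, `term_id`, `term_name`,
#'   `namespace` ([readTermMapTsv()]).
#' @param background character vector of expressed mRNA ids defining the
#'   enrichment universe (intersected per namespace with annotated genes).
#' @param qCut significance cutoff on adjusted p (default 0.1, strict `<`).
#' @param lncIds lncRNAs to report (default: all with >= 1 selected edge).
#' @return a data.frame: `lnc_id`, `namespace`, `term_id`, `term_name`,
#'   `N`, `K`, `n`, `k`, `p`, `p_adj`, `significant`.
#' @export
enrichTerms <- function(edges, termMap, background, qCut = 0.1,
                        lncIds = NULL) {
  sel <- edges[edges$selected, c("lnc_id", "mrna_id")]
  if (is.null(lncIds)) lncIds <- unique(sel$lnc_id)
  if (!nrow(termMap) || !any(termMap$namespace %in% c("BP", "KEGG"))) {
    stop("empty annotated background: term map has no BP/KEGG rows")
  }
  out <- list()
  for (ns in intersect(c("BP", "KEGG"), unique(termMap$namespace))) {
    tm <- termMap[termMap$namespace == ns, ]
    bg <- intersect(background, unique(tm$gene_id))
    if (!length(bg)) stop("empty annotated background for namespace ", ns)
    tm <- tm[tm$gene_id %in% bg, ]
    N <- length(bg)
    terms <- unique(tm[, c("term_id", "term_name")])
    genesByTerm <- split(tm$gene_id, tm$term_id)
    Kv <- lengths(genesByTerm)[terms$term_id]
    for (lnc in lncIds) {
      genes <- intersect(unique(sel$mrna_id[sel$lnc_id == lnc]), bg)
      n <- length(genes)
      if (n == 0L) next
      kv <- vapply(terms$term_id, function(t) {
        sum(genes %in% genesByTerm[[t]])
      }, 0L)
      pv <- stats::phyper(kv - 1, Kv, N - Kv, n, lower.tail = FALSE)
      padj <- bhAdjust(pv)
      out[[length(out) + 1L]] <- data.frame(
        lnc_id = lnc, namespace = ns,
        term_id = terms$term_id, term_name = terms$term_name,
        N = N, K = as.integer(Kv), n = n, k = as.integer(kv),
        p = pv, p_adj = padj, significant = padj < qCut,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  if (!length(out)) {
    return(data.frame(lnc_id = character(), namespace = character(),
                      term_id = character(), term_name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric(), p_adj = numeric(),
                      significant = logical()))
  }
  do.call(rbind, out)
}

#' Functional profile report by tissue-specificity group
#'
#' Counts, per tissue-specific group (and the non-specific pool) and
#' namespace, how many lncRNAs are significantly enriched for each term,
#' and reports the top `k` terms per group by lncRNA count (the shape of
#' "top enriched biological processes per tissue" summaries).
#'
#' @param enrichment data.frame from [enrichTerms()].
#' @param groups data.frame `transcript_id`, `group` (a tissue name for
#'   specific lncRNAs, `"non_specific"` otherwise).
#' @param topK terms reported per group and namespace (default 20).
#' @return a data.frame `group`, `namespace`, `term_id`, `term_name`,
#'   `n_lnc`, `rank`.
#' @export
profileReport <- function(enrichment, groups, topK = 20L) {
  sig <- enrichment[enrichment$significant, ]
  if (!nrow(sig)) {
    return(data.frame(group = character(), namespace = character(),
                      term_id = character(), term_name = character(),
                      n_lnc = integer(), rank = integer()))
  }
  sig$group <- groups$group[match(sig$lnc_id, groups$transcript_id)]
  sig <- sig[!is.na(sig$group), ]
  out <- list()
  for (g in unique(sig$group)) for (ns in unique(sig$namespace)) {
    d <- sig[sig$group == g & sig$namespace == ns, ]
    if (!nrow(d)) next
    cnt <- tapply(d$lnc_id, d$term_id, function(x) length(unique(x)))
    ord <- order(-cnt, names(cnt))
    top <- utils::head(ord, topK)
    out[[length(out) + 1L]] <- data.frame(
      group = g, namespace = ns, term_id = names(cnt)[top],
      term_name = d$term_name[match(names(cnt)[top], d$term_id)],
      n_lnc = as.integer(cnt[top]), rank = seq_along(top),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
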