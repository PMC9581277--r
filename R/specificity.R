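#' Tissue-specificity fractions and scores
#'
#' For transcript i with expression `E[i, j]` in tissue j (j = 1..n), the
#' fraction is `F[i, j] = E[i, j] / sum_j E[i, j]` and the
#' tissue-specificity score is `max_j F[i, j]` — bounded between `1/n`
#' (uniform expression) and 1 (single-tissue expression). Transcripts with
#' all-zero expression have an undefined score (0/0): they are flagged
#' `defined = FALSE`, excluded from screening, and reported separately.
#' Argmax ties are broken by lexicographically smallest tissue name.
#'
#' @param exprTissue matrix transcripts x tissues of non-negative
#'   expression values (tissue-level FPKM, see [tissueMeanFpkm()]), or a
#'   single non-negative vector of length n.
#' @return a data.frame with `transcript_id`, `score`, `top_tissue`,
#'   `defined`, and one `frac_<tissue>` column per tissue.
#' @examples
#' specificityScores(matrix(c(6, 2, 1, 1, 0, 0), 1,
#'   dimnames = list("t1", paste0("ts", 1:6))))$score  # 0.6
#' @export
specificityScores <- function(exprTissue) {
  if (is.null(dim(exprTissue))) {
    exprTissue <- matrix(exprTissue, nrow = 1,
                         dimnames = list("tx1", names(exprTissue)))
  }
  if (any(exprTissue < 0)) stop("expression values must be non-negative")
  if (ncol(exprTissue) < 2L) stop("need >= 2 tissues")
  if (is.null(colnames(exprTissue))) {
    colnames(exprTissue) <- paste0("tissue", seq_len(ncol(exprTissue)))
  }
  tot <- rowSums(exprTissue)
  defined <- tot > 0
  fr <- exprTissue / ifelse(tot == 0, NA_real_, tot)
  score <- apply(fr, 1, function(v) if (all(is.na(v))) NA_real_ else max(v))
  ord <- order(colnames(exprTissue))
  top <- apply(fr[, ord, drop = FALSE], 1, function(v) {
    if (all(is.na(v))) NA_character_ else colnames(exprTissue)[ord][which.max(v)]
  })
  out <- data.frame(
    transcript_id = rownames(exprTissue) %||% paste0("tx", seq_len(nrow(exprTissue))),
    score = unname(score), top_tissue = unname(top),
    defined = unname(defined), stringsAsFactors = FALSE)
  fr[!defined, ] <- NA_real_
  colnames(fr) <- paste0("frac_", colnames(exprTissue))
  cbind(out, as.data.frame(fr, row.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen tissue-specific transcripts
#'
#' A transcript is tissue-specific when its score strictly exceeds the
#' cutoff (default 0.6; a score of exactly 0.6 is not specific).
#' Transcripts with undefined scores are never specific.
#'
#' @param records data.frame from [specificityScores()].
#' @param cutoff score cutoff (default 0.6, strict `>`).
#' @return a list: `records` (input plus a `specific` column), `counts`
#'   (data.frame `tissue`, `n_specific` over specific transcripts grouped
#'   by their top tissue), `n_undefined`.
#' @export
screenSpecific <- function(records, cutoff = 0.6) {
  specific <- !is.na(records$score) & records$defined & records$score > cutoff
  records$specific <- specific
  tis <- sort(unique(records$top_tissue[!is.na(records$top_tissue)]))
  counts <- data.frame(
    tissue = tis,
    n_specific = vapply(tis, function(t) {
      sum(specific & records$top_tissue == t)
    }, 0L),
    stringsAsFactors = FALSE)
  list(records = records, counts = counts,
       n_undefined = sum(!records$defined))
}

#' Threshold sweep comparing specificity of two groups
#'
#' For every threshold on a grid, the fraction of each group with score
#' strictly above it (the shape behind "percent tissue-specific under
#' varying thresholds" comparisons), plus the score ECDF values.
#'
#' @param lncRecords,mrnaRecords data.frames from [specificityScores()].
#' @param grid numeric thresholds (default `seq(0, 1, 0.05)`).
#' @return a data.frame `threshold`, `lnc_frac`, `mrna_frac` (fraction of
#'   defined records with score > threshold).
#' @export
specificityComparison <- function(lncRecords, mrnaRecords,
                                  grid = seq(0, 1, by = 0.05)) {
  a <- lncRecords$score[lncRecords$defined]
  b <- mrnaRecords$score[mrnaRecords$defined]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  data.frame(
    threshold = grid,
    lnc_frac = vapply(grid, function(t) mean(a > t), 0),
    mrna_frac = vapply(grid, function(t) mean(b > t), 0))
}
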