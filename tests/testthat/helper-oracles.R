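# Independent brute-force oracles and random fixture builders.
# These deliberately share no code path with the package implementations
# they check.

# O(L^2) ORF finder: for every ATG in every forward frame, walk codon by
# codon to the first in-frame stop.
oracleLongestOrf <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  i <- 1L
  while (i + 2L <= L) {
    if (substr(seq, i, i + 2L) == "ATG") {
      j <- i + 3L
      while (j + 2L <= L) {
        cod <- substr(seq, j, j + 2L)
        if (cod %in% stops) {
          best <- max(best, (j - i) %/% 3L)
          break
        }
        j <- j + 3L
      }
    }
    i <- i + 1L
  }
  as.integer(best)
}

randomDnaString <- function(len, withN = FALSE) {
  alpha <- c("A", "C", "G", "T", if (withN) "N")
  prob <- if (withN) c(rep(0.24, 4), 0.04) else rep(0.25, 4)
  paste(sample(alpha, len, replace = TRUE, prob = prob), collapse = "")
}

# quick TranscriptSet builder: df columns transcript_id, gene_id, seqid,
# strand, and a list column of exon (start, end) matrices
makeTs <- function(df, biotype = "candidate") {
  grl <- GenomicRanges::GRangesList(lapply(seq_len(nrow(df)), function(i) {
    ex <- df$exons[[i]]
    GenomicRanges::GRanges(df$seqid[i],
                           IRanges::IRanges(ex[, 1], ex[, 2]),
                           strand = df$strand[i])
  }))
  names(grl) <- df$transcript_id
  TranscriptSet(grl, geneId = df$gene_id,
                biotype = rep_len(biotype, nrow(df)))
}

# random toy annotation for the overlap/classification oracles:
# coding genes with 1-4 exons and candidate transcripts scattered over
# two scaffolds so that every positional relation occurs
randomToyAnnotation <- function(nGenes = 150, nCand = 350,
                                scaffolds = c("sA", "sB"),
                                scafLen = 200000L) {
  mkTx <- function(id, gid) {
    k <- sample(1:4, 1)
    w <- sample(80:300, k, replace = TRUE)
    gaps <- if (k > 1) sample(50:1500, k - 1, replace = TRUE) else integer(0)
    s0 <- sample.int(scafLen - sum(w) - sum(gaps) - 10L, 1)
    starts <- s0 + cumsum(c(0L, w[-k] + gaps))
    data.frame(transcript_id = id, gene_id = gid,
               seqid = sample(scaffolds, 1),
               strand = sample(c("+", "-"), 1)) -> d
    d$exons <- list(cbind(starts, starts + w - 1L))
    d
  }
  genes <- do.call(rbind, lapply(seq_len(nGenes), function(i) {
    mkTx(sprintf("tm%03d", i), sprintf("tg%03d", i))
  }))
  cand <- do.call(rbind, lapply(seq_len(nCand), function(i) {
    mkTx(sprintf("tc%03d", i), sprintf("tcg%03d", i))
  }))
  list(coding = makeTs(genes, "coding"), cand = makeTs(cand, "candidate"),
       genesDf = genes, candDf = cand)
}

# total overlap length of two sets of disjoint closed intervals
ovLen <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + max(0L, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]) + 1L)
  }
  tot
}

# naive all-pairs same-strand exonic-overlap filter
oracleOverlapRemoved <- function(candDf, genesDf) {
  removed <- character(0)
  for (i in seq_len(nrow(candDf))) {
    hit <- FALSE
    for (j in seq_len(nrow(genesDf))) {
      if (candDf$seqid[i] != genesDf$seqid[j]) next
      if (candDf$strand[i] != genesDf$strand[j]) next
      if (ovLen(candDf$exons[[i]], genesDf$exons[[j]]) > 0) { hit <- TRUE; break }
    }
    if (hit) removed <- c(removed, candDf$transcript_id[i])
  }
  removed
}

# naive classifier following the stated decision order
oracleClassify <- function(candDf, genesDf) {
  spans <- t(vapply(genesDf$exons, function(e) c(min(e[, 1]), max(e[, 2])),
                    numeric(2)))
  introns <- lapply(genesDf$exons, function(e) {
    if (nrow(e) < 2) return(matrix(numeric(0), 0, 2))
    cbind(e[-nrow(e), 2] + 1, e[-1, 1] - 1)
  })
  out <- data.frame(transcript_id = candDf$transcript_id,
                    lnc_class = NA_character_,
                    partner_gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(candDf))) {
    ex <- candDf$exons[[i]]
    s <- min(ex[, 1]); e <- max(ex[, 2])
    onScaf <- which(genesDf$seqid == candDf$seqid[i])
    spanOv <- onScaf[spans[onScaf, 1] <= e & spans[onScaf, 2] >= s]
    if (!length(spanOv)) { out$lnc_class[i] <- "intergenic"; next }
    # antisense: exonic overlap with opposite-strand gene exons
    opp <- spanOv[genesDf$strand[spanOv] != candDf$strand[i]]
    exOv <- vapply(opp, function(j) ovLen(ex, genesDf$exons[[j]]), 0L)
    if (length(opp) && any(exOv > 0)) {
      sel <- opp[exOv > 0]
      ov <- exOv[exOv > 0]
      ord <- order(-ov, genesDf$gene_id[sel])
      out$lnc_class[i] <- "antisense"
      out$partner_gene_id[i] <- genesDf$gene_id[sel][ord[1]]
      next
    }
    # intronic: same strand, whole span inside one intron
    same <- spanOv[genesDf$strand[spanOv] == candDf$strand[i]]
    host <- same[vapply(same, function(j) {
      ii <- introns[[j]]
      any(ii[, 1] <= s & ii[, 2] >= e)
    }, logical(1))]
    if (length(host)) {
      out$lnc_class[i] <- "intronic"
      out$partner_gene_id[i] <- sort(genesDf$gene_id[host])[1]
      next
    }
    out$lnc_class[i] <- "other"
    ov <- vapply(spanOv, function(j) {
      max(0, min(spans[j, 2], e) - max(spans[j, 1], s) + 1)
    }, 0)
    ord <- order(-ov, genesDf$gene_id[spanOv])
    out$partner_gene_id[i] <- genesDf$gene_id[spanOv][ord[1]]
  }
  out
}

# independent step-up BH implementation from the definition
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  cummin_rev <- rev(cummin(rev(m * p[o] / seq_len(m))))
  adj[o] <- pmin(1, cummin_rev)
  adj
}

# exhaustive hypergeometric upper tail by enumeration of draws
oracleHyperUpper <- function(N, K, n, k) {
  sum(vapply(k:min(K, n), function(x) {
    choose(K, x) * choose(N - K, n - x)
  }, 0)) / choose(N, n)
}

# the default simulated dataset, built once and shared across test files
.simCache <- new.env(parent = emptyenv())
defaultSim <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.simCache[[key]])) {
    .simCache[[key]] <- simulateDataset(simulationConfig(seed = seed))
  }
  .simCache[[key]]
}
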