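mk1 <- function(id, seqid, strand, exons, gene = id) {
  df <- data.frame(transcript_id = id, gene_id = gene,
                   seqid = seqid, strand = strand)
  df$exons <- list(exons)
  df
}

test_that("the longest-ORF finder matches hand-scanned cases", {
  expect_equal(longestOrf("ATGAAATAG"), 2L)
  expect_equal(longestOrf("CCCCCCCCC"), 0L)
  expect_equal(longestOrf(""), 0L)
  # ATG + 100 sense codons + TAA: 101 aa, confirmed by the brute-force scan
  seq <- paste0("ATG", strrep("GCT", 100), "TAA")
  expect_equal(longestOrf(seq), 101L)
  expect_equal(oracleLongestOrf(seq), 101L)
  # an ORF ends at its FIRST in-frame stop
  expect_equal(longestOrf("ATGAAATAGAAAAAATAA"), 2L)
  # codons containing N are neither starts nor stops
  expect_equal(longestOrf("ATGAAATNAAAATAA"), 4L)
  expect_equal(longestOrf("ATNAAATAA"), 0L)
})

test_that("the longest-ORF finder agrees with the brute-force oracle on random sequences", {
  withr::with_seed(101, {
    for (i in 1:60) {
      s <- randomDnaString(sample(10:400, 1), withN = i %% 3 == 0)
      expect_identical(longestOrf(s), oracleLongestOrf(s))
    }
  })
})

test_that("the built-in coding score is ORF coverage of the transcript", {
  full <- paste0("ATG", strrep("GCT", 99), "TAA")  # one ORF end to end
  expect_equal(builtinCodingScore(full), 1.0)
  expect_equal(builtinCodingScore("CCCCCCCC"), 0.0)
  # 1000 nt with longest ORF 99 aa -> (297 + 3) / 1000
  orf99 <- paste0("ATG", strrep("GCT", 98), "TAA")  # 300 nt, 99 aa
  pad <- strrep("TTAATTAATTAA", 59)                 # 708 nt of stops
  seq <- paste0(substr(pad, 1, 700), orf99)
  expect_equal(nchar(seq), 1000L)
  expect_equal(longestOrf(seq), 99L)
  expect_equal(builtinCodingScore(seq), 0.30)
})

test_that("the structural filter enforces length, exon count, and strand", {
  df <- rbind(
    mk1("keep200", "c1", "+", cbind(c(1, 151), c(100, 250))),      # 200 nt, 2 ex
    mk1("single", "c1", "+", cbind(1, 5000)),                      # 1 exon
    mk1("nostrand", "c1", "*", cbind(c(1, 201), c(150, 350))),     # 300 nt
    mk1("short", "c1", "-", cbind(c(1, 101), c(80, 170))))         # 150 nt
  step <- filterStructure(makeTs(df))
  expect_setequal(txIds(step$survivors), "keep200")
  expect_equal(step$reasons[["single"]], "single_exon")
  expect_equal(step$reasons[["nostrand"]], "no_strand")
  expect_equal(step$reasons[["short"]], "short")
})

test_that("exonic overlap with coding genes is strand-aware", {
  coding <- makeTs(mk1("cod1", "c1", "+", cbind(c(150, 400), c(160, 500))),
                   biotype = "coding")
  cand <- rbind(
    mk1("sameStrand", "c1", "+", cbind(c(100, 600), c(200, 700))),
    mk1("oppStrand", "c1", "-", cbind(c(100, 600), c(200, 700))),
    mk1("inIntron", "c1", "+", cbind(c(170, 300), c(250, 390))))
  step <- filterExonOverlap(makeTs(cand), coding)
  expect_setequal(step$removed, "sameStrand")
  expect_setequal(txIds(step$survivors), c("oppStrand", "inIntron"))
  both <- filterExonOverlap(makeTs(cand), coding, strandMode = "both")
  expect_setequal(both$removed, c("sameStrand", "oppStrand"))
})

test_that("exonic-overlap filtering matches the naive all-pairs oracle", {
  withr::with_seed(77, {
    toy <- randomToyAnnotation(nGenes = 60, nCand = 120)
  })
  step <- filterExonOverlap(toy$cand, toy$coding)
  expect_setequal(step$removed, oracleOverlapRemoved(toy$candDf, toy$genesDf))
})

test_that("the coding filter applies the strict ORF rule, then evidence, then the built-in score", {
  df <- rbind(mk1("orf100", "c1", "+", cbind(1, 400)),
              mk1("orf99", "c1", "+", cbind(1, 400)),
              mk1("pfamCoding", "c1", "+", cbind(1, 400)),
              mk1("builtinHigh", "c1", "+", cbind(1, 400)))
  ts <- makeTs(df)
  ev <- data.frame(
    transcript_id = c("orf100", "orf99", "pfamCoding", "builtinHigh"),
    longest_orf_aa = c(100L, 99L, 50L, 60L),
    builtin_score = c(0.76, 0.30, 0.38, 0.60),
    blastx = c("noncoding", "noncoding", "noncoding", "absent"),
    pfam = c("noncoding", "noncoding", "coding", "absent"),
    cpc2 = c("noncoding", "noncoding", "noncoding", "absent"),
    rnaplonc = c("noncoding", "noncoding", "noncoding", "absent"),
    stringsAsFactors = FALSE)
  step <- filterCoding(ts, ev)
  expect_setequal(txIds(step$survivors), "orf99")
  expect_equal(step$reasons[["orf100"]], "orf")   # exactly 100 aa: removed
  expect_equal(step$reasons[["pfamCoding"]], "pfam")
  expect_equal(step$reasons[["builtinHigh"]], "builtin_score")
  expect_error(filterCoding(ts, ev[-1, ]), "missing coding evidence")
  expect_error(filterCoding(ts, ev, fallback = FALSE), "fallback disabled")
})

test_that("read support keeps a total of exactly minReads and errors on missing rows", {
  df <- rbind(mk1("six", "c1", "+", cbind(1, 300)),
              mk1("five", "c1", "+", cbind(1, 300)),
              mk1("zero", "c1", "+", cbind(1, 300)))
  ts <- makeTs(df)
  counts <- rbind(six = c(3L, 3L), five = c(2L, 3L), zero = c(0L, 0L))
  colnames(counts) <- c("a", "b")
  step <- filterReadSupport(ts, counts)
  expect_setequal(txIds(step$survivors), "six")
  expect_equal(unname(readSupport(step$survivors)[["six"]]), 6L)
  expect_error(filterReadSupport(ts, counts[1:2, ]), "absent from count")
})

test_that("the cascade funnel is monotone and partitions the input", {
  sim <- defaultSim()
  res <- runIdentification(sim$annotation, sim$seqs, sim$counts)
  f <- res$funnel
  expect_true(all(f$n_out <= f$n_in))
  expect_equal(f$n_in[-1], f$n_out[-nrow(f)])
  removed <- unlist(f$removed)
  expect_setequal(c(removed, txIds(res$lncrna)), txIds(sim$annotation))
  expect_equal(length(removed) + length(res$lncrna), length(sim$annotation))
  expect_true(all(txBiotype(res$lncrna) == "lncRNA"))
  # nothing the generator labeled coding survives
  cod <- sim$truth$transcript_id[sim$truth$true_class == "coding"]
  expect_length(intersect(cod, txIds(res$lncrna)), 0L)
})

test_that("an empty annotation yields an empty result and a funnel of zeros", {
  ts <- TranscriptSet(GenomicRanges::GRangesList())
  counts <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("a", "b")))
  seqs <- Biostrings::DNAStringSet(c(c1 = "ACGT"))
  res <- runIdentification(ts, seqs, counts)
  expect_equal(length(res$lncrna), 0L)
  expect_true(all(res$funnel$n_in == 0L) && all(res$funnel$n_out == 0L))
})
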