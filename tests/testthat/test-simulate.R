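test_that("the generator produces the requested class counts and valid annotation", {
  cfg <- simulationConfig(seed = 5, nCoding = 30, nLncIntergenic = 12,
                          nLncAntisense = 5, nLncIntronic = 2, nLncOther = 1,
                          nDecoyShort = 2, nDecoySingleExon = 2,
                          nDecoyNoStrand = 2, nDecoyLongOrf = 2,
                          nDecoyLowSupport = 2, nBlocks = 2L,
                          blockCoding = 5L, blockLnc = 1L)
  g <- simulateGenome(cfg)
  expect_s4_class(g$annotation, "TranscriptSet")
  expect_true(methods::validObject(g$annotation))
  tab <- table(g$truth$true_class)
  expect_equal(unname(tab[["coding"]]), 30L)
  expect_equal(sum(startsWith(g$truth$true_class, "lncRNA_")), 20L)
  expect_equal(unname(tab[["decoy_no_strand"]]), 2L)
  # truth and annotation agree one-to-one
  expect_setequal(g$truth$transcript_id, txIds(g$annotation))
  # biotype never leaks truth: only coding/candidate before identification
  expect_setequal(unique(unname(txBiotype(g$annotation))),
                  c("coding", "candidate"))
})

test_that("planted coding ORFs and frame-broken lncRNAs verify under the ORF finder", {
  sim <- defaultSim()
  tr <- sim$truth
  stranded <- sim$annotation[txStrand(sim$annotation) != "*"]
  orf <- vapply(as.character(spliceTranscriptSeq(stranded, sim$seqs)),
                longestOrf, integer(1))
  cod <- intersect(tr$transcript_id[tr$true_class == "coding"], names(orf))
  lnc <- intersect(tr$transcript_id[startsWith(tr$true_class, "lncRNA_")],
                   names(orf))
  expect_true(all(orf[cod] >= 100L))
  expect_true(all(orf[lnc] < 100L))
  long <- intersect(tr$transcript_id[tr$true_class == "decoy_long_orf"],
                    names(orf))
  expect_true(all(orf[long] >= 100L))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulationConfig(seed = 77, nCoding = 20, nLncIntergenic = 8,
                          nLncAntisense = 3, nLncIntronic = 1, nLncOther = 1,
                          nDecoyShort = 1, nDecoySingleExon = 1,
                          nDecoyNoStrand = 1, nDecoyLongOrf = 1,
                          nDecoyLowSupport = 1, nBlocks = 1L,
                          blockCoding = 4L, blockLnc = 1L)
  a <- simulateDataset(cfg)
  b <- simulateDataset(cfg)
  expect_identical(as.character(a$seqs), as.character(b$seqs))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulation(a, d1); writeSimulation(b, d2)
  for (f in c("genome.fa", "transcripts.gtf", "counts.tsv", "terms.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generator output survives the round trip through the readers", {
  sim <- defaultSim()
  dir <- tempfile()
  writeSimulation(sim, dir)
  back <- readTranscriptGtf(file.path(dir, "transcripts.gtf"))
  expect_setequal(txIds(back), txIds(sim$annotation))
  back <- back[txIds(sim$annotation)]
  expect_identical(unname(txStrand(back)), unname(txStrand(sim$annotation)))
  expect_identical(unname(txLengths(back)), unname(txLengths(sim$annotation)))
  expect_identical(unname(txBiotype(back)), unname(txBiotype(sim$annotation)))
  cm <- readCountsTsv(file.path(dir, "counts.tsv"))
  expect_identical(cm, sim$counts)
  expect_silent(readDesignTsv(file.path(dir, "design.tsv"), counts = cm))
  expect_gt(nrow(readTermMapTsv(file.path(dir, "terms.tsv"))), 0L)
})

test_that("low-support decoys are planted with at most 5 total reads", {
  sim <- defaultSim()
  low <- sim$truth$transcript_id[sim$truth$true_class == "decoy_low_support"]
  expect_true(all(rowSums(sim$counts[low, , drop = FALSE]) <= 5))
})

test_that("counts are Poisson in the zero-dispersion limit", {
  cfg <- simulationConfig(seed = 6, dispersion = 0, libSizeRange = 1,
                          blockSd = 0, propSpecificLnc = 0,
                          propSpecificMrna = 0, nBlocks = 0L,
                          nDecoyLowSupport = 0L)
  g <- simulateGenome(cfg)
  cc <- simulateCounts(g$truth, txLengths(g$annotation), cfg)
  m <- cc$counts
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_equal(mean(ratio), 1, tolerance = 0.1)
})

test_that("exchangeable tissues give near-uniform specificity scores", {
  cfg <- simulationConfig(seed = 16, specificityFold = 1, blockSd = 0,
                          nBlocks = 0L, nDecoyLowSupport = 0L)
  g <- simulateGenome(cfg)
  cc <- simulateCounts(g$truth, txLengths(g$annotation), cfg)
  se <- buildExpression(cc$counts, cc$design, txLengths(g$annotation))
  rec <- specificityScores(tissueMeanFpkm(se))
  expect_equal(mean(rec$score[rec$defined]), 1 / 6, tolerance = 0.35)
  scr <- screenSpecific(rec)
  expect_lt(mean(scr$records$specific), 0.02)
})
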