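test_that("GC content excludes N from the denominator", {
  expect_equal(unname(gcContent("ATGC")), 0.5)
  expect_equal(unname(gcContent("GGCC")), 1.0)
  expect_equal(unname(gcContent("ANGC")), 2 / 3)
  expect_true(is.na(gcContent("NNNN")))
})

test_that("TMM factors behave on identical, depth-scaled, and degenerate libraries", {
  withr::with_seed(9, {
    x <- matrix(rnbinom(400, mu = 50, size = 10), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  })
  x[, 2] <- x[, 1]
  expect_equal(unname(tmmFactors(x)), c(1, 1), tolerance = 1e-9)
  y <- cbind(a = x[, 1], b = 3L * x[, 1])  # pure depth change
  expect_equal(unname(tmmFactors(y)), c(1, 1), tolerance = 1e-9)
  z <- matrix(c(5L, 3L, 0L, 0L, 0L, 7L), ncol = 2)  # no common nonzero gene
  expect_warning(fz <- tmmFactors(z), "no genes expressed in both")
  expect_equal(unname(fz), c(1, 1))
  expect_error(tmmFactors(x[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("TMM factors have geometric mean 1 and match the edgeR reference", {
  skip_if_not_installed("edgeR")
  withr::with_seed(12, {
    for (i in 1:5) {
      n <- 400
      mu <- exp(rnorm(n, 4, 1.5))
      m <- sapply(1:5, function(j) rnbinom(n, mu = mu * runif(1, 0.5, 2),
                                           size = 5))
      colnames(m) <- paste0("s", 1:5)
      f <- tmmFactors(m)
      expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
      ref <- edgeR::calcNormFactors(m, method = "TMM")
      expect_equal(unname(f), unname(ref), tolerance = 1e-8)
    }
  })
})

test_that("FPKM follows its defining formula exactly", {
  cm <- matrix(c(10L, 0L), 1, 2, dimnames = list("t1", c("a", "b")))
  f <- fpkmMatrix(cm, lengths = c(t1 = 1000), factors = c(a = 1, b = 1),
                  libSize = c(a = 1e6, b = 1e6))
  expect_equal(unname(f["t1", ]), c(10, 0))
  half <- fpkmMatrix(cm, lengths = c(t1 = 1000), factors = c(a = 2, b = 1),
                     libSize = c(a = 1e6, b = 1e6))
  expect_equal(unname(half["t1", "a"]), 5)
  # row scales inversely with length
  dbl <- fpkmMatrix(cm, lengths = c(t1 = 2000), factors = c(a = 1, b = 1),
                    libSize = c(a = 1e6, b = 1e6))
  expect_equal(unname(dbl["t1", "a"]), 5)
  expect_error(fpkmMatrix(cm, lengths = c(other = 10)), "missing length")
})

test_that("feature tables report lengths, introns, and GC per transcript", {
  seqs <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 200)))
  df <- data.frame(transcript_id = "t1", gene_id = "g1", seqid = "c1",
                   strand = "+")
  df$exons <- list(cbind(c(1, 201), c(100, 300)))
  ts <- makeTs(df)
  ft <- featureTable(ts, seqs)
  expect_equal(ft$length, 200L)
  expect_equal(ft$n_exons, 2L)
  expect_equal(ft$intron_lengths[[1]], 100L)
  expect_equal(sum(ft$exon_lengths[[1]]), ft$length)
  expect_equal(ft$gc, 0.5)
})

test_that("group comparisons are symmetric for identical groups and see planted shifts", {
  sim <- defaultSim()
  tr <- sim$truth
  lncIds <- tr$transcript_id[startsWith(tr$true_class, "lncRNA_")]
  coding <- sim$annotation[txBiotype(sim$annotation) == "coding"]
  ftL <- featureTable(sim$annotation[lncIds], sim$seqs)
  ftM <- featureTable(coding, sim$seqs)
  same <- compareGroups(ftL, ftL)
  expect_true(all(same$wilcox_p[same$feature == "length"] > 0.9))
  cmp <- compareGroups(ftL, ftM)
  med <- function(g, f) cmp$q50[cmp$group == g & cmp$feature == f]
  # lncRNAs are built shorter and AT-richer than mRNAs
  expect_lt(med("lncRNA", "length"), med("mRNA", "length"))
  expect_lt(med("lncRNA", "gc"), med("mRNA", "gc"))
  expect_lt(med("lncRNA", "n_exons"), med("mRNA", "n_exons"))
})

test_that("bin assignment uses the leftmost coordinate with 1-based closed bins", {
  mk <- function(id, start, strand = "+") {
    df <- data.frame(transcript_id = id, gene_id = id, seqid = "c1",
                     strand = strand)
    df$exons <- list(cbind(start, start + 99))
    df
  }
  lnc <- makeTs(rbind(mk("a", 50000 - 99), mk("b", 50001)))
  cod <- makeTs(mk("m", 1), biotype = "coding")
  prof <- binDistribution(lnc, cod, binSize = 50000)
  expect_equal(prof$lnc_count[prof$bin == 1], 1L)  # starts at 49901 -> bin 1
  expect_equal(prof$lnc_count[prof$bin == 2], 1L)  # starts at 50001 -> bin 2
  expect_equal(sum(prof$lnc_count), 2L)
  expect_equal(sum(prof$mrna_count), 1L)
  expect_equal(prof$lnc_plus + prof$lnc_minus, prof$lnc_count)
})

test_that("bin correlation is 1 for identical placements and near 0 for independent ones", {
  mkMany <- function(prefix, starts, strand = "+") {
    df <- do.call(rbind, lapply(seq_along(starts), function(i) {
      d <- data.frame(transcript_id = paste0(prefix, i),
                      gene_id = paste0(prefix, i), seqid = "c1",
                      strand = strand)
      d$exons <- list(cbind(starts[i], starts[i] + 49))
      d
    }))
    makeTs(df)
  }
  withr::with_seed(21, {
    starts <- sample.int(5e6, 300)
    same <- binCorrelation(binDistribution(mkMany("l", starts),
                                           mkMany("m", starts),
                                           binSize = 50000))
    expect_equal(same$pearson_r[same$seqid == "all"], 1.0)
    indep <- binCorrelation(binDistribution(
      mkMany("l", sample.int(5e6, 400)), mkMany("m", sample.int(5e6, 400)),
      binSize = 50000))
    expect_lt(abs(indep$pearson_r[indep$seqid == "all"]), 0.25)
  })
})

test_that("bin counts conserve transcript totals on simulated data", {
  sim <- defaultSim()
  tr <- sim$truth
  lncIds <- tr$transcript_id[startsWith(tr$true_class, "lncRNA_")]
  coding <- sim$annotation[txBiotype(sim$annotation) == "coding"]
  prof <- binDistribution(sim$annotation[lncIds], coding,
                          seqLengths = setNames(BiocGenerics::width(sim$seqs),
                                                names(sim$seqs)))
  expect_equal(sum(prof$lnc_count), length(lncIds))
  expect_equal(sum(prof$mrna_count), length(coding))
})
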