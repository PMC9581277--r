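test_that("Pearson correlation p-values match the t transform and cor.test", {
  p <- pearsonWithP(1:10, 1:10)
  expect_equal(p$r, 1)
  expect_equal(p$p, 0)
  withr::with_seed(8, {
    for (i in 1:20) {
      m <- sample(4:30, 1)
      x <- rnorm(m); y <- rnorm(m)
      got <- pearsonWithP(x, y)
      ref <- cor.test(x, y)
      expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    }
  })
  # hand case of the transform: m = 5, r = 0.9 -> t ~ 3.576, p ~ 0.0374
  r <- 0.9; m <- 5
  tstat <- r * sqrt(m - 2) / sqrt(1 - r^2)
  expect_equal(tstat, 3.576, tolerance = 1e-3)
  expect_equal(2 * pt(-tstat, 3), 0.0374, tolerance = 1e-3)
  expect_error(pearsonWithP(1:2, 1:2), "at least 3")
  expect_true(is.na(pearsonWithP(rep(1, 5), 1:5)$r))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      adj <- bhAdjust(p)
      expect_equal(adj, oracleBH(p), tolerance = 1e-12)
      # permutation invariance and monotonicity in sorted order
      perm <- sample(seq_along(p))
      expect_equal(bhAdjust(p[perm]), adj[perm], tolerance = 1e-12)
      expect_true(all(diff(adj[order(p)]) >= -1e-12))
    }
  })
})

test_that("the hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeomUpper(10, 4, 5, 0), 1.0)
  expect_equal(hypergeomUpper(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  # k = n = K: a single term C(K, n) / C(N, n)
  expect_equal(hypergeomUpper(8, 3, 3, 3), choose(3, 3) / choose(8, 3),
               tolerance = 1e-12)
  expect_error(hypergeomUpper(10, 4, 5, 5), "infeasible")
  expect_error(hypergeomUpper(10, 12, 5, 2), "invalid")
  for (N in 4:9) for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
    expect_equal(hypergeomUpper(N, K, n, k), oracleHyperUpper(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("co-expression edges require r strictly above 0.8 and adjusted p strictly below 0.05", {
  x <- c(1, 2, 3, 4)
  mrna <- rbind(perfect = x, exact08 = c(1, 2, 4, 3), anti = rev(x))
  colnames(mrna) <- paste0("s", 1:4)
  lnc <- matrix(x, 1, dimnames = list("l1", colnames(mrna)))
  e <- coexpressionEdges(lnc, mrna, qCut = 1)  # isolate the r rule
  r <- setNames(e$r, e$mrna_id)
  expect_equal(unname(r[c("perfect", "exact08", "anti")]), c(1, 0.8, -1))
  sel <- setNames(e$selected, e$mrna_id)
  expect_true(sel[["perfect"]])
  expect_false(sel[["exact08"]])   # r = 0.8 exactly: strict > fails
  expect_false(sel[["anti"]])
  expect_error(coexpressionEdges(lnc[, 1:2, drop = FALSE],
                                 mrna[, 1:2, drop = FALSE]), "at least 3")
})

test_that("edge selection is invariant to positive affine rescaling of expression", {
  withr::with_seed(19, {
    lnc <- matrix(rexp(5 * 12), 5, 12,
                  dimnames = list(paste0("l", 1:5), paste0("s", 1:12)))
    mrna <- matrix(rexp(20 * 12), 20, 12,
                   dimnames = list(paste0("m", 1:20), paste0("s", 1:12)))
    mrna[1, ] <- lnc[1, ] * 2 + rnorm(12, sd = 0.01)
    a <- coexpressionEdges(lnc, mrna)
    b <- coexpressionEdges(lnc * 3.7 + 2, mrna * 0.21 + 5)
    expect_equal(a$r, b$r, tolerance = 1e-9)
    expect_identical(a$selected, b$selected)
    expect_true(a$selected[a$lnc_id == "l1" & a$mrna_id == "m1"])
  })
})

test_that("enrichment flags planted terms and leaves absent terms at p = 1", {
  edges <- data.frame(lnc_id = "l1", mrna_id = paste0("g", 1:5),
                      selected = TRUE)
  termMap <- rbind(
    data.frame(gene_id = paste0("g", 1:5), term_id = "GO:PLANT",
               term_name = "planted", namespace = "BP"),
    data.frame(gene_id = paste0("g", 6:50), term_id = "GO:OTHER",
               term_name = "other", namespace = "BP"))
  bg <- paste0("g", 1:50)
  en <- enrichTerms(edges, termMap, background = bg)
  planted <- en[en$term_id == "GO:PLANT", ]
  expect_equal(planted$k, 5L)
  expect_equal(planted$N, 50L)
  expect_lt(planted$p_adj, 0.1)
  expect_true(planted$significant)
  other <- en[en$term_id == "GO:OTHER", ]
  expect_equal(other$k, 0L)
  expect_equal(other$p, 1)
  expect_false(other$significant)
  expect_error(enrichTerms(edges, termMap[termMap$namespace == "KEGG", ],
                           background = bg))
})

test_that("profile reports count lncRNAs per significant term within groups", {
  en <- data.frame(
    lnc_id = c("l1", "l2", "l1", "l3"),
    namespace = "BP",
    term_id = c("T1", "T1", "T2", "T1"),
    term_name = c("one", "one", "two", "one"),
    N = 50L, K = 5L, n = 5L, k = 3L, p = 1e-4, p_adj = 1e-3,
    significant = c(TRUE, TRUE, TRUE, FALSE))
  groups <- data.frame(transcript_id = c("l1", "l2", "l3"),
                       group = c("latex", "latex", "non_specific"))
  prof <- profileReport(en, groups)
  latexT1 <- prof[prof$group == "latex" & prof$term_id == "T1", ]
  expect_equal(latexT1$n_lnc, 2L)
  expect_equal(latexT1$rank, 1L)
  expect_false("non_specific" %in% prof$group)  # l3 row was not significant
})
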