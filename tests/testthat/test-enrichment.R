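mkScanTable <- function(drivers, kos, ts) {
  df <- data.frame(driver = drivers, ko_gene = kos, t = ts, p = 0.5,
                   fdr = 0.5, mean_mut = 0, mean_wt = 0, n_mut = 2L,
                   n_wt = 2L, filtered = FALSE, significant = FALSE,
                   stringsAsFactors = FALSE)
  new("SLResultTable", results = df, metadata = list())
}

test_that("ranked lists append the driver at the mean partner score", {
  tab <- mkScanTable(rep("drv", 2), c("gA", "gB"), c(3.0, -2.0))
  rl <- buildRankedList("drv", tab)
  expect_equal(rl$gene, c("gA", "gB", "drv"))
  expect_equal(rl$score, c(3.0, -2.0, 0.5))
  expect_equal(attr(rl, "driver"), "drv")

  single <- buildRankedList("drv", mkScanTable("drv", "gA", -4))
  expect_equal(single$score, c(-4, -4))
  ## full tie (same |score| and raw score): lexicographic gene id
  expect_equal(single$gene, c("drv", "gA"))

  zero <- buildRankedList("drv", mkScanTable(rep("drv", 2),
                                             c("gA", "gB"), c(0, 0)))
  expect_equal(zero$score, rep(0, 3))
  expect_error(buildRankedList("ghost", tab), "no tested pairs")
})

test_that("self-pairs never duplicate the driver in its own list", {
  tab <- mkScanTable(rep("drv", 3), c("gA", "drv", "gB"), c(3, 9, -2))
  rl <- buildRankedList("drv", tab)
  expect_equal(sum(rl$gene == "drv"), 1)
  expect_equal(rl$score[rl$gene == "drv"], 0.5)  # mean of 3 and -2
})

test_that("enrichment score follows the weighted running sum", {
  ranked <- data.frame(gene = paste0("g", 1:4), score = c(4, 3, 2, 1),
                       stringsAsFactors = FALSE)
  res <- prerankedGsea(ranked, list(top = c("g1", "g2")), nPerm = 50,
                       seed = 1)
  expect_equal(res$ES, 1.0)            # 4/7 then 7/7 before any miss
  ## hand-computed alternative: set {g1, g4}
  res2 <- prerankedGsea(ranked, list(s = c("g1", "g4")), nPerm = 50,
                        seed = 1)
  expect_equal(res2$ES, 4 / 5, tolerance = 1e-12)

  skipres <- prerankedGsea(ranked,
                           list(none = c("zz"), all = paste0("g", 1:4),
                                small = "g1"), nPerm = 10, seed = 1)
  expect_equal(nrow(skipres), 0)
  expect_setequal(attr(skipres, "skipped"), c("none", "all", "small"))
})

test_that("ES is bounded and maximal for the top prefix among same sizes", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 8
    scores <- sort(abs(rnorm(n)), decreasing = TRUE)
    for (size in 2:4) {
      esAll <- apply(utils::combn(n, size), 2, function(idx) {
        hit <- logical(n); hit[idx] <- TRUE
        metaboSL:::.gseaES(scores, hit)
      })
      expect_true(all(esAll >= -1 - 1e-12 & esAll <= 1 + 1e-12))
      prefixES <- metaboSL:::.gseaES(scores,
                                     seq_len(n) <= size)
      expect_gte(prefixES + 1e-12, max(esAll))
    }
  }
})

test_that("permutation p-values are reproducible and seed-derived per set", {
  ranked <- data.frame(gene = paste0("g", 1:12),
                       score = seq(6, 0.5, length.out = 12))
  sets <- list(a = c("g1", "g2", "g3"), b = c("g10", "g11", "g12"))
  r1 <- prerankedGsea(ranked, sets, nPerm = 200, seed = 5)
  r2 <- prerankedGsea(ranked, sets, nPerm = 200, seed = 5)
  expect_identical(r1, r2)
  ## set order must not matter
  r3 <- prerankedGsea(ranked, rev(sets), nPerm = 200, seed = 5)
  expect_equal(r1[match(r3$set, r1$set), "p"], r3$p)
  ## a coherent top set should look more enriched than a bottom set
  expect_lt(r1$p[r1$set == "a"], 0.2)
})

test_that("null permutation p-values are roughly uniform", {
  set.seed(77)
  pvals <- replicate(50, {
    scores <- sort(abs(rnorm(20)), decreasing = TRUE)
    genes <- paste0("g", 1:20)
    ranked <- data.frame(gene = genes, score = scores,
                         stringsAsFactors = FALSE)
    hit <- sample(genes, 5)
    prerankedGsea(ranked, list(s = hit), nPerm = 200,
                  seed = sample.int(1e6, 1))$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 1e-3)
  expect_lt(abs(mean(pvals) - 0.5), 0.1)
})

test_that("implementation agrees with the reference GSEA statistic", {
  skip_if_not_installed("fgsea")
  set.seed(101)
  for (rep in 1:10) {
    n <- 25
    stats <- sort(runif(n, 0.1, 5), decreasing = TRUE)
    names(stats) <- paste0("g", 1:n)
    idx <- sort(sample(n, 6))
    mine <- metaboSL:::.gseaES(unname(stats),
                               seq_len(n) %in% idx)
    ref <- fgsea::calcGseaStat(stats, selectedStats = idx, gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("process frequencies count significant drivers per set", {
  res <- list(
    d1 = data.frame(set = c("S1", "S2"), size = 3, ES = 0.5,
                    p = c(0.01, 0.2)),
    d2 = data.frame(set = c("S1", "S2"), size = 3, ES = 0.5,
                    p = c(0.04, 0.04)),
    d3 = data.frame(set = c("S1", "S3"), size = 3, ES = 0.5,
                    p = c(0.5, 0.01)))
  freq <- processFrequency(res, alpha = 0.05)
  expect_equal(freq$set, c("S1", "S2", "S3"))
  expect_equal(freq$frequency, c(2L, 1L, 1L))
  expect_true(all(freq$frequency <= length(res)))
  expect_equal(nrow(processFrequency(list())), 0)
})
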