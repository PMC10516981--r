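test_that("KO-gene lists come from the parsimonious flux support", {
  toyP <- makeToyModel("parallel")
  expect_equal(deriveKoGeneList(toyP), "g1")
  ## restricted context (backup route removed): the AND-free chain
  ctx <- subsetReactions(toyP, c("EX_A", "R1", "BIO"))
  expect_equal(deriveKoGeneList(ctx), "g1")
  ## no GPRs anywhere -> empty list
  bare <- MetabolicModel("bare", list(
    EX = list(metabolites = c(A = 1), lb = 0, ub = 1),
    B = list(metabolites = c(A = -1), lb = 0, ub = 10, objective = 1)))
  expect_equal(deriveKoGeneList(bare), character(0))
  expect_true(all(deriveKoGeneList(toyP) %in% modelGenes(toyP)))
})

test_that("the KO-score matrix defaults to 1 outside each KO list", {
  toyP <- makeToyModel("parallel")
  noBackup <- subsetReactions(toyP, c("EX_A", "R1", "BIO"))
  universe <- c(modelGenes(toyP), "absent_gene")
  ko <- buildKoScoreMatrix(list(CL1 = noBackup, CL2 = toyP), universe)
  sc <- koScores(ko)
  expect_equal(dim(sc), c(5L, 2L))
  expect_equal(sc["g1", "CL1"], 0)      # essential in the cut-down context
  expect_equal(sc["g1", "CL2"], 1)      # reroutes in the full model
  expect_equal(unname(sc["absent_gene", ]), c(1, 1))
  expect_true(all(sc >= 0 & sc <= 1))
  ## KOScoreMatrix validity refuses out-of-range entries
  bad <- matrix(1.2, 1, 1, dimnames = list("g", "c"))
  expect_error(KOScoreMatrix(bad), "ratios")
})

test_that("driver genes need damaging mutations in enough lines", {
  calls <- matrix(FALSE, 3, 6,
                  dimnames = list(c("gA", "gB", "gC"),
                                  sprintf("CL%02d", 1:6)))
  calls["gA", c(1, 4)] <- TRUE
  calls["gB", 2] <- TRUE
  mm <- new("MutationMatrix", calls = calls, provenance = list())
  expect_equal(identifyDriverGenes(mm), "gA")
  expect_equal(identifyDriverGenes(mm, minMutatedLines = 1),
               c("gA", "gB"))
  none <- new("MutationMatrix",
              calls = matrix(FALSE, 2, 2,
                             dimnames = list(c("x", "y"), c("a", "b"))),
              provenance = list())
  expect_equal(identifyDriverGenes(none), character(0))
})

test_that("pair test: filter, closed-form t, and zero-variance rescue", {
  ## mean 0.99 > 0.95 triggers the filter without testing
  r <- slscanTestPair(c(1.0, 0.98), c(0.1, 0.2), seed = 1)
  expect_equal(r[c("t", "p", "filtered")],
               list(t = 0, p = 1, filtered = TRUE))

  ## pooled closed form: delta 0.5, s 0.1, n 3 per group, df 4
  r <- slscanTestPair(c(0.4, 0.5, 0.6), c(0.9, 1.0, 1.1), seed = 1)
  expect_equal(r$t, -6.123724, tolerance = 1e-3)
  expect_equal(r$p, 0.003602, tolerance = 1e-3)
  expect_false(r$filtered)

  ## all-zero groups: the injected noise keeps the statistic finite
  r <- slscanTestPair(c(0, 0, 0), c(0, 0, 0), seed = 1)
  expect_true(is.finite(r$t))
  expect_true(r$p >= 0 && r$p <= 1)

  ## determinism & seed sensitivity of the noise
  a <- slscanTestPair(c(0, 0, 0), c(0, 0, 0), seed = 42)
  b <- slscanTestPair(c(0, 0, 0), c(0, 0, 0), seed = 42)
  expect_identical(a, b)
})

test_that("pooled t matches stats::t.test on random inputs", {
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), mean = 0.3)
    mine <- metaboSL:::.pooledT(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("noise leaves well-separated groups' p-values unchanged", {
  set.seed(4)
  for (rep in 1:10) {
    x <- runif(5, 0, 0.4)
    y <- x + 1e-3 + runif(5, 0, 0.4)
    noised <- slscanTestPair(x, y, seed = rep)
    clean <- metaboSL:::.pooledT(x, y)
    expect_equal(noised$p, clean$p, tolerance = 1e-4)
    expect_equal(noised$t, clean$t, tolerance = 1e-4)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
  expect_error(bhAdjust(c(0.5, 1.7)), "0, 1")
})

test_that("the scan recovers a planted SL pair as its top hit", {
  ds <- generatePlantedSLDataset(list(seed = 7))
  tab <- scanFixtureDataset(ds, seed = 7)
  res <- scanResults(tab)
  expect_equal(nrow(res), 4)          # 1 driver x 4 universe genes
  best <- res[which.min(res$fdr), ]
  expect_equal(best$driver, ds$truth$driver)
  expect_equal(best$ko_gene, ds$truth$partner)
  expect_lte(best$fdr, 0.05)
  expect_lt(best$t, 0)                # KO more lethal in mutated lines
  ## the filter dominates pairs with near-1 mutated means
  filt <- res[res$filtered, ]
  expect_true(all(filt$p == 1))
  expect_true(all(res$fdr >= res$p - 1e-12))
})

test_that("scan output is deterministic for a fixed seed", {
  ds <- generatePlantedSLDataset(list(seed = 5))
  t1 <- scanFixtureDataset(ds, seed = 11)
  t2 <- scanFixtureDataset(ds, seed = 11)
  expect_identical(scanResults(t1), scanResults(t2))
  t3 <- scanFixtureDataset(ds, seed = 12)
  expect_false(identical(scanResults(t1)$p, scanResults(t3)$p))
})

test_that("permuted mutation labels kill the planted signal", {
  ds <- generatePlantedSLDataset(list(seed = 19))
  builds <- buildContextModels(ds$model, ds$expression, grid = ds$grid)
  ko <- buildKoScoreMatrix(lapply(builds, `[[`, "model"),
                           modelGenes(ds$model))
  mut <- mutationMatrixFromMAF(ds$maf,
                               cellLines = colnames(ds$expression),
                               genes = modelGenes(ds$model))
  falsePos <- vapply(1:20, function(k) {
    set.seed(k)
    perm <- mutationCalls(mut)
    colnames(perm) <- sample(colnames(perm))
    perm <- perm[, colnames(mutationCalls(mut))]
    pm <- new("MutationMatrix", calls = perm, provenance = list())
    sum(scanResults(slScan(ko, pm, seed = k))$significant)
  }, 0)
  expect_lte(mean(falsePos), 0.5)
})

test_that("small strata are skipped, not mistested", {
  scores <- matrix(runif(12), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("CL", 1:4)))
  calls <- matrix(FALSE, 3, 4,
                  dimnames = dimnames(scores))
  calls["g1", c(1, 2, 3)] <- TRUE    # only 1 wild line -> skip driver
  calls["g2", c(1, 2)] <- TRUE       # 2/2 split -> testable
  mm <- new("MutationMatrix", calls = calls, provenance = list())
  tab <- slScan(scores, mm, seed = 1)
  res <- scanResults(tab)
  expect_false("g1" %in% res$driver)
  expect_equal(sum(res$driver == "g2"), 3)
  expect_true(!is.null(scanMetadata(tab)$skipped))
})
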