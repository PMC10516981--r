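test_that("screen scan tests separated dependency scores", {
  dep <- rbind(
    gX = c(-1.2, -1.0, -1.1, 0.0, 0.1, -0.1),
    gY = rep(0.2, 6))
  colnames(dep) <- sprintf("CL%02d", 1:6)
  calls <- matrix(FALSE, 1, 6, dimnames = list("drv", colnames(dep)))
  calls["drv", 1:3] <- TRUE
  mm <- new("MutationMatrix", calls = calls, provenance = list())
  tab <- screenSlScan(dep, mm)
  res <- scanResults(tab)
  hit <- res[res$ko_gene == "gX", ]
  expect_lt(hit$p, 0.01)
  expect_true(hit$significant)
  expect_lt(hit$t, 0)
  ## identical groups: t = 0, p = 1 (no noise injection on screens)
  same <- res[res$ko_gene == "gY", ]
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("missing values drop pairwise and small strata are skipped", {
  dep <- rbind(gX = c(NA, -1.0, -1.1, 0.0, 0.1, NA),
               gZ = c(NA, NA, -1.0, 0.0, 0.1, 0.2))
  colnames(dep) <- sprintf("CL%02d", 1:6)
  calls <- matrix(FALSE, 1, 6, dimnames = list("drv", colnames(dep)))
  calls["drv", 1:3] <- TRUE
  mm <- new("MutationMatrix", calls = calls, provenance = list())
  tab <- screenSlScan(dep, mm)
  res <- scanResults(tab)
  expect_equal(res$ko_gene, "gX")            # gZ has 1 mutated obs left
  expect_equal(res$n_mut, 2L)
  expect_equal(scanMetadata(tab)$skippedPairs, 1L)
  ## driver with one mutated line is absent entirely
  calls2 <- calls; calls2["drv", ] <- c(TRUE, rep(FALSE, 5))
  mm2 <- new("MutationMatrix", calls = calls2, provenance = list())
  expect_equal(nrow(scanResults(screenSlScan(dep, mm2))), 0)
})

test_that("concordance counts are plain set arithmetic on shared pairs", {
  mkTab <- function(df, alpha = 0.05) {
    df$t <- 0; df$p <- df$fdr; df$mean_mut <- 0; df$mean_wt <- 0
    df$n_mut <- 2L; df$n_wt <- 2L; df$filtered <- FALSE
    df$significant <- df$fdr <= alpha
    new("SLResultTable", results = df, metadata = list(alpha = alpha))
  }
  method <- mkTab(data.frame(
    driver = c("a", "a", "a", "b", "b"),
    ko_gene = c("x", "y", "z", "x", "z"),
    fdr = c(0.01, 0.02, 0.8, 0.9, 0.7), stringsAsFactors = FALSE))
  screen <- mkTab(data.frame(
    driver = c("a", "a", "b", "b", "a"),
    ko_gene = c("y", "z", "z", "x", "x"),
    fdr = c(0.01, 0.9, 0.04, 0.6, 0.99), stringsAsFactors = FALSE))
  cc <- concordance(method, screen)
  expect_equal(cc@universe, 5L)       # all five pairs shared here
  expect_equal(cc@nMethod, 2L)
  expect_equal(cc@nScreen, 2L)
  expect_equal(cc@overlap, 1L)        # (a, y)
  ## identical tables: full overlap
  cc2 <- concordance(method, method)
  expect_equal(cc2@overlap, cc2@nMethod)
  ## invariants are enforced
  expect_error(ContingencyCounts(3, 2, 3, 10), "overlap")
  expect_error(ContingencyCounts(11, 2, 1, 10), "universe")
})

test_that("hypergeometric tail is exact, symmetric and monotone", {
  ## closed-form toy: P(X >= 3) = 11/42 for (4, 5, 3, 10)
  expect_equal(hypergeometricEnrichment(
    ContingencyCounts(4, 5, 3, 10))$p, 11 / 42, tolerance = 1e-12)
  ## overlap 0 is certain
  expect_equal(hypergeometricEnrichment(
    ContingencyCounts(4, 5, 0, 10))$p, 1)
  ## symmetry in the margins
  expect_equal(hypergeometricEnrichment(
    ContingencyCounts(7, 3, 2, 30))$p,
    hypergeometricEnrichment(ContingencyCounts(3, 7, 2, 30))$p,
    tolerance = 1e-12)
  ## monotone in the overlap
  ps <- vapply(0:5, function(k) hypergeometricEnrichment(
    ContingencyCounts(8, 5, k, 40))$p, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("hypergeometric tail matches brute-force pmf summation", {
  set.seed(14)
  for (rep in 1:40) {
    universe <- sample(20:500, 1)
    nScreen <- sample(1:(universe - 1), 1)
    nMethod <- sample(1:(universe - 1), 1)
    overlap <- sample(0:min(nMethod, nScreen), 1)
    p <- hypergeometricEnrichment(
      ContingencyCounts(nMethod, nScreen, overlap, universe))$p
    expect_equal(p, bruteHyperTail(nMethod, nScreen, overlap, universe),
                 tolerance = 1e-9)
  }
})

test_that("published screen-concordance counts reproduce their p-values", {
  ## printed (method, screen, overlap, universe) rows with 3-figure targets
  rows <- list(
    leukemia = list(c(6462, 2929, 140, 159030), 2.87e-02),
    lung = list(c(8281, 4407, 181, 249426), 2.44e-03),
    ovarian = list(c(3623, 1363, 78, 80352), 2.00e-02),
    gastric = list(c(2479, 613, 28, 55242), 4.89e-01),
    bile_duct = list(c(580, 170, 5, 15066), 7.88e-01),
    head_neck = list(c(665, 223, 7, 15066), 8.67e-01))
  for (nm in names(rows)) {
    k <- rows[[nm]][[1]]
    p <- hypergeometricEnrichment(
      ContingencyCounts(k[1], k[2], k[3], k[4]))$p
    expect_equal(p, rows[[nm]][[2]], tolerance = 5e-3, label = nm)
  }
})

test_that("the per-cancer report assembles rows in input order", {
  mk <- function(fdrs) {
    df <- data.frame(driver = "d", ko_gene = paste0("k", seq_along(fdrs)),
                     t = 0, p = fdrs, fdr = fdrs, mean_mut = 0,
                     mean_wt = 0, n_mut = 2L, n_wt = 2L, filtered = FALSE,
                     significant = fdrs <= 0.05, stringsAsFactors = FALSE)
    new("SLResultTable", results = df, metadata = list())
  }
  per <- list(
    one = list(method = mk(c(0.01, 0.5)), screen = mk(c(0.02, 0.6))),
    two = list(method = mk(c(0.5, 0.5)), screen = mk(c(0.5, 0.5))))
  rep <- concordanceReport(per)
  expect_equal(rep$cancer, c("one", "two"))
  expect_equal(rep$overlap, c(1L, 0L))
  expect_equal(rep$p[2], 1)
})
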