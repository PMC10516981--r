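toyP <- makeToyModel("parallel")

test_that("classification respects thresholds and the unmapped convention", {
  vec <- c(a = 7, b = 1, c = 3, d = NA)
  cls <- classifyReactions(vec, 2, 5)
  expect_equal(unname(cls), c("high", "low", "moderate", "moderate"))
  # boundary convention: >= UB high, <= LB low
  expect_equal(unname(classifyReactions(c(x = 5, y = 2), 2, 5)),
               c("high", "low"))
  expect_error(classifyReactions(vec, 5, 2))
})

test_that("extraction keeps the expressed route and silences the low one", {
  vec <- mapExpressionToReactions(toyP, c(g1 = 10, g2 = 1, g3 = 1, g4 = 1))
  cls <- classifyReactions(vec, 2, 5)
  ctx <- imatExtract(toyP, cls, core = c("BIO", "EX_A"), epsilon = 0.1)
  expect_setequal(reactionIds(ctx), c("EX_A", "R1", "BIO"))
  expect_equal(attr(ctx, "imatObjective"), 3)       # 1 high active + 2 low off
  expect_false("C" %in% metaboliteIds(ctx))         # orphan pruned
  expect_equal(solutionStatus(solveFBA(ctx)), "optimal")

  ## all high -> full model, extraction is the identity on the reaction set
  allHigh <- stats::setNames(rep("high", 5), reactionIds(toyP))
  full <- imatExtract(toyP, allHigh, core = reactionIds(toyP))
  expect_equal(reactionIds(full), reactionIds(toyP))

  ## biomass always present (core containment)
  expect_true("BIO" %in% reactionIds(ctx))
  expect_error(imatExtract(toyP, cls, core = "EX_A"), "biomass")
})

test_that("extraction MILP matches exhaustive indicator enumeration", {
  cases <- list(
    list(model = toyP, expr = c(g1 = 10, g2 = 1, g3 = 1, g4 = 1)),
    list(model = toyP, expr = c(g1 = 1, g2 = 10, g3 = 10, g4 = 1)),
    list(model = toyP, expr = c(g1 = 10, g2 = 10, g3 = 10, g4 = 10)),
    list(model = makeToyModel("branched"),
         expr = c(g1 = 10, g2 = 1, g3 = 1, g4 = 1, g5 = 10, g6 = 10,
                  g7 = 10, g8 = 1, g9 = 1)),
    list(model = makeToyModel("branched"),
         expr = c(g1 = 1, g2 = 10, g3 = 10, g4 = 10, g5 = 1, g6 = 1,
                  g7 = 10, g8 = 10, g9 = 10)))
  for (cs in cases) {
    vec <- mapExpressionToReactions(cs$model, cs$expr)
    for (thr in list(c(2, 5), c(0.5, 9))) {
      cls <- classifyReactions(vec, thr[1], thr[2])
      core <- reactionIds(cs$model)[
        objectiveCoefficients(cs$model) != 0 | isExchange(cs$model)]
      ctx <- imatExtract(cs$model, cls, core = core, epsilon = 0.1)
      expect_equal(attr(ctx, "imatObjective"),
                   imatEnumOracle(cs$model, cls, epsilon = 0.1),
                   label = paste(cs$model@id, paste(thr, collapse = "/")))
    }
  }
})

test_that("grid search returns the first growth-viable threshold pair", {
  prof <- c(g1 = 10, g2 = 1, g3 = 1, g4 = 1)
  ## first pair classifies every mapped reaction low -> silent network
  gs <- thresholdGridSearch(toyP, prof,
                            grid = data.frame(lb = c(10.5, 2),
                                              ub = c(11, 5)))
  expect_equal(gs$index, 2)
  expect_equal(gs$thresholds$lb, 2)
  expect_gt(gs$objective, 1e-6)
  expect_setequal(reactionIds(gs$model), c("EX_A", "R1", "BIO"))

  one <- thresholdGridSearch(toyP, prof, grid = data.frame(lb = 2, ub = 5))
  expect_equal(one$index, 1)

  expect_error(
    thresholdGridSearch(toyP, prof, grid = data.frame(lb = 10.5, ub = 11)),
    "no threshold pair")
})

test_that("grid-searched models always satisfy the growth postcondition", {
  set.seed(33)
  for (rep in 1:10) {
    prof <- stats::setNames(sample(c(1, 9), 4, replace = TRUE) +
                              stats::runif(4, -0.1, 0.1),
                            paste0("g", 1:4))
    res <- tryCatch(
      thresholdGridSearch(toyP, prof, grid = data.frame(lb = 2, ub = 5)),
      noViableThresholdsError = function(e) NULL)
    if (!is.null(res)) {
      rep <- verifyContextModel(res$model)
      expect_gt(rep$biomassValue, 0)
    }
  }
})

test_that("consistency report finds blocked reactions and growth", {
  repP <- verifyContextModel(toyP)
  expect_equal(repP$blocked, character(0))
  expect_equal(repP$biomassValue, 10)
  expect_true(repP$consistent)

  repB <- verifyContextModel(makeToyModel("branched"))
  expect_equal(repB$blocked, "DEAD")
  expect_false(repB$consistent)
  expect_equal(repB$biomassValue, 10)

  noObj <- makeToyModel("parallel")
  noObj@obj[] <- 0
  repN <- verifyContextModel(noObj)
  expect_false(repN$checks[["hasObjective"]])
  expect_false(repN$consistent)
})

test_that("functionality tasks open imports and demand the target", {
  tasks <- data.frame(id = c("makeB", "makeD2", "none"),
                      inputs = c("A", "A", ""),
                      target = c("B", "D2", "B"),
                      stringsAsFactors = FALSE)
  res <- runFunctionalityTasks(toyP, tasks)
  expect_equal(as.integer(res), 1L)
  passed <- attr(res, "passed")
  expect_true(passed[["makeB"]])
  expect_false(passed[["makeD2"]])   # metabolite absent -> fail, no error
  expect_false(passed[["none"]])     # B not producible without any input
  expect_equal(as.integer(runFunctionalityTasks(toyP, tasks[0, ])), 0L)
})

test_that("random-model benchmark is seeded and sized correctly", {
  b <- makeToyModel("branched")
  tasks <- data.frame(id = "makeE", inputs = "A", target = "E",
                      stringsAsFactors = FALSE)
  counts <- randomModelBenchmark(b, size = 6, tasks = tasks, n = 100,
                                 seed = 7)
  expect_length(counts, 100)
  expect_identical(counts,
                   randomModelBenchmark(b, size = 6, tasks = tasks,
                                        n = 100, seed = 7))
  expect_false(identical(counts,
                         randomModelBenchmark(b, size = 6, tasks = tasks,
                                              n = 100, seed = 8)))
  expect_error(randomModelBenchmark(b, size = 1, tasks = tasks),
               "size must lie")
})

test_that("construction success requires beating 99% of random models", {
  expect_true(constructionReport(5, rep(4, 100))$success)
  expect_true(constructionReport(5, c(rep(0:4, 20)))$success)
  # exceeding only 98 of 100 fails
  expect_false(constructionReport(3, c(rep(2, 98), 4, 4))$success)
  expect_false(constructionReport(3, rep(3, 100))$success)  # ties don't count
})
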