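#' @include model.R context.R slscan.R
NULL

#' Deterministic toy metabolic models
#'
#' Three fixed toy networks used throughout the documentation and tests:
#' \describe{
#'   \item{\code{"parallel"}}{5 reactions, genes g1-g4. Import
#'     \code{EX_A} (bounds [0, 10]) feeds two parallel routes to B: direct
#'     \code{R1} (A -> B, gene g1) and the two-step \code{R2a} (A -> C, g2),
#'     \code{R2b} (C -> B, "g3 or g4"); biomass \code{BIO} drains B. FBA
#'     optimum 10, forced by the import bound. g1 and g2 form the only
#'     synthetic-lethal pair.}
#'   \item{\code{"linear"}}{AND-gated linear chain: \code{EX_A} [0, 5],
#'     \code{R1} (A -> B, "gA and gB"), biomass drains B. FBA optimum 5;
#'     gA and gB are each single-lethal.}
#'   \item{\code{"branched"}}{10 reactions, genes g1-g9, two routes to the
#'     biomass precursor plus an auxiliary drain and one dead-end reaction
#'     \code{DEAD} (B -> X with no consumer of X), which is the model's
#'     single blocked reaction. FBA optimum 10.}
#' }
#'
#' @param name one of \code{"parallel"}, \code{"linear"},
#'   \code{"branched"}.
#' @return a \linkS4class{MetabolicModel}.
#' @examples
#' solveFBA(makeToyModel("linear"))
#' @export
makeToyModel <- function(name = c("parallel", "linear", "branched")) {
  name <- match.arg(name)
  switch(name,
    parallel = MetabolicModel("TOY-P", list(
      EX_A = list(metabolites = c(A = 1), lb = 0, ub = 10),
      R1   = list(metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
                  gpr = "g1"),
      R2a  = list(metabolites = c(A = -1, C = 1), lb = 0, ub = 1000,
                  gpr = "g2"),
      R2b  = list(metabolites = c(C = -1, B = 1), lb = 0, ub = 1000,
                  gpr = "g3 or g4"),
      BIO  = list(metabolites = c(B = -1), lb = 0, ub = 1000,
                  objective = 1))),
    linear = MetabolicModel("TOY-L", list(
      EX_A = list(metabolites = c(A = 1), lb = 0, ub = 5),
      R1   = list(metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
                  gpr = "gA and gB"),
      BIO  = list(metabolites = c(B = -1), lb = 0, ub = 1000,
                  objective = 1))),
    branched = MetabolicModel("TOY-B", list(
      EX_A   = list(metabolites = c(A = 1), lb = 0, ub = 10),
      R1     = list(metabolites = c(A = -1, B = 1), lb = 0, ub = 1000,
                    gpr = "g1"),
      R2a    = list(metabolites = c(A = -1, C = 1), lb = 0, ub = 1000,
                    gpr = "g2"),
      R2b    = list(metabolites = c(C = -1, B = 1), lb = 0, ub = 1000,
                    gpr = "g3 or g4"),
      R3     = list(metabolites = c(B = -1, D = 1), lb = 0, ub = 1000,
                    gpr = "g5"),
      R4     = list(metabolites = c(D = -1, E = 1), lb = 0, ub = 1000,
                    gpr = "g6 and g7"),
      R5     = list(metabolites = c(C = -1, E = 1), lb = 0, ub = 1000,
                    gpr = "g8"),
      SINK_D = list(metabolites = c(D = -1), lb = 0, ub = 1000),
      BIO    = list(metabolites = c(E = -1), lb = 0, ub = 1000,
                    objective = 1),
      DEAD   = list(metabolites = c(B = -1, X = 1), lb = 0, ub = 1000,
                    gpr = "g9"))))
}

.defaultScenario <- function(seed = 1L) {
  list(nCellLines = 20L, driver = "g2", partner = "g1",
       fractionMutated = 0.5, expressionHigh = 9, expressionLow = 1,
       seed = as.integer(seed))
}

#' Synthetic expression/mutation dataset with one planted SL pair
#'
#' Emulates the statistical structure the mutation-stratified scan assumes,
#' on the \code{"parallel"} toy network. In mutated cell lines the driver
#' gene carries a damaging MAF record and its backup route is silenced at
#' the expression level (driver expression = \code{expressionLow}), so
#' context extraction drops that route and the partner gene becomes
#' essential only there; wild-type lines express everything highly. A small
#' seeded uniform jitter (±0.1 on the log2 scale, too small to cross the
#' toy classification thresholds) is added to every expression value.
#'
#' @param scenario list with elements \code{nCellLines},
#'   \code{driver}, \code{partner}, \code{fractionMutated},
#'   \code{expressionHigh}, \code{expressionLow}, \code{seed}; defaults
#'   via \code{scenario = list()} are n = 20, driver g2, partner g1,
#'   fraction 0.5, high 9, low 1.
#' @return list with \code{expression} (gene x cell-line matrix),
#'   \code{maf} (MAF-like data.frame), \code{truth} (list naming the
#'   planted driver/partner and the mutated lines), \code{model}
#'   (the generic toy model) and \code{grid} (the absolute threshold
#'   pair, LB 2 / UB 5, that separates the scenario's two expression
#'   levels; the jitter cannot cross it).
#' @examples
#' ds <- generatePlantedSLDataset(list(seed = 7))
#' ds$truth$driver
#' @export
generatePlantedSLDataset <- function(scenario = list()) {
  sc <- utils::modifyList(.defaultScenario(), scenario)
  stopifnot(sc$driver != sc$partner,
            sc$fractionMutated > 0, sc$fractionMutated < 1)
  model <- makeToyModel("parallel")
  genes <- modelGenes(model)
  n <- as.integer(sc$nCellLines)
  lines <- sprintf("CL%02d", seq_len(n))
  nMut <- max(1L, round(sc$fractionMutated * n))
  .withSeed(.stableHash("planted", seed = sc$seed), {
    mutLines <- sort(sample(lines, nMut))
    expr <- matrix(sc$expressionHigh, nrow = length(genes), ncol = n,
                   dimnames = list(genes, lines))
    expr[sc$driver, mutLines] <- sc$expressionLow
    expr <- expr + matrix(stats::runif(length(expr), -0.1, 0.1),
                          nrow = nrow(expr))
    maf <- data.frame(
      Hugo_Symbol = c(rep(sc$driver, nMut), genes[1]),
      Tumor_Sample_Barcode = c(mutLines,
                               setdiff(lines, mutLines)[1]),
      Variant_Classification = c(rep("Nonsense_Mutation", nMut), "Silent"),
      isDeleterious = c(rep(TRUE, nMut), FALSE),
      stringsAsFactors = FALSE)
  })
  list(expression = expr, maf = maf,
       truth = list(driver = sc$driver, partner = sc$partner,
                    mutatedLines = mutLines, scenario = sc),
       model = model, grid = data.frame(lb = 2, ub = 5))
}

#' Null dataset: random mutation labels, label-independent expression
#'
#' Mutation calls are Bernoulli(0.5) per gene and cell line, independent of
#' expression. Expression keeps every cell line's context model viable (the
#' trunk route gene g1 is always high) while the backup-route gene g2 is
#' lowly expressed in a random half of the lines, independently of the
#' labels — so knockout scores genuinely vary across lines but carry no SL
#' signal.
#'
#' @param nCellLines number of cell lines (>= 8).
#' @param seed integer seed.
#' @return list with \code{expression}, \code{maf}, \code{model} and
#'   \code{grid} (as in \code{\link{generatePlantedSLDataset}}).
#' @export
generateNullDataset <- function(nCellLines = 20L, seed = 1L) {
  stopifnot(nCellLines >= 8)
  model <- makeToyModel("parallel")
  genes <- modelGenes(model)
  n <- as.integer(nCellLines)
  lines <- sprintf("CL%02d", seq_len(n))
  .withSeed(.stableHash("null", seed = seed), {
    expr <- matrix(9, nrow = length(genes), ncol = n,
                   dimnames = list(genes, lines))
    lowG2 <- stats::runif(n) < 0.5
    expr["g2", lowG2] <- 1
    expr <- expr + matrix(stats::runif(length(expr), -0.1, 0.1),
                          nrow = nrow(expr))
    calls <- matrix(stats::runif(length(genes) * n) < 0.5,
                    nrow = length(genes),
                    dimnames = list(genes, lines))
    rows <- which(calls, arr.ind = TRUE)
    maf <- data.frame(
      Hugo_Symbol = genes[rows[, 1]],
      Tumor_Sample_Barcode = lines[rows[, 2]],
      Variant_Classification = "Nonsense_Mutation",
      isDeleterious = TRUE,
      stringsAsFactors = FALSE)
    maf <- maf[order(maf$Hugo_Symbol, maf$Tumor_Sample_Barcode), ,
               drop = FALSE]
    rownames(maf) <- NULL
  })
  list(expression = expr, maf = maf, model = model,
       grid = data.frame(lb = 2, ub = 5))
}

#' Run the planted / null pipeline on a fixture dataset
#'
#' Convenience composition used by the calibration studies: context models
#' for every cell line (at the dataset's threshold grid), KO-score matrix
#' over the toy gene universe, mutation matrix from the MAF table, and the
#' mutation-stratified scan.
#'
#' @param dataset a list from \code{\link{generatePlantedSLDataset}} or
#'   \code{\link{generateNullDataset}}.
#' @param alpha,seed passed to \code{\link{slScan}}.
#' @return an \linkS4class{SLResultTable}.
#' @export
scanFixtureDataset <- function(dataset, alpha = 0.05, seed = 1L) {
  builds <- buildContextModels(dataset$model, dataset$expression,
                               grid = dataset$grid)
  universe <- modelGenes(dataset$model)
  ko <- buildKoScoreMatrix(lapply(builds, `[[`, "model"), universe)
  mut <- mutationMatrixFromMAF(dataset$maf,
                               cellLines = colnames(dataset$expression),
                               genes = universe, source = "fixture")
  slScan(ko, mut, alpha = alpha, seed = seed)
}
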