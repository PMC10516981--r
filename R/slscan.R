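#' @include context.R
NULL

#' KO-gene list of a context model
#'
#' Composition of FBA, L1-minimal flux at the FBA optimum, and GPR mapping
#' of the flux-carrying reactions: the genes whose knockouts are worth
#' simulating for this cell line.
#'
#' @param contextModel a growth-viable \linkS4class{MetabolicModel}.
#' @param tol zero-flux threshold for the support (default 1e-6).
#' @return sorted character vector of gene ids (a subset of the model's
#'   genes).
#' @export
deriveKoGeneList <- function(contextModel, tol = 1e-6) {
  stopifnot(is(contextModel, "MetabolicModel"))
  fba <- solveFBA(contextModel)
  if (fba@status != "optimal" || fba@objective <= 0)
    stop("context model must have positive FBA biomass", call. = FALSE)
  l1 <- solveL1Min(contextModel, fba@objective)
  fluxSupportGenes(contextModel, l1, tol = tol)
}

#' Construct a KOScoreMatrix
#'
#' @param scores genes x cell-lines numeric matrix in [0, 1] with
#'   dimnames.
#' @param metadata optional list of provenance metadata.
#' @return a \linkS4class{KOScoreMatrix}.
#' @export
KOScoreMatrix <- function(scores, metadata = list()) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  se <- SummarizedExperiment(assays = list(ratio = scores))
  S4Vectors::metadata(se) <- metadata
  new("KOScoreMatrix", se)
}

#' @rdname accessors
#' @export
setMethod("koScores", "KOScoreMatrix", function(object)
  assay(object, "ratio"))

#' Simulate the KO-score matrix over cell lines
#'
#' For each cell line, single-gene-deletion growth ratios are computed over
#' the intersection of its KO-gene list with the gene universe; every other
#' universe gene is filled with 1 (its knockout is assumed to have no
#' simulated growth effect).
#'
#' @param models named list of growth-viable context
#'   \linkS4class{MetabolicModel}s (names = cell lines).
#' @param universe gene id universe (rows of the result), typically the
#'   generic model's gene set.
#' @param koLists optional named list of precomputed KO-gene lists; by
#'   default \code{\link{deriveKoGeneList}} is applied per model.
#' @return a \linkS4class{KOScoreMatrix} of dimension
#'   \code{length(universe)} x \code{length(models)}.
#' @export
buildKoScoreMatrix <- function(models, universe, koLists = NULL) {
  stopifnot(is.list(models), !is.null(names(models)),
            is.character(universe), !anyDuplicated(universe))
  scores <- matrix(1, nrow = length(universe), ncol = length(models),
                   dimnames = list(universe, names(models)))
  for (cl in names(models)) {
    model <- models[[cl]]
    ko <- if (is.null(koLists)) {
      tryCatch(deriveKoGeneList(model), error = function(e)
        stop(sprintf("cell line '%s': %s", cl, conditionMessage(e)),
             call. = FALSE))
    } else koLists[[cl]]
    ko <- intersect(ko, universe)
    if (length(ko)) {
      r <- singleGeneDeletionRatios(model, ko)
      scores[ko, cl] <- pmin(1, pmax(0, r))
    }
  }
  KOScoreMatrix(scores, metadata = list(universe = universe))
}

#' Identify driver genes from a mutation matrix
#'
#' Driver genes are the (metabolic) genes harbouring at least one damaging
#' mutation in at least \code{minMutatedLines} cell lines.
#'
#' @param mutations a \linkS4class{MutationMatrix}.
#' @param minMutatedLines minimum number of mutated cell lines (default 2).
#' @return sorted character vector of driver gene ids.
#' @export
identifyDriverGenes <- function(mutations, minMutatedLines = 2L) {
  stopifnot(is(mutations, "MutationMatrix"), minMutatedLines >= 1)
  calls <- mutations@calls
  sort(rownames(calls)[rowSums(calls) >= minMutatedLines])
}

## Pooled-variance two-sample t (Student, two-sided). Returned t is signed
## meanX - meanY. Degenerate zero-variance groups: equal means give
## (t = 0, p = 1), separated means (t = +/-Inf, p = 0). Cross-checked
## against stats::t.test(var.equal = TRUE) in the test suite.
.pooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (d == 0) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  tstat <- d / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

#' Mutation-stratified test of one (driver, KO gene) pair
#'
#' If the mutated-group mean exceeds \code{filterMean} the pair is filtered
#' without testing (the knockout is essentially inert where the driver is
#' mutated) and assigned p = 1. Otherwise independent uniform noise on
#' [\code{noiseLo}, \code{noiseHi}] is added to every observation of both
#' groups — the simulated ratios are piecewise constant and would otherwise
#' produce zero-variance groups — and a two-sided pooled-variance t-test
#' compares the groups. The sign of t is mean(mutated) - mean(wild).
#'
#' @param scoresMut,scoresWt KO scores of the mutated / wild-type groups
#'   (each of length >= 2).
#' @param filterMean mutated-group mean filter threshold (default 0.95).
#' @param noiseLo,noiseHi uniform noise bounds (defaults 1e-12, 1e-11).
#' @param seed integer seed for the noise draws.
#' @return list with \code{t}, \code{p}, \code{filtered}, \code{meanMut},
#'   \code{meanWt}.
#' @export
slscanTestPair <- function(scoresMut, scoresWt, filterMean = 0.95,
                           noiseLo = 1e-12, noiseHi = 1e-11, seed = 1L) {
  stopifnot(length(scoresMut) >= 2, length(scoresWt) >= 2)
  meanMut <- mean(scoresMut); meanWt <- mean(scoresWt)
  if (meanMut > filterMean) {
    return(list(t = 0, p = 1, filtered = TRUE,
                meanMut = meanMut, meanWt = meanWt))
  }
  res <- .withSeed(seed, {
    nm <- length(scoresMut); nw <- length(scoresWt)
    noise <- stats::runif(nm + nw, noiseLo, noiseHi)
    .pooledT(scoresMut + noise[seq_len(nm)],
             scoresWt + noise[nm + seq_len(nw)])
  })
  list(t = res$t, p = res$p, filtered = FALSE,
       meanMut = meanMut, meanWt = meanWt)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving with
#' the input.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Mutation-stratified synthetic-lethality scan
#'
#' For every (driver, KO gene) pair — drivers from
#' \code{\link{identifyDriverGenes}} restricted to the score-matrix gene
#' universe — the cell lines are stratified by the driver's mutation
#' status and the KO scores compared with \code{\link{slscanTestPair}}.
#' Benjamini-Hochberg adjustment is applied across all tested pairs of the
#' scan (filtered pairs contribute p = 1 to the family); pairs with fewer
#' than 2 cell lines in either stratum are skipped and excluded from the
#' family. Per-pair noise seeds derive from (\code{seed}, driver, KO gene),
#' so results do not depend on iteration order.
#'
#' @param scores a \linkS4class{KOScoreMatrix} (or plain genes x lines
#'   matrix).
#' @param mutations a \linkS4class{MutationMatrix} sharing the cell lines.
#' @param alpha FDR significance threshold (default 0.05).
#' @param seed integer master seed for the pair noise.
#' @param filterMean,noiseLo,noiseHi passed to
#'   \code{\link{slscanTestPair}}.
#' @param minMutatedLines driver-gene definition (default 2).
#' @param cancer optional cancer-type label stored in the metadata.
#' @return an \linkS4class{SLResultTable}.
#' @export
slScan <- function(scores, mutations, alpha = 0.05, seed = 1L,
                   filterMean = 0.95, noiseLo = 1e-12, noiseHi = 1e-11,
                   minMutatedLines = 2L, cancer = NA_character_) {
  mat <- if (is(scores, "KOScoreMatrix")) koScores(scores) else scores
  stopifnot(is.matrix(mat), is(mutations, "MutationMatrix"))
  calls <- mutations@calls
  lines <- intersect(colnames(mat), colnames(calls))
  if (!length(lines))
    stop("score and mutation matrices share no cell lines", call. = FALSE)
  mat <- mat[, lines, drop = FALSE]
  calls <- calls[, lines, drop = FALSE]
  drivers <- identifyDriverGenes(
    new("MutationMatrix", calls = calls, provenance = mutations@provenance),
    minMutatedLines)
  drivers <- intersect(drivers, rownames(mat))
  skipped <- list()
  rows <- list()
  for (drv in drivers) {
    isMut <- calls[drv, ]
    nMut <- sum(isMut); nWt <- sum(!isMut)
    if (nMut < 2 || nWt < 2) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(driver = drv, ko_gene = NA_character_,
                   reason = sprintf("stratum too small (%d mutated, %d wild)",
                                    nMut, nWt))
      next
    }
    for (ko in rownames(mat)) {
      r <- slscanTestPair(mat[ko, isMut], mat[ko, !isMut],
                          filterMean = filterMean, noiseLo = noiseLo,
                          noiseHi = noiseHi,
                          seed = .stableHash(drv, ko, seed = seed))
      rows[[length(rows) + 1L]] <- data.frame(
        driver = drv, ko_gene = ko, t = r$t, p = r$p, fdr = NA_real_,
        mean_mut = r$meanMut, mean_wt = r$meanWt,
        n_mut = nMut, n_wt = nWt, filtered = r$filtered,
        significant = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no testable driver genes; returning an empty table")
    res <- data.frame(driver = character(0), ko_gene = character(0),
                      t = numeric(0), p = numeric(0), fdr = numeric(0),
                      mean_mut = numeric(0), mean_wt = numeric(0),
                      n_mut = integer(0), n_wt = integer(0),
                      filtered = logical(0), significant = logical(0))
  } else {
    res <- do.call(rbind, rows)
    res$fdr <- bhAdjust(res$p)
    res$significant <- res$fdr <= alpha
  }
  new("SLResultTable", results = res,
      metadata = list(alpha = alpha, seed = seed, cancer = cancer,
                      filterMean = filterMean,
                      noise = c(noiseLo, noiseHi),
                      minMutatedLines = minMutatedLines,
                      skipped = if (length(skipped))
                        do.call(rbind, skipped) else NULL))
}

#' @rdname accessors
#' @export
setMethod("scanResults", "SLResultTable", function(object) object@results)

#' @rdname accessors
#' @export
setMethod("scanMetadata", "SLResultTable", function(object) object@metadata)

#' @rdname accessors
#' @param alpha optional FDR threshold overriding the scan's own.
#' @export
setMethod("significantPairs", "SLResultTable", function(object, alpha = NULL) {
  r <- object@results
  if (is.null(alpha)) r[r$significant, c("driver", "ko_gene")]
  else r[r$fdr <= alpha, c("driver", "ko_gene")]
})

setMethod("show", "SLResultTable", function(object) {
  r <- object@results
  cat(sprintf("SLResultTable: %d (driver, KO gene) pairs, %d significant%s\n",
              nrow(r), sum(r$significant),
              if (!is.na(object@metadata$cancer))
                sprintf(" [%s]", object@metadata$cancer) else ""))
  if (nrow(r)) {
    top <- utils::head(r[order(r$fdr), ], 5)
    print(top, row.names = FALSE)
  }
})
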