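#' @include slscan.R
NULL

#' Mutation-stratified scan of an experimental dependency matrix
#'
#' Runs the same driver-gene stratified two-sample t-test scheme as
#' \code{\link{slScan}} on a measured dependency matrix (CRISPR gene
#' effect, shRNA ATARiS score or drug-response log-fold-change). No
#' mean-based filter and no noise injection: experimental screens carry
#' natural variance. Missing values are dropped pairwise; a pair is tested
#' only when both strata retain at least 2 observations.
#'
#' @param dep numeric entities x cell-lines matrix (genes or compounds;
#'   lower = stronger killing). May contain \code{NA}.
#' @param mutations a \linkS4class{MutationMatrix}.
#' @param alpha FDR significance threshold (default 0.05).
#' @param minMutatedLines driver definition (default 2).
#' @param compoundTargets optional data.frame (compound_id, gene_id) used
#'   to annotate compound entities with their target gene.
#' @param cancer optional label.
#' @return an \linkS4class{SLResultTable} (entities appear in the
#'   \code{ko_gene} column; a \code{target_gene} column is appended when
#'   \code{compoundTargets} is given).
#' @export
screenSlScan <- function(dep, mutations, alpha = 0.05,
                         minMutatedLines = 2L, compoundTargets = NULL,
                         cancer = NA_character_) {
  stopifnot(is.matrix(dep), is(mutations, "MutationMatrix"))
  calls <- mutations@calls
  lines <- intersect(colnames(dep), colnames(calls))
  if (length(lines) < 4)
    stop("need at least 4 shared cell lines", call. = FALSE)
  dep <- dep[, lines, drop = FALSE]
  calls <- calls[, lines, drop = FALSE]
  drivers <- sort(rownames(calls)[rowSums(calls) >= minMutatedLines])
  rows <- list(); skipped <- 0L
  for (drv in drivers) {
    isMut <- calls[drv, ]
    for (ent in rownames(dep)) {
      x <- dep[ent, isMut]; y <- dep[ent, !isMut]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2) { skipped <- skipped + 1L; next }
      r <- .pooledT(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        driver = drv, ko_gene = ent, t = r$t, p = r$p, fdr = NA_real_,
        mean_mut = mean(x), mean_wt = mean(y),
        n_mut = length(x), n_wt = length(y), filtered = FALSE,
        significant = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
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
  if (!is.null(compoundTargets) && nrow(res)) {
    res$target_gene <- compoundTargets$gene_id[
      match(res$ko_gene, compoundTargets$compound_id)]
  }
  new("SLResultTable", results = res,
      metadata = list(alpha = alpha, cancer = cancer,
                      kind = attr(dep, "kind"),
                      skippedPairs = skipped))
}

#' Construct ContingencyCounts
#'
#' @param nMethod,nScreen,overlap,universe nonnegative integer counts; the
#'   overlap may not exceed either margin and margins may not exceed the
#'   universe.
#' @return a \linkS4class{ContingencyCounts}.
#' @export
ContingencyCounts <- function(nMethod, nScreen, overlap, universe) {
  new("ContingencyCounts", nMethod = as.integer(nMethod),
      nScreen = as.integer(nScreen), overlap = as.integer(overlap),
      universe = as.integer(universe))
}

setMethod("show", "ContingencyCounts", function(object) {
  cat(sprintf(paste0("ContingencyCounts: method %d, screen %d, ",
                     "overlap %d, universe %d\n"),
              object@nMethod, object@nScreen, object@overlap,
              object@universe))
})

#' Concordance counts between a method scan and a screen scan
#'
#' The universe is the set of (driver, entity) pairs tested in both
#' tables; margins count pairs significant (FDR at or below \code{alpha})
#' within the universe, and the overlap counts pairs significant in both.
#'
#' @param methodTable,screenTable \linkS4class{SLResultTable}s.
#' @param alpha significance threshold applied to both tables.
#' @return a \linkS4class{ContingencyCounts}.
#' @export
concordance <- function(methodTable, screenTable, alpha = 0.05) {
  stopifnot(is(methodTable, "SLResultTable"),
            is(screenTable, "SLResultTable"))
  key <- function(tab) paste(tab@results$driver, tab@results$ko_gene,
                             sep = "\r")
  kM <- key(methodTable); kS <- key(screenTable)
  universe <- intersect(kM, kS)
  if (!length(universe))
    stop("no (driver, KO gene) pairs tested in both tables", call. = FALSE)
  sigM <- kM[methodTable@results$fdr <= alpha]
  sigS <- kS[screenTable@results$fdr <= alpha]
  sigM <- intersect(sigM, universe)
  sigS <- intersect(sigS, universe)
  ContingencyCounts(length(sigM), length(sigS),
                    length(intersect(sigM, sigS)), length(universe))
}

#' Hypergeometric enrichment of screen hits among method hits
#'
#' Upper-tail probability \eqn{P(X \ge overlap)} for \eqn{X}
#' hypergeometric with population \code{universe}, \code{nScreen} successes
#' and \code{nMethod} draws, computed exactly in log space. Symmetric in
#' the two margins.
#'
#' @param counts a \linkS4class{ContingencyCounts}.
#' @return list with \code{counts} and \code{p}.
#' @examples
#' hypergeometricEnrichment(ContingencyCounts(4, 5, 3, 10))$p  # 11/42
#' @export
hypergeometricEnrichment <- function(counts) {
  stopifnot(is(counts, "ContingencyCounts"))
  p <- stats::phyper(counts@overlap - 1, counts@nScreen,
                     counts@universe - counts@nScreen, counts@nMethod,
                     lower.tail = FALSE)
  list(counts = counts, p = p)
}

#' Per-cancer concordance and enrichment report
#'
#' @param perCancer named list; each element a list with components
#'   \code{method} and \code{screen} (two \linkS4class{SLResultTable}s).
#' @param alpha significance threshold.
#' @return data.frame with one row per cancer: enrichment p, margins,
#'   overlap and universe (input order preserved).
#' @export
concordanceReport <- function(perCancer, alpha = 0.05) {
  rows <- lapply(names(perCancer), function(cn) {
    cc <- concordance(perCancer[[cn]]$method, perCancer[[cn]]$screen,
                      alpha = alpha)
    data.frame(cancer = cn, p = hypergeometricEnrichment(cc)$p,
               n_method = cc@nMethod, n_screen = cc@nScreen,
               overlap = cc@overlap, universe = cc@universe,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
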