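#' @import methods
#' @importFrom Matrix sparseMatrix Matrix t colSums rowSums
NULL

setOldClass("data.frame")

#' GprExpression: a gene-protein-reaction boolean rule
#'
#' Boolean expression tree whose leaves are gene identifiers and whose
#' internal nodes are AND (enzyme complex) / OR (isozymes). The empty rule is
#' a distinguished "always active" value. The textual source form is
#' retained so rules survive round-tripping unmodified.
#'
#' @slot tree parsed expression: nested lists with elements \code{op}
#'   (\code{"gene"}, \code{"and"}, \code{"or"}, \code{"true"}) plus
#'   \code{gene} or \code{args}.
#' @slot text the source rule string.
#' @exportClass GprExpression
setClass("GprExpression",
  representation(tree = "list", text = "character"))

setValidity("GprExpression", function(object) {
  msgs <- character(0)
  check <- function(nd) {
    if (!is.list(nd) || is.null(nd$op)) return("malformed node")
    switch(nd$op,
      gene = if (!nzchar(nd$gene)) "empty gene identifier leaf" else NULL,
      true = NULL,
      and = ,
      or  = unlist(lapply(nd$args, check)),
      sprintf("unknown node op '%s'", nd$op))
  }
  msgs <- c(msgs, check(object@tree))
  if (length(msgs)) msgs else TRUE
})

#' MetabolicModel: a stoichiometric network
#'
#' Genome-scale (or toy) metabolic network: stoichiometric matrix, flux
#' bounds, objective coefficients and one GPR rule per reaction. Gene
#' identifiers are opaque strings (dotted entrez.transcript ids survive
#' unmodified). The gene set of the model is derived as the union of GPR
#' leaves.
#'
#' @slot id model identifier.
#' @slot mets ordered metabolite identifiers (rows of \code{S}).
#' @slot rxns ordered reaction identifiers (columns of \code{S}).
#' @slot S sparse stoichiometric matrix, metabolites x reactions.
#' @slot lb,ub numeric flux bounds per reaction.
#' @slot obj objective coefficients per reaction (the biomass reaction
#'   carries a nonzero entry).
#' @slot gpr GPR rule strings per reaction ("" = no rule, always active).
#' @slot gprTree cached parsed \linkS4class{GprExpression} trees.
#' @slot metData optional per-metabolite annotation (name, compartment,
#'   formula); zero-row data.frame when absent.
#' @exportClass MetabolicModel
setClass("MetabolicModel",
  representation(id = "character", mets = "character", rxns = "character",
                 S = "Matrix", lb = "numeric", ub = "numeric",
                 obj = "numeric", gpr = "character", gprTree = "list",
                 metData = "data.frame"))

setValidity("MetabolicModel", function(object) {
  msgs <- character(0)
  nr <- length(object@rxns); nm <- length(object@mets)
  if (anyDuplicated(object@rxns)) msgs <- c(msgs, "duplicate reaction ids")
  if (anyDuplicated(object@mets)) msgs <- c(msgs, "duplicate metabolite ids")
  if (!identical(dim(object@S), c(nm, nr)))
    msgs <- c(msgs, "S must be metabolites x reactions")
  for (nmslot in c("lb", "ub", "obj", "gpr"))
    if (length(slot(object, nmslot)) != nr)
      msgs <- c(msgs, sprintf("'%s' must have one entry per reaction", nmslot))
  if (length(object@lb) == nr && length(object@ub) == nr &&
      any(object@lb > object@ub))
    msgs <- c(msgs, "lower bounds must not exceed upper bounds")
  if (length(object@obj) == nr && any(!is.finite(object@obj)))
    msgs <- c(msgs, "objective coefficients must be finite")
  if (length(object@gprTree) != nr)
    msgs <- c(msgs, "gprTree cache must have one entry per reaction")
  if (length(msgs)) msgs else TRUE
})

#' FluxSolution: solver status, flux vector and objective value
#'
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @slot fluxes named numeric flux vector (empty unless optimal).
#' @slot objective achieved objective value (\code{NA} unless optimal).
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(status = "character", fluxes = "numeric",
                 objective = "numeric"))

setValidity("FluxSolution", function(object) {
  ok <- c("optimal", "infeasible", "unbounded")
  if (!(length(object@status) == 1L && object@status %in% ok))
    return(sprintf("status must be one of %s", paste(ok, collapse = ", ")))
  if (object@status == "optimal" && is.null(names(object@fluxes)))
    return("optimal solutions must carry named fluxes")
  TRUE
})

#' KOScoreMatrix: simulated knockout growth ratios
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"ratio"} assay of
#' genes x cell lines knockout/wild-type growth ratios in [0, 1]. Genes of
#' the generic-model universe absent from a cell line's KO-gene list carry
#' the default value 1 (knockout has no simulated effect).
#'
#' @exportClass KOScoreMatrix
#' @import SummarizedExperiment
setClass("KOScoreMatrix", contains = "SummarizedExperiment")

setValidity("KOScoreMatrix", function(object) {
  if (!"ratio" %in% assayNames(object))
    return("KOScoreMatrix needs a 'ratio' assay")
  a <- assay(object, "ratio")
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1))
    return("knockout ratios must lie in [0, 1]")
  TRUE
})

#' MutationMatrix: damaging-mutation calls per gene and cell line
#'
#' @slot calls logical genes x cell lines matrix; \code{TRUE} means the gene
#'   harbours at least one damaging mutation in that cell line.
#' @slot provenance list recording the source and the
#'   damaging-classification rule used.
#' @exportClass MutationMatrix
setClass("MutationMatrix",
  representation(calls = "matrix", provenance = "list"))

setValidity("MutationMatrix", function(object) {
  if (!is.logical(object@calls)) return("calls must be a logical matrix")
  if (is.null(rownames(object@calls)) || is.null(colnames(object@calls)))
    return("calls must have gene rownames and cell-line colnames")
  TRUE
})

#' SLResultTable: one mutation-stratified test per (driver, KO gene) pair
#'
#' @slot results data.frame with columns driver, ko_gene, t, p, fdr,
#'   mean_mut, mean_wt, n_mut, n_wt, filtered, significant.
#' @slot metadata scan metadata: alpha, seed, cancer label, skipped pairs.
#' @exportClass SLResultTable
setClass("SLResultTable",
  representation(results = "data.frame", metadata = "list"))

setValidity("SLResultTable", function(object) {
  need <- c("driver", "ko_gene", "t", "p", "fdr", "mean_mut", "mean_wt",
            "n_mut", "n_wt", "filtered", "significant")
  miss <- setdiff(need, colnames(object@results))
  if (length(miss))
    return(sprintf("missing result columns: %s", paste(miss, collapse = ", ")))
  r <- object@results
  if (anyDuplicated(paste(r$driver, r$ko_gene, sep = "\r")))
    return("duplicate (driver, ko_gene) pairs")
  fin <- is.finite(r$p) & is.finite(r$fdr)
  if (any(r$fdr[fin] < r$p[fin] - 1e-12))
    return("fdr must be >= p")
  if (any(r$filtered & r$p != 1))
    return("filtered pairs must carry p = 1")
  TRUE
})

#' ContingencyCounts: overlap counts feeding the hypergeometric test
#'
#' @slot nMethod number of significant pairs called by the method.
#' @slot nScreen number of significant pairs called by the screen.
#' @slot overlap pairs significant in both.
#' @slot universe total pairs tested in common.
#' @exportClass ContingencyCounts
setClass("ContingencyCounts",
  representation(nMethod = "integer", nScreen = "integer",
                 overlap = "integer", universe = "integer"))

setValidity("ContingencyCounts", function(object) {
  v <- c(object@nMethod, object@nScreen, object@overlap, object@universe)
  if (any(is.na(v)) || any(v < 0)) return("counts must be nonnegative")
  if (object@overlap > min(object@nMethod, object@nScreen))
    return("overlap cannot exceed either margin")
  if (max(object@nMethod, object@nScreen) > object@universe)
    return("margins cannot exceed the universe")
  TRUE
})
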