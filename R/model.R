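#' @include AllClasses.R AllGenerics.R gpr.R
NULL

#' Construct a MetabolicModel
#'
#' Builds a \linkS4class{MetabolicModel} from a list of reactions. Each
#' reaction is a list with elements \code{metabolites} (named numeric,
#' metabolite id -> signed stoichiometric coefficient; negative = consumed),
#' \code{lb}, \code{ub}, optional \code{gpr} (rule string, default "") and
#' optional \code{objective} (coefficient in the FBA objective, default 0).
#' Exchange/demand reactions are the one-sided ones (a single metabolite).
#'
#' @param id model identifier.
#' @param reactions named list of reaction descriptions (names are reaction
#'   ids).
#' @param metData optional data.frame of per-metabolite annotation with a
#'   \code{met} column (plus e.g. name/compartment/formula).
#' @return a validated \linkS4class{MetabolicModel}.
#' @examples
#' m <- MetabolicModel("mini", list(
#'   EX_A = list(metabolites = c(A = 1), lb = 0, ub = 10),
#'   BIO  = list(metabolites = c(A = -1), lb = 0, ub = 1000, objective = 1)))
#' solveFBA(m)
#' @export
MetabolicModel <- function(id, reactions, metData = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.list(reactions),
            !is.null(names(reactions)), all(nzchar(names(reactions))))
  rxns <- names(reactions)
  mets <- unique(unlist(lapply(reactions, function(r) names(r$metabolites))))
  if (is.null(mets)) mets <- character(0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- numeric(length(rxns)); ub <- numeric(length(rxns))
  obj <- numeric(length(rxns)); gpr <- character(length(rxns))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    st <- r$metabolites
    if (length(st)) {
      ii <- c(ii, match(names(st), mets)); jj <- c(jj, rep(j, length(st)))
      xx <- c(xx, as.numeric(st))
    }
    lb[j] <- r$lb; ub[j] <- r$ub
    obj[j] <- if (is.null(r$objective)) 0 else r$objective
    gpr[j] <- if (is.null(r$gpr)) "" else r$gpr
  }
  S <- sparseMatrix(i = ii, j = jj, x = xx,
                    dims = c(length(mets), length(rxns)),
                    dimnames = list(mets, rxns))
  if (is.null(metData))
    metData <- data.frame(met = character(0), stringsAsFactors = FALSE)
  new("MetabolicModel", id = id, mets = mets, rxns = rxns,
      S = S, lb = lb, ub = ub, obj = obj, gpr = gpr,
      gprTree = lapply(gpr, function(g) parseGpr(g)@tree), metData = metData)
}

#' @rdname accessors
#' @export
setMethod("reactionIds", "MetabolicModel", function(object) object@rxns)

#' @rdname accessors
#' @export
setMethod("metaboliteIds", "MetabolicModel", function(object) object@mets)

#' @rdname accessors
#' @export
setMethod("modelGenes", "MetabolicModel", function(object)
  sort(unique(as.character(unlist(lapply(object@gprTree, .treeGenes))))))

#' @rdname accessors
#' @export
setMethod("lowerBounds", "MetabolicModel", function(object)
  stats::setNames(object@lb, object@rxns))

#' @rdname accessors
#' @export
setMethod("upperBounds", "MetabolicModel", function(object)
  stats::setNames(object@ub, object@rxns))

#' @rdname accessors
#' @export
setMethod("objectiveCoefficients", "MetabolicModel", function(object)
  stats::setNames(object@obj, object@rxns))

#' @rdname accessors
#' @export
setMethod("gprRules", "MetabolicModel", function(object)
  stats::setNames(object@gpr, object@rxns))

#' @rdname accessors
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel", function(object) object@S)

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel '%s': %d metabolites, %d reactions, %d genes\n",
              object@id, length(object@mets), length(object@rxns),
              length(modelGenes(object))))
  nob <- sum(object@obj != 0)
  cat(sprintf("  objective: %s\n",
              if (nob) paste(object@rxns[object@obj != 0], collapse = ", ")
              else "<none>"))
})

#' Exchange reactions of a model
#'
#' A reaction is treated as an exchange/demand when it involves a single
#' metabolite (one-sided stoichiometry across the system boundary).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @return named logical vector over reactions.
#' @export
isExchange <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  nz <- Matrix::colSums(model@S != 0)
  stats::setNames(nz <= 1, model@rxns)
}

#' Subset a model to a set of reactions
#'
#' Keeps the given reactions and, optionally, prunes metabolites no longer
#' referenced by any kept reaction.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param rxns reaction ids to keep.
#' @param pruneMetabolites drop orphan metabolites (default \code{TRUE}).
#' @param id id for the subset model (default: parent id).
#' @return a \linkS4class{MetabolicModel}.
#' @export
subsetReactions <- function(model, rxns, pruneMetabolites = TRUE,
                            id = model@id) {
  stopifnot(is(model, "MetabolicModel"))
  miss <- setdiff(rxns, model@rxns)
  if (length(miss))
    stop("unknown reaction ids: ", paste(miss, collapse = ", "))
  j <- match(rxns, model@rxns)
  S <- model@S[, j, drop = FALSE]
  mets <- model@mets
  if (pruneMetabolites && nrow(S)) {
    keep <- Matrix::rowSums(S != 0) > 0
    S <- S[keep, , drop = FALSE]
    mets <- mets[keep]
  }
  metData <- model@metData
  if (nrow(metData) && "met" %in% colnames(metData))
    metData <- metData[metData$met %in% mets, , drop = FALSE]
  new("MetabolicModel", id = id, mets = mets, rxns = model@rxns[j],
      S = S, lb = model@lb[j], ub = model@ub[j], obj = model@obj[j],
      gpr = model@gpr[j], gprTree = model@gprTree[j], metData = metData)
}

## internal: set bounds of selected reactions (returns a new model)
.setBounds <- function(model, rxns, lb, ub) {
  j <- match(rxns, model@rxns)
  stopifnot(!anyNA(j))
  model@lb[j] <- lb
  model@ub[j] <- ub
  model
}
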