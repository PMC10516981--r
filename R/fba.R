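#' @include AllClasses.R AllGenerics.R model.R lp-solver.R
NULL

#' @rdname accessors
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname accessors
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

#' @rdname accessors
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objective)

setMethod("show", "FluxSolution", function(object) {
  cat(sprintf("FluxSolution: status %s", object@status))
  if (object@status == "optimal")
    cat(sprintf(", objective %.6g, %d reactions (%d carrying flux > 1e-6)",
                object@objective, length(object@fluxes),
                sum(abs(object@fluxes) > 1e-6)))
  cat("\n")
})

.fluxSolution <- function(status, fluxes = numeric(0), objective = NA_real_) {
  new("FluxSolution", status = status, fluxes = fluxes, objective = objective)
}

#' Flux balance analysis
#'
#' Maximises the model objective \eqn{c^T x} subject to steady state
#' \eqn{Sx = 0} and the flux bounds \eqn{l \le x \le u}. Deterministic:
#' repeated calls return identical flux vectors.
#'
#' @param model a \linkS4class{MetabolicModel} with at least one nonzero
#'   objective coefficient.
#' @return a \linkS4class{FluxSolution}.
#' @examples
#' solveFBA(makeToyModel("parallel"))
#' @export
solveFBA <- function(model) {
  stopifnot(is(model, "MetabolicModel"))
  if (all(model@obj == 0))
    stop("model has no objective reaction (all objective coefficients zero)",
         call. = FALSE)
  r <- .lpSolve(model@obj, Aeq = as.matrix(model@S),
                beq = rep(0, length(model@mets)),
                lb = model@lb, ub = model@ub, maximize = TRUE)
  if (r$status != "optimal") return(.fluxSolution(r$status))
  .fluxSolution("optimal", stats::setNames(r$x, model@rxns), r$objval)
}

#' L1-minimal (parsimonious) flux distribution at a pinned objective
#'
#' Minimises the taxicab norm \eqn{\sum_i |v_i|} subject to \eqn{Sv = 0},
#' the model bounds, and the objective pinned to \code{targetObjective}
#' (within \code{fixTolerance}; exact equality is numerically brittle).
#' Standard split-variable LP reformulation \eqn{v = v^+ - v^-}.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param targetObjective objective value to pin (normally the
#'   \code{\link{solveFBA}} optimum).
#' @param fixTolerance half-width of the pinning band; default
#'   \code{1e-6 * max(1, |targetObjective|)}.
#' @return a \linkS4class{FluxSolution}; its \code{objective} is the
#'   achieved \eqn{c^T v} (within tolerance of the target), and the sum of
#'   absolute fluxes is minimal among all flux vectors meeting the pin.
#' @export
solveL1Min <- function(model, targetObjective,
                       fixTolerance = 1e-6 * max(1, abs(targetObjective))) {
  stopifnot(is(model, "MetabolicModel"), is.numeric(targetObjective),
            length(targetObjective) == 1L, is.finite(targetObjective))
  n <- length(model@rxns)
  m <- length(model@mets)
  S <- as.matrix(model@S)
  ## variables: v+ (n), v- (n); v = v+ - v-
  Aeq <- cbind(S, -S)
  beq <- rep(0, m)
  ## model bounds on v and the +/- objective pin, as <= rows
  D <- cbind(diag(n), -diag(n))
  cc <- model@obj
  Aub <- rbind(D, -D, c(cc, -cc), -c(cc, -cc))
  bub <- c(model@ub, -model@lb,
           targetObjective + fixTolerance,
           -(targetObjective - fixTolerance))
  r <- .lpSolve(rep(1, 2 * n), Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
                lb = rep(0, 2 * n), ub = rep(Inf, 2 * n))
  if (r$status != "optimal") {
    ## distinguish an unattainable pin from a structurally infeasible model
    base <- .lpSolve(rep(0, n), Aeq = S, beq = rep(0, m),
                     lb = model@lb, ub = model@ub)
    if (base$status == "optimal")
      stop(sprintf(paste0("objective pin %.6g not attainable within ",
                          "tolerance %.3g (model itself is feasible)"),
                   targetObjective, fixTolerance), call. = FALSE)
    return(.fluxSolution(r$status))
  }
  v <- r$x[seq_len(n)] - r$x[n + seq_len(n)]
  v[abs(v) < .LP_TOL] <- 0
  .fluxSolution("optimal", stats::setNames(v, model@rxns), sum(cc * v))
}

#' Genes behind the flux-carrying reactions of a solution
#'
#' Collects reactions with \code{|flux| > tol} and returns the union of the
#' gene leaves of their GPR rules; reactions without a rule contribute
#' nothing. Applied to the L1-minimal solution this yields the KO-gene list.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param solution an optimal \linkS4class{FluxSolution} for \code{model}.
#' @param tol zero-flux threshold (default \code{1e-6}).
#' @return character vector of gene ids (sorted).
#' @export
fluxSupportGenes <- function(model, solution, tol = 1e-6) {
  stopifnot(is(model, "MetabolicModel"), is(solution, "FluxSolution"))
  if (solution@status != "optimal")
    stop("flux support requires an optimal solution", call. = FALSE)
  v <- solution@fluxes[model@rxns]
  act <- which(abs(v) > tol)
  sort(unique(as.character(unlist(lapply(model@gprTree[act], .treeGenes)))))
}

#' Apply a gene knockout to a model
#'
#' Every reaction whose GPR rule evaluates to inactive under the knockout
#' has both flux bounds closed to zero; other reactions are unchanged. The
#' input model is not modified (reaction set and dimensions are stable
#' across simulations). Unknown gene ids are inert.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param genes character vector of gene ids to knock out.
#' @return a new \linkS4class{MetabolicModel}.
#' @export
applyGeneKnockout <- function(model, genes) {
  stopifnot(is(model, "MetabolicModel"), is.character(genes))
  dead <- vapply(model@gprTree, function(tr) !.treeEval(tr, genes), NA)
  model@lb[dead] <- 0
  model@ub[dead] <- 0
  model
}

#' Single-gene-deletion growth ratios
#'
#' For each gene, the FBA objective of the knockout model divided by the
#' wild-type objective. Negative solver noise is clipped to 0; a knockout
#' that renders the model infeasible scores 0; genes absent from every GPR
#' score 1.
#'
#' @param model a growth-viable \linkS4class{MetabolicModel} (wild-type
#'   objective > 0).
#' @param genes gene ids to delete one at a time (default: all model
#'   genes).
#' @return named numeric vector of ratios in [0, 1].
#' @export
singleGeneDeletionRatios <- function(model, genes = modelGenes(model)) {
  stopifnot(is(model, "MetabolicModel"))
  wt <- solveFBA(model)
  if (wt@status != "optimal" || wt@objective <= 0)
    stop("model is not growth-viable (wild-type objective must be > 0)",
         call. = FALSE)
  ratios <- vapply(genes, function(g) {
    ko <- applyGeneKnockout(model, g)
    if (identical(ko@lb, model@lb) && identical(ko@ub, model@ub))
      return(1)  # gene touches no reaction
    s <- solveFBA(ko)
    if (s@status != "optimal") return(0)
    min(1, max(0, s@objective) / wt@objective)
  }, 0)
  stats::setNames(ratios, genes)
}

#' Exhaustive double-deletion synthetic-lethal baseline
#'
#' Naive all-pairs search: a pair \{gi, gj\} is synthetic lethal when both
#' single-deletion ratios exceed \code{cutoff} but the double-deletion ratio
#' drops to \code{cutoff} or below. Pairs containing a single-lethal gene
#' are excluded.
#'
#' @param model a growth-viable \linkS4class{MetabolicModel}.
#' @param cutoff growth-ratio lethality cutoff in (0, 1); default 0.01.
#' @param genes genes to consider (default: all model genes).
#' @return data.frame with columns \code{gene1}, \code{gene2} (unordered
#'   pairs, gene1 < gene2) and \code{ratio} (the double-deletion ratio).
#' @export
exhaustiveDoubleDeletionSL <- function(model, cutoff = 0.01,
                                       genes = modelGenes(model)) {
  stopifnot(is(model, "MetabolicModel"), cutoff > 0, cutoff < 1)
  wt <- solveFBA(model)
  if (wt@status != "optimal" || wt@objective <= 0)
    stop("model is not growth-viable (wild-type objective must be > 0)",
         call. = FALSE)
  singles <- singleGeneDeletionRatios(model, genes)
  viable <- names(singles)[singles > cutoff]
  out <- list()
  if (length(viable) >= 2) {
    cmb <- utils::combn(sort(viable), 2)
    for (k in seq_len(ncol(cmb))) {
      pair <- cmb[, k]
      ko <- applyGeneKnockout(model, pair)
      s <- solveFBA(ko)
      ratio <- if (s@status != "optimal") 0 else
        min(1, max(0, s@objective) / wt@objective)
      if (ratio <= cutoff)
        out[[length(out) + 1L]] <- data.frame(gene1 = pair[1],
                                              gene2 = pair[2],
                                              ratio = ratio,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      ratio = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
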