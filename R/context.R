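#' @include fba.R
NULL

#' Map an expression profile onto reactions
#'
#' Aggregates gene expression over each reaction's GPR rule with the COBRA
#' convention AND -> minimum (complex limited by its scarcest subunit),
#' OR -> maximum (isozymes add alternatives). Genes absent from the profile
#' are ignored within a rule; reactions with no rule (or none of whose genes
#' are profiled) receive \code{NA}, the "unmapped" sentinel.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param profile named numeric vector of gene expression (log2 TPM
#'   semantics), names = gene ids.
#' @return named numeric reaction expression vector (one entry per
#'   reaction; \code{NA} = unmapped).
#' @export
mapExpressionToReactions <- function(model, profile) {
  stopifnot(is(model, "MetabolicModel"), is.numeric(profile),
            !is.null(names(profile)))
  if (any(!is.finite(profile)))
    stop("expression values must be finite", call. = FALSE)
  vals <- vapply(model@gprTree, .treeValue, 0, values = profile)
  stats::setNames(vals, model@rxns)
}

#' Classify reactions into high / low / moderate expression states
#'
#' Values at or above the upper threshold are "high", at or below the lower
#' threshold "low", everything else — including unmapped reactions —
#' "moderate" (never rewarded nor penalised by the extraction).
#'
#' @param vec reaction expression vector from
#'   \code{\link{mapExpressionToReactions}}.
#' @param lb,ub lower/upper expression thresholds, \code{lb <= ub}.
#' @return named character vector with values \code{"high"}, \code{"low"},
#'   \code{"moderate"}.
#' @export
classifyReactions <- function(vec, lb, ub) {
  stopifnot(is.numeric(vec), length(lb) == 1L, length(ub) == 1L, lb <= ub)
  cls <- rep("moderate", length(vec))
  cls[!is.na(vec) & vec >= ub] <- "high"
  cls[!is.na(vec) & vec <= lb] <- "low"
  stats::setNames(cls, names(vec))
}

#' iMAT-style context-specific model extraction
#'
#' Solves the integrative MILP that maximises the number of
#' highly-expressed reactions carrying flux of at least \code{epsilon}
#' (in either direction) plus the number of lowly-expressed reactions
#' carrying zero flux, subject to steady state and the model bounds.
#' Binary indicators enter through big-M constraints; the search is a
#' deterministic zero-gap branch-and-bound. The returned sub-model keeps
#' the core reactions plus every reaction carrying nonzero flux
#' (\code{|v| > fluxTol}) in the MILP optimum; orphan metabolites are
#' pruned. By construction the restricted optimal flux vector remains
#' feasible in the sub-model.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param classes reaction classification from
#'   \code{\link{classifyReactions}} (one entry per reaction).
#' @param core reaction ids that must be retained; must include the
#'   objective (biomass) reaction.
#' @param epsilon activation flux threshold (default 0.1 flux units).
#' @param fluxTol zero-flux threshold for membership in the extracted
#'   model (default 1e-6).
#' @return a \linkS4class{MetabolicModel} (the context-specific sub-model)
#'   with attribute \code{"imatObjective"} (the achieved MILP score).
#' @export
imatExtract <- function(model, classes, core, epsilon = 0.1,
                        fluxTol = 1e-6) {
  stopifnot(is(model, "MetabolicModel"),
            length(classes) == length(model@rxns))
  bioRxns <- model@rxns[model@obj != 0]
  if (!all(bioRxns %in% core))
    stop("core must include the objective (biomass) reaction(s)",
         call. = FALSE)
  miss <- setdiff(core, model@rxns)
  if (length(miss))
    stop("core reactions absent from model: ", paste(miss, collapse = ", "),
         call. = FALSE)
  mil <- .imatMilp(model, classes, epsilon)
  sol <- .milpSolve(mil$obj, Aeq = mil$Aeq, beq = mil$beq,
                    Aub = mil$Aub, bub = mil$bub,
                    lb = mil$lb, ub = mil$ub, binary = mil$binary)
  if (sol$status != "optimal")
    stop(structure(class = c("imatExtractionError", "error", "condition"),
                   list(message = "iMAT MILP infeasible: no context model",
                        call = sys.call())))
  v <- sol$x[seq_along(model@rxns)]
  keep <- model@rxns[abs(v) > fluxTol]
  keep <- union(core, keep)
  keep <- model@rxns[model@rxns %in% keep]          # preserve model order
  out <- subsetReactions(model, keep,
                         id = paste0(model@id, "_context"))
  attr(out, "imatObjective") <- sol$objval
  out
}

## Build the iMAT MILP: variables [v (n), binaries...]; maximize sum of
## activation/silencing indicators.
.imatMilp <- function(model, classes, epsilon) {
  n <- length(model@rxns)
  S <- as.matrix(model@S)
  lb <- model@lb; ub <- model@ub
  hi <- which(classes == "high")
  lo <- which(classes == "low")
  nv <- n
  cols <- list()      # per binary: list(rxn, dir)
  for (i in hi) {
    cols[[length(cols) + 1L]] <- list(rxn = i, dir = "fwd")
    if (lb[i] < -epsilon / 2) cols[[length(cols) + 1L]] <-
        list(rxn = i, dir = "rev")
  }
  for (i in lo) cols[[length(cols) + 1L]] <- list(rxn = i, dir = "zero")
  nb <- length(cols)
  tot <- nv + nb
  Aeq <- cbind(S, matrix(0, nrow(S), nb))
  beq <- rep(0, nrow(S))
  Aub <- NULL; bub <- NULL
  addRow <- function(row, rhs) {
    Aub <<- rbind(Aub, row); bub <<- c(bub, rhs)
  }
  fwdOf <- rep(NA_integer_, n); revOf <- rep(NA_integer_, n)
  for (k in seq_len(nb)) {
    b <- cols[[k]]
    i <- b$rxn
    row <- numeric(tot)
    if (b$dir == "fwd") {
      ## y = 1 => v_i >= epsilon:  -v_i + (epsilon - lb_i) y <= -lb_i
      row[i] <- -1; row[nv + k] <- epsilon - lb[i]
      addRow(row, -lb[i])
      fwdOf[i] <- k
    } else if (b$dir == "rev") {
      ## y = 1 => v_i <= -epsilon:  v_i + (epsilon + ub_i) y <= ub_i
      row[i] <- 1; row[nv + k] <- epsilon + ub[i]
      addRow(row, ub[i])
      revOf[i] <- k
    } else {
      ## z = 1 => v_i = 0
      row[i] <- 1; row[nv + k] <- ub[i]
      addRow(row, ub[i])
      row2 <- numeric(tot)
      row2[i] <- -1; row2[nv + k] <- -lb[i]
      addRow(row2, -lb[i])
    }
  }
  ## forward/reverse activation of the same reaction is exclusive
  both <- which(!is.na(fwdOf) & !is.na(revOf))
  for (i in both) {
    row <- numeric(tot)
    row[nv + fwdOf[i]] <- 1; row[nv + revOf[i]] <- 1
    addRow(row, 1)
  }
  list(obj = c(numeric(nv), rep(1, nb)),
       Aeq = Aeq, beq = beq, Aub = Aub, bub = bub,
       lb = c(lb, rep(0, nb)), ub = c(ub, rep(1, nb)),
       binary = nv + seq_len(nb))
}

#' Default threshold grid from expression quantiles
#'
#' Quantile pairs (LB, UB) evaluated in the fixed order (q25, q75),
#' (q25, q90), (q10, q75), (q10, q90), (q50, q75): "first suitable" in
#' \code{\link{thresholdGridSearch}} is defined by this order.
#'
#' @param profile named numeric expression vector.
#' @return data.frame with columns \code{lb}, \code{ub} (threshold values).
#' @export
defaultThresholdGrid <- function(profile) {
  q <- stats::quantile(profile, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE)
  data.frame(lb = c(q[2], q[2], q[1], q[1], q[3]),
             ub = c(q[4], q[5], q[4], q[5], q[4]))
}

#' Grid search for viable expression thresholds
#'
#' Iterates threshold pairs in order; for each, classifies reactions,
#' extracts a context model and runs FBA. Returns the first pair whose
#' extracted model grows (objective above \code{objectiveZeroTol}),
#' together with that model.
#'
#' @param model the generic \linkS4class{MetabolicModel}.
#' @param profile named numeric expression vector for one cell line (or an
#'   averaged profile for a cancer type).
#' @param grid data.frame with columns \code{lb}, \code{ub}; default
#'   \code{\link{defaultThresholdGrid}(profile)}.
#' @param core core reaction set passed to \code{\link{imatExtract}};
#'   default: objective reaction(s) plus all exchange reactions.
#' @param epsilon iMAT activation threshold.
#' @param objectiveZeroTol growth counts as nonzero above this (default
#'   1e-6).
#' @param cache optional environment used to memoise extractions keyed on
#'   the classification vector (profiles sharing a classification share the
#'   extraction).
#' @return list with \code{thresholds} (row of \code{grid}), \code{model}
#'   (context model), \code{objective} (its FBA optimum) and \code{index}
#'   (grid row used).
#' @export
thresholdGridSearch <- function(model, profile, grid = NULL,
                                core = NULL, epsilon = 0.1,
                                objectiveZeroTol = 1e-6, cache = NULL) {
  stopifnot(is(model, "MetabolicModel"))
  if (is.null(grid)) grid <- defaultThresholdGrid(profile)
  stopifnot(nrow(grid) >= 1, all(c("lb", "ub") %in% colnames(grid)))
  if (is.null(core))
    core <- model@rxns[model@obj != 0 | isExchange(model)]
  vec <- mapExpressionToReactions(model, profile)
  for (i in seq_len(nrow(grid))) {
    cls <- classifyReactions(vec, grid$lb[i], grid$ub[i])
    key <- paste(c(format(epsilon), cls, core), collapse = "|")
    ctx <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]]
    else {
      c0 <- tryCatch(imatExtract(model, cls, core, epsilon),
                     imatExtractionError = function(e) NULL)
      if (!is.null(cache)) cache[[key]] <- if (is.null(c0)) list(NULL) else c0
      if (is.null(c0)) list(NULL) else c0
    }
    if (is.list(ctx) && !is(ctx, "MetabolicModel")) next  # memoised failure
    fba <- solveFBA(ctx)
    if (fba@status == "optimal" && fba@objective > objectiveZeroTol) {
      return(list(thresholds = grid[i, , drop = FALSE], model = ctx,
                  objective = fba@objective, index = i))
    }
  }
  stop(structure(class = c("noViableThresholdsError", "error", "condition"),
                 list(message = paste0("no threshold pair in the grid ",
                                       "yields a growing context model"),
                      call = sys.call())))
}

#' Structural and flux-consistency report for a model
#'
#' Reports blocked reactions (zero flux in every feasible steady-state
#' solution, detected by per-reaction flux maximisation/minimisation), the
#' biomass FBA value, and structural field checks. The model is
#' "consistent" iff it has no blocked reactions and grows.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tol zero-flux tolerance for blocked-reaction detection.
#' @return list with \code{blocked} (character), \code{biomassValue},
#'   \code{checks} (named logical), \code{consistent} (logical).
#' @export
verifyContextModel <- function(model, tol = 1e-6) {
  stopifnot(is(model, "MetabolicModel"))
  checks <- c(
    hasObjective = any(model@obj != 0),
    boundsOrdered = all(model@lb <= model@ub),
    uniqueReactionIds = !anyDuplicated(model@rxns),
    metabolitesReferenced = all(Matrix::rowSums(model@S != 0) > 0))
  biomass <- NA_real_
  if (checks[["hasObjective"]]) {
    fba <- solveFBA(model)
    if (fba@status == "optimal") biomass <- fba@objective
  }
  S <- as.matrix(model@S)
  m <- length(model@mets)
  blocked <- character(0)
  for (j in seq_along(model@rxns)) {
    e <- numeric(length(model@rxns)); e[j] <- 1
    hi <- .lpSolve(e, Aeq = S, beq = rep(0, m), lb = model@lb,
                   ub = model@ub, maximize = TRUE)
    lo <- .lpSolve(e, Aeq = S, beq = rep(0, m), lb = model@lb,
                   ub = model@ub, maximize = FALSE)
    mx <- if (hi$status == "optimal") hi$objval else 0
    mn <- if (lo$status == "optimal") lo$objval else 0
    if (abs(mx) < tol && abs(mn) < tol)
      blocked <- c(blocked, model@rxns[j])
  }
  consistent <- length(blocked) == 0L && all(checks) &&
    !is.na(biomass) && biomass > 0
  list(blocked = blocked, biomassValue = biomass, checks = checks,
       consistent = consistent)
}

#' Run metabolic functionality tasks against a model
#'
#' Each task specifies importable input metabolites and a target metabolite
#' that must be producible. All exchange reactions are first closed; then an
#' import is opened for each task input present in the model, a demand for
#' the target is added, and the demand is maximised. A task passes when the
#' demand reaches at least \code{epsilonTask}; a task whose target (or
#' whose machinery) is absent fails without raising an error.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param tasks data.frame with columns \code{id}, \code{inputs}
#'   (semicolon-separated metabolite ids) and \code{target}.
#' @param epsilonTask minimum demand flux to pass (default 1e-4).
#' @return integer: number of passed tasks, with attribute
#'   \code{"passed"} (logical vector named by task id).
#' @export
runFunctionalityTasks <- function(model, tasks, epsilonTask = 1e-4) {
  stopifnot(is(model, "MetabolicModel"), is.data.frame(tasks),
            all(c("id", "inputs", "target") %in% colnames(tasks)))
  if (!nrow(tasks)) {
    res <- logical(0)
    out <- 0L; attr(out, "passed") <- res
    return(out)
  }
  ex <- isExchange(model)
  closed <- model
  closed@lb[ex] <- 0
  closed@ub[ex] <- 0
  passed <- vapply(seq_len(nrow(tasks)), function(k) {
    target <- tasks$target[k]
    if (!(target %in% model@mets)) return(FALSE)
    inputs <- strsplit(tasks$inputs[k], ";", fixed = TRUE)[[1]]
    inputs <- intersect(trimws(inputs), model@mets)
    m2 <- closed
    extra <- list()
    for (met in inputs)
      extra[[paste0("TASKIN_", met)]] <-
        list(metabolites = stats::setNames(1, met), lb = 0, ub = 1000)
    extra[[paste0("TASKDM_", target)]] <-
      list(metabolites = stats::setNames(-1, target), lb = 0, ub = 1000)
    m2 <- .appendReactions(m2, extra)
    obj <- numeric(length(m2@rxns))
    obj[length(obj)] <- 1
    m2@obj <- obj
    fba <- solveFBA(m2)
    fba@status == "optimal" && fba@objective >= epsilonTask
  }, NA)
  names(passed) <- tasks$id
  out <- sum(passed)
  attr(out, "passed") <- passed
  out
}

## append reactions (list in MetabolicModel() format) to a model
.appendReactions <- function(model, reactions) {
  newMets <- setdiff(unique(unlist(lapply(reactions,
                                          function(r) names(r$metabolites)))),
                     model@mets)
  mets <- c(model@mets, newMets)
  S <- as.matrix(model@S)
  if (length(newMets))
    S <- rbind(S, matrix(0, length(newMets), ncol(S)))
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    col <- numeric(length(mets))
    col[match(names(r$metabolites), mets)] <- as.numeric(r$metabolites)
    S <- cbind(S, col)
  }
  rxns <- c(model@rxns, names(reactions))
  lb <- c(model@lb, vapply(reactions, function(r) r$lb, 0))
  ub <- c(model@ub, vapply(reactions, function(r) r$ub, 0))
  obj <- c(model@obj, vapply(reactions, function(r)
    if (is.null(r$objective)) 0 else r$objective, 0))
  gpr <- c(model@gpr, vapply(reactions, function(r)
    if (is.null(r$gpr)) "" else r$gpr, ""))
  trees <- c(model@gprTree, lapply(reactions, function(r)
    parseGpr(if (is.null(r$gpr)) "" else r$gpr)@tree))
  dimnames(S) <- list(mets, rxns)
  new("MetabolicModel", id = model@id, mets = mets, rxns = rxns,
      S = Matrix(S, sparse = TRUE), lb = lb, ub = ub, obj = obj,
      gpr = gpr, gprTree = unname(trees), metData = model@metData)
}

#' Functionality benchmark against random sub-models
#'
#' Draws \code{n} seeded uniform random reaction subsets of the generic
#' model at the stated size — always retaining all exchange reactions and
#' the biomass reaction, without which essentially every random model fails
#' trivially — and counts the functionality tasks each passes.
#'
#' @param generic the generic \linkS4class{MetabolicModel}.
#' @param size total reaction count of each random model (at least the
#'   number of always-retained reactions, at most the generic reaction
#'   count).
#' @param tasks task table (see \code{\link{runFunctionalityTasks}}).
#' @param n number of random models (default 100).
#' @param seed integer seed; same seed, same pass-count list.
#' @return integer vector of length \code{n} of passed-task counts.
#' @export
randomModelBenchmark <- function(generic, size, tasks, n = 100L,
                                 seed = 1L) {
  stopifnot(is(generic, "MetabolicModel"), n >= 1)
  keep <- generic@rxns[generic@obj != 0 | isExchange(generic)]
  pool <- setdiff(generic@rxns, keep)
  extra <- size - length(keep)
  if (extra < 0 || size > length(generic@rxns))
    stop("size must lie between the retained-reaction count and the ",
         "generic reaction count", call. = FALSE)
  .withSeed(.stableHash("random-model-benchmark", seed = seed), {
    vapply(seq_len(n), function(k) {
      sub <- c(keep, sample(pool, extra))
      sm <- subsetReactions(generic, generic@rxns[generic@rxns %in% sub])
      as.integer(runFunctionalityTasks(sm, tasks))
    }, 0L)
  })
}

#' Assemble a model-construction report
#'
#' Success requires the constructed model to pass more functionality tasks
#' than at least 99% of the random models.
#'
#' @param passedTasks tasks passed by the constructed model.
#' @param randomPassCounts vector of random-model pass counts from
#'   \code{\link{randomModelBenchmark}}.
#' @param blocked blocked reactions (from
#'   \code{\link{verifyContextModel}}).
#' @param biomassValue the model's FBA optimum.
#' @return list with fields \code{passedTasks}, \code{randomPassCounts},
#'   \code{success}, \code{blocked}, \code{biomassValue}.
#' @export
constructionReport <- function(passedTasks, randomPassCounts,
                               blocked = character(0),
                               biomassValue = NA_real_) {
  stopifnot(length(randomPassCounts) >= 1)
  success <- mean(passedTasks > randomPassCounts) >= 0.99
  list(passedTasks = as.integer(passedTasks),
       randomPassCounts = as.integer(randomPassCounts),
       success = success, blocked = blocked,
       biomassValue = biomassValue)
}

#' Build context models for every cell line of an expression matrix
#'
#' Runs the threshold grid search per cell line. Extractions are memoised
#' on the reaction classification, so cell lines whose profiles classify
#' identically share one MILP solve.
#'
#' @param model the generic \linkS4class{MetabolicModel}.
#' @param expression gene x cell-line numeric matrix (log2 TPM semantics).
#' @param grid optional fixed threshold grid; default: per-line quantile
#'   grid (\code{\link{defaultThresholdGrid}}).
#' @param core,epsilon passed to \code{\link{thresholdGridSearch}}.
#' @return named list of per-cell-line results as returned by
#'   \code{\link{thresholdGridSearch}}; lines for which no thresholds are
#'   viable raise an error naming the line.
#' @export
buildContextModels <- function(model, expression, grid = NULL,
                               core = NULL, epsilon = 0.1) {
  stopifnot(is(model, "MetabolicModel"), is.matrix(expression),
            !is.null(rownames(expression)), !is.null(colnames(expression)))
  cache <- new.env(parent = emptyenv())
  out <- vector("list", ncol(expression))
  names(out) <- colnames(expression)
  for (cl in colnames(expression)) {
    profile <- expression[, cl]
    out[[cl]] <- tryCatch(
      thresholdGridSearch(model, profile, grid = grid, core = core,
                          epsilon = epsilon, cache = cache),
      noViableThresholdsError = function(e)
        stop(sprintf("cell line '%s': %s", cl, conditionMessage(e)),
             call. = FALSE))
  }
  out
}
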