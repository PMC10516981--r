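# Independent oracles used to cross-check the package's solvers and tests'
# random-instance generators. Everything here is deliberately brute-force
# and shares no code with the implementation paths it checks.

## Dense-LP oracle: maximise cc'x s.t. S x = 0, lb <= x <= ub (finite
## bounds) by enumerating candidate vertices: every subset of n - rank(S)
## variables fixed at a bound, remaining square system solved exactly.
vertexLPOracle <- function(S, cc, lb, ub) {
  n <- ncol(S)
  qrS <- qr(t(S))               # rank via qr of transpose (rows of S)
  rk <- qr(S)$rank
  ## reduce to independent rows (redundant homogeneous rows are removable)
  if (rk < nrow(S)) S <- S[qr(t(S))$pivot[seq_len(rk)], , drop = FALSE]
  m <- nrow(S)
  nFree <- n - m
  best <- -Inf
  feasibleSeen <- FALSE
  consider <- function(x) {
    if (all(x >= lb - 1e-8) && all(x <= ub + 1e-8) &&
        max(abs(S %*% x)) < 1e-7) {
      feasibleSeen <<- TRUE
      v <- sum(cc * x)
      if (v > best) best <<- v
    }
  }
  if (nFree <= 0) {
    ## fully determined (up to null space rank): only x = 0 candidate
    consider(numeric(n))
  } else {
    combs <- utils::combn(n, nFree)
    for (ci in seq_len(ncol(combs))) {
      Fi <- combs[, ci]
      Bi <- setdiff(seq_len(n), Fi)
      AB <- S[, Bi, drop = FALSE]
      if (qr(AB)$rank < length(Bi)) next
      grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(Fi)))
      for (g in seq_len(nrow(grid))) {
        xF <- ifelse(unlist(grid[g, ]), ub[Fi], lb[Fi])
        xB <- tryCatch(qr.solve(AB, -S[, Fi, drop = FALSE] %*% xF),
                       error = function(e) NULL)
        if (is.null(xB)) next
        x <- numeric(n)
        x[Fi] <- xF
        x[Bi] <- as.numeric(xB)
        consider(x)
      }
    }
  }
  list(feasible = feasibleSeen, objval = best)
}

## Random small consistent network as a MetabolicModel: n reactions over m
## metabolites, integer stoichiometry, finite bounds containing 0 (so the
## zero flux vector is always feasible and the LP is bounded).
randomNetwork <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      k <- sample(1:min(3, m), 1)
      rowsel <- sample(m, k)
      S[rowsel, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (all(rowSums(S != 0) > 0)) break
  }
  lb <- ifelse(stats::runif(n) < 0.5, 0, -round(stats::runif(n, 1, 5), 1))
  ub <- round(stats::runif(n, 1, 10), 1)
  obj <- numeric(n)
  obj[sample(n, max(1, n %/% 3))] <- sample(c(1, 2), max(1, n %/% 3),
                                            replace = TRUE)
  mets <- paste0("m", seq_len(m))
  rxns <- stats::setNames(lapply(seq_len(n), function(j) {
    nz <- which(S[, j] != 0)
    list(metabolites = stats::setNames(S[nz, j], mets[nz]),
         lb = lb[j], ub = ub[j], objective = obj[j])
  }), paste0("r", seq_len(n)))
  MetabolicModel(sprintf("rand%d", seed), rxns)
}

## Exhaustive iMAT oracle: enumerate every indicator assignment over the
## high (forward/reverse) and low reactions, check LP feasibility of the
## implied flux constraints, and return the maximal achievable count.
imatEnumOracle <- function(model, classes, epsilon = 0.1) {
  S <- as.matrix(stoichiometricMatrix(model))
  lb <- unname(lowerBounds(model)); ub <- unname(upperBounds(model))
  n <- ncol(S)
  hi <- which(classes == "high")
  lo <- which(classes == "low")
  ## indicator slots: (reaction, mode) with mode fwd/rev for high, zero for low
  slots <- list()
  for (i in hi) {
    slots[[length(slots) + 1L]] <- c(i, 1)
    if (lb[i] < -epsilon / 2) slots[[length(slots) + 1L]] <- c(i, -1)
  }
  for (i in lo) slots[[length(slots) + 1L]] <- c(i, 0)
  ns <- length(slots)
  best <- -1L
  for (mask in 0:(2^ns - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(ns) - 1)))
    lo2 <- lb; hi2 <- ub
    ok <- TRUE
    for (k in which(sel)) {
      i <- slots[[k]][1]; mode <- slots[[k]][2]
      if (mode == 1) lo2[i] <- max(lo2[i], epsilon)
      else if (mode == -1) hi2[i] <- min(hi2[i], -epsilon)
      else { lo2[i] <- max(lo2[i], 0); hi2[i] <- min(hi2[i], 0) }
      if (lo2[i] > hi2[i]) { ok <- FALSE; break }
    }
    if (!ok) next
    r <- metaboSL:::.lpSolve(numeric(n), Aeq = S, beq = rep(0, nrow(S)),
                             lb = lo2, ub = hi2)
    if (r$status == "optimal" && sum(sel) > best) best <- sum(sel)
  }
  best
}

## Brute-force hypergeometric upper tail via log-binomials.
bruteHyperTail <- function(nMethod, nScreen, overlap, universe) {
  kmax <- min(nMethod, nScreen)
  if (overlap > kmax) return(0)
  k <- overlap:kmax
  terms <- lchoose(nScreen, k) + lchoose(universe - nScreen, nMethod - k) -
    lchoose(universe, nMethod)
  sum(exp(terms))
}

## Random boolean expression tree over the given genes; returns list(text,
## eval = function(knockedOut) logical) built independently of parseGpr.
randomGprCase <- function(genes, depth = 0) {
  if (depth >= 3 || stats::runif(1) < 0.4) {
    g <- sample(genes, 1)
    return(list(text = g,
                eval = local({
                  gg <- g
                  function(ko) !(gg %in% ko)
                })))
  }
  op <- sample(c("and", "or"), 1)
  kids <- lapply(seq_len(sample(2:3, 1)), function(i)
    randomGprCase(genes, depth + 1))
  list(text = paste0("(", paste(vapply(kids, `[[`, "", "text"),
                                collapse = paste0(" ", op, " ")), ")"),
       eval = local({
         kk <- kids; oo <- op
         function(ko) {
           vals <- vapply(kk, function(k) k$eval(ko), NA)
           if (oo == "and") all(vals) else any(vals)
         }
       }))
}
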