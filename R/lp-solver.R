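# Internal dense LP/MILP machinery.
#
# Constraint-based model analysis needs exact control over solver status and
# deterministic pivoting (repeated runs must give identical flux vectors), so
# the package carries its own two-phase primal simplex with Bland's rule and a
# depth-first branch-and-bound for the handful of binary variables the iMAT
# extraction introduces. Problems here are small and dense (tens of variables).

.LP_TOL <- 1e-9

#' Solve a linear program
#'
#' Minimises (or maximises) \code{obj \%*\% x} subject to
#' \code{Aeq x = beq}, \code{Aub x <= bub} and \code{lb <= x <= ub}.
#' Deterministic: Bland's anti-cycling rule, no randomisation.
#'
#' @param obj numeric objective coefficients.
#' @param Aeq,beq equality constraints (matrix may be \code{NULL}).
#' @param Aub,bub inequality (\code{<=}) constraints (may be \code{NULL}).
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical; maximise instead of minimise.
#' @return list with \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}), \code{x} and \code{objval}.
#' @keywords internal
#' @noRd
.lpSolve <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                     lb = NULL, ub = NULL, maximize = FALSE) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(-Inf, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))
  }
  cvec <- if (maximize) -obj else obj

  ## --- translate each variable to one or two nonnegative columns ----------
  ## x_j = shift_j + sum(sign_jk * s_k); finite upper caps become rows.
  colOrig <- integer(0)   # originating variable of each standard column
  colSign <- numeric(0)
  shift <- numeric(n)
  capRowVar <- integer(0) # columns with an upper cap
  capRowVal <- numeric(0)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      shift[j] <- lb[j]
      colOrig <- c(colOrig, j); colSign <- c(colSign, 1)
      k <- length(colOrig)
      if (is.finite(ub[j])) {
        capRowVar <- c(capRowVar, k)
        capRowVal <- c(capRowVal, ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      shift[j] <- ub[j]
      colOrig <- c(colOrig, j); colSign <- c(colSign, -1)
    } else {
      shift[j] <- 0
      colOrig <- c(colOrig, j, j); colSign <- c(colSign, 1, -1)
    }
  }
  ns <- length(colOrig)

  expand <- function(A) {
    if (is.null(A)) return(NULL)
    A <- as.matrix(A)
    M <- matrix(0, nrow(A), ns)
    for (k in seq_len(ns)) M[, k] <- A[, colOrig[k]] * colSign[k]
    M
  }
  Meq <- expand(Aeq); Mub <- expand(Aub)
  deq <- if (is.null(Aeq)) numeric(0) else beq - as.vector(as.matrix(Aeq) %*% shift)
  dub <- if (is.null(Aub)) numeric(0) else bub - as.vector(as.matrix(Aub) %*% shift)

  ## cap rows s_k <= cap
  nCap <- length(capRowVar)
  if (nCap) {
    Mcap <- matrix(0, nCap, ns)
    Mcap[cbind(seq_len(nCap), capRowVar)] <- 1
    Mub <- rbind(Mub, Mcap)
    dub <- c(dub, capRowVal)
  }

  mEq <- if (is.null(Meq)) 0L else nrow(Meq)
  mUb <- if (is.null(Mub)) 0L else nrow(Mub)
  m <- mEq + mUb
  nSlack <- mUb
  N <- ns + nSlack

  M <- matrix(0, m, N)
  d <- numeric(m)
  if (mEq) { M[seq_len(mEq), seq_len(ns)] <- Meq; d[seq_len(mEq)] <- deq }
  if (mUb) {
    r <- mEq + seq_len(mUb)
    M[r, seq_len(ns)] <- Mub
    M[cbind(r, ns + seq_len(mUb))] <- 1
    d[r] <- dub
  }
  flip <- d < 0
  if (any(flip)) { M[flip, ] <- -M[flip, , drop = FALSE]; d[flip] <- -d[flip] }

  cost <- c(cvec[colOrig] * colSign, numeric(nSlack))

  res <- .simplexTwoPhase(M, d, cost)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n), objval = NA_real_))
  }
  s <- res$x[seq_len(ns)]
  x <- shift
  for (k in seq_len(ns)) x[colOrig[k]] <- x[colOrig[k]] + colSign[k] * s[k]
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}

## Two-phase tableau simplex for min cost's s.t. M s = d (d >= 0), s >= 0.
.simplexTwoPhase <- function(M, d, cost, maxit = 50000L) {
  m <- nrow(M); N <- ncol(M)
  if (m == 0L) {
    # no constraints: min of cost * s over s >= 0
    if (any(cost < -.LP_TOL)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(N), objval = 0))
  }
  ## phase 1: artificials on every row
  Tab <- cbind(M, diag(m), d)
  art <- N + seq_len(m)
  basis <- art
  p1cost <- c(numeric(N), rep(1, m))
  r <- .simplexRun(Tab, basis, p1cost, ncol(Tab), maxit)
  if (r$status != "optimal") return(list(status = r$status))
  Tab <- r$Tab; basis <- r$basis
  p1obj <- sum(p1cost[basis] * Tab[, ncol(Tab)])
  if (p1obj > 1e-7) return(list(status = "infeasible"))
  ## drive artificials out of the basis where possible
  for (i in seq_len(m)) {
    if (basis[i] > N) {
      piv <- which(abs(Tab[i, seq_len(N)]) > .LP_TOL)
      if (length(piv)) {
        Tab <- .pivot(Tab, i, piv[1])
        basis[i] <- piv[1]
      }
    }
  }
  keep <- basis <= N
  Tab <- Tab[keep, , drop = FALSE]   # rows still basic in an artificial are redundant
  basis <- basis[keep]
  Tab <- Tab[, c(seq_len(N), ncol(Tab)), drop = FALSE]  # drop artificial columns
  ## phase 2
  r <- .simplexRun(Tab, basis, cost, N + 1L, maxit)
  if (r$status != "optimal") return(list(status = r$status))
  x <- numeric(N)
  x[r$basis] <- r$Tab[, N + 1L]
  list(status = "optimal", x = x)
}

.simplexRun <- function(Tab, basis, cost, rhsCol, maxit) {
  ncols <- rhsCol - 1L
  for (it in seq_len(maxit)) {
    cB <- cost[basis]
    red <- cost[seq_len(ncols)] -
      as.vector(crossprod(Tab[, seq_len(ncols), drop = FALSE], cB))
    ent <- which(red < -1e-8)
    if (!length(ent)) {
      return(list(status = "optimal", Tab = Tab, basis = basis))
    }
    j <- ent[1]                               # Bland: smallest index
    col <- Tab[, j]
    pos <- which(col > .LP_TOL)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- Tab[pos, rhsCol] / col[pos]
    best <- min(ratio)
    cand <- pos[ratio <= best + .LP_TOL]
    i <- cand[which.min(basis[cand])]         # Bland on leaving variable
    Tab <- .pivot(Tab, i, j)
    basis[i] <- j
  }
  list(status = "maxiter")
}

.pivot <- function(Tab, i, j) {
  Tab[i, ] <- Tab[i, ] / Tab[i, j]
  other <- setdiff(seq_len(nrow(Tab)), i)
  if (length(other)) {
    Tab[other, ] <- Tab[other, , drop = FALSE] -
      outer(Tab[other, j], Tab[i, ])
  }
  Tab
}

#' Branch-and-bound mixed-binary LP
#'
#' Maximises \code{obj \%*\% x} over the constraints of \code{.lpSolve} with
#' the variables listed in \code{binary} restricted to \{0, 1\}. Zero
#' optimality gap; deterministic depth-first search branching on the most
#' fractional binary (ties to the smallest index), 1-branch explored first.
#'
#' @keywords internal
#' @noRd
.milpSolve <- function(obj, Aeq = NULL, beq = NULL, Aub = NULL, bub = NULL,
                       lb, ub, binary = integer(0), intTol = 1e-6) {
  best <- NULL
  bestObj <- -Inf
  explore <- function(lo, hi) {
    rel <- .lpSolve(obj, Aeq, beq, Aub, bub, lo, hi, maximize = TRUE)
    if (rel$status != "optimal") return(invisible(NULL))
    if (rel$objval <= bestObj + 1e-9) return(invisible(NULL))  # bound prune
    xb <- rel$x[binary]
    frac <- pmin(xb - floor(xb), ceiling(xb) - xb)
    if (!length(binary) || max(frac) <= intTol) {
      if (rel$objval > bestObj + 1e-9) {
        bestObj <<- rel$objval
        best <<- rel
      }
      return(invisible(NULL))
    }
    k <- binary[which.max(frac)]
    lo1 <- lo; hi1 <- hi
    lo1[k] <- 1; explore(lo1, hi)        # 1-branch first
    hi1[k] <- 0; explore(lo, hi1)
    invisible(NULL)
  }
  lo <- lb; hi <- ub
  lo[binary] <- pmax(lo[binary], 0)
  hi[binary] <- pmin(hi[binary], 1)
  explore(lo, hi)
  if (is.null(best)) {
    return(list(status = "infeasible", x = rep(NA_real_, length(obj)),
                objval = NA_real_))
  }
  x <- best$x
  x[binary] <- round(x[binary])
  list(status = "optimal", x = x, objval = best$objval)
}
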