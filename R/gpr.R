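#' @include AllClasses.R AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GPR boolean algebra.
##
## Grammar (case-insensitive keywords, everything else is a gene id):
##   or_expr  := and_expr ("or" and_expr)*
##   and_expr := primary ("and" primary)*
##   primary  := "(" or_expr ")" | GENE
## The empty rule parses to the distinguished always-active expression.

.gprTokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1L) return(data.frame(tok = character(0), pos = integer(0)))
  data.frame(tok = regmatches(text, list(m))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean GPR rule ("and"/"or", case-insensitive, parentheses;
#' any other token is a gene identifier) into a \linkS4class{GprExpression}.
#' A blank rule yields the always-active expression. Parsing, unparsing and
#' re-parsing is idempotent; dotted identifiers such as \code{"1234.1"}
#' survive unmodified.
#'
#' @param text GPR rule string.
#' @return a \linkS4class{GprExpression}.
#' @examples
#' parseGpr("(g1 and g2) or g3")
#' evaluateGpr(parseGpr("g1 or g2"), knockedOut = "g1")
#' @export
parseGpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(new("GprExpression", tree = list(op = "true"), text = ""))
  }
  toks <- .gprTokenize(text)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  err <- function(msg, at = if (i <= n) toks$pos[i] else nchar(text) + 1L) {
    stop(sprintf("GPR parse error at offset %d: %s (rule: '%s')",
                 at, msg, text), call. = FALSE)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      i <<- i + 1L
      args <- c(args, list(parseAnd()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parseAnd <- function() {
    args <- list(parsePrimary())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      i <<- i + 1L
      args <- c(args, list(parsePrimary()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parsePrimary <- function() {
    tk <- peek()
    if (is.na(tk)) err("unexpected end of rule")
    if (tk == "(") {
      open <- toks$pos[i]
      i <<- i + 1L
      node <- parseOr()
      if (is.na(peek()) || peek() != ")")
        err("unbalanced parenthesis", open)
      i <<- i + 1L
      return(node)
    }
    if (tk == ")") err("unmatched closing parenthesis")
    if (tolower(tk) %in% c("and", "or")) err(sprintf("stray '%s'", tk))
    i <<- i + 1L
    list(op = "gene", gene = tk)
  }
  tree <- parseOr()
  if (i <= n) err(sprintf("stray token '%s'", peek()))
  new("GprExpression", tree = tree, text = text)
}

#' Unparse a GprExpression back to rule text
#'
#' @param expr a \linkS4class{GprExpression}.
#' @return a rule string; \code{""} for the always-active expression.
#' @export
unparseGpr <- function(expr) {
  stopifnot(is(expr, "GprExpression"))
  de <- function(nd, parentOp = "") {
    switch(nd$op,
      true = "",
      gene = nd$gene,
      and = {
        s <- paste(vapply(nd$args, de, "", parentOp = "and"),
                   collapse = " and ")
        if (parentOp == "") s else s
      },
      or = {
        s <- paste(vapply(nd$args, de, "", parentOp = "or"),
                   collapse = " or ")
        if (parentOp == "and") paste0("(", s, ")") else s
      })
  }
  de(expr@tree)
}

## Tree-level workers (plain nested lists; the MetabolicModel gprTree cache
## stores these directly).
.treeEval <- function(nd, knockedOut) {
  switch(nd$op,
    true = TRUE,
    gene = !(nd$gene %in% knockedOut),
    and = all(vapply(nd$args, .treeEval, NA, knockedOut = knockedOut)),
    or  = any(vapply(nd$args, .treeEval, NA, knockedOut = knockedOut)))
}

.treeGenes <- function(nd) {
  unique(switch(nd$op,
    true = character(0),
    gene = nd$gene,
    unlist(lapply(nd$args, .treeGenes))))
}

## Numeric aggregation of expression over a rule: AND -> min, OR -> max
## (the COBRA convention). Genes absent from `values` are ignored; a rule
## whose genes are all absent (or the always-active rule) yields NA, the
## "unmapped" sentinel.
.treeValue <- function(nd, values) {
  switch(nd$op,
    true = NA_real_,
    gene = if (nd$gene %in% names(values)) values[[nd$gene]] else NA_real_,
    and = {
      v <- vapply(nd$args, .treeValue, 0, values = values)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    },
    or = {
      v <- vapply(nd$args, .treeValue, 0, values = values)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
}

#' Evaluate a GPR rule under a gene knockout
#'
#' A leaf is active iff its gene is not knocked out; AND/OR combine as
#' boolean conjunction/disjunction; the always-active rule returns
#' \code{TRUE}.
#'
#' @param expr a \linkS4class{GprExpression}.
#' @param knockedOut character vector of knocked-out gene ids.
#' @return logical scalar: does the reaction remain catalysable?
#' @export
evaluateGpr <- function(expr, knockedOut = character(0)) {
  stopifnot(is(expr, "GprExpression"))
  .treeEval(expr@tree, knockedOut)
}

#' Genes appearing in a GPR rule
#'
#' @param expr a \linkS4class{GprExpression}.
#' @return character vector of distinct gene ids (empty for always-active).
#' @export
gprGenes <- function(expr) {
  stopifnot(is(expr, "GprExpression"))
  .treeGenes(expr@tree)
}

setMethod("show", "GprExpression", function(object) {
  txt <- unparseGpr(object)
  cat("GprExpression:",
      if (nzchar(txt)) txt else "<always active>", "\n")
})
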