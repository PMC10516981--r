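## Shared internal helpers.

## Deterministic 31-base polynomial string hash in [0, 2^31 - 2]; used to
## derive independent sub-seeds from (master seed, label) so results do not
## depend on iteration order. Exact in double precision (values < 2^53).
.stableHash <- function(..., seed = 0L) {
  s <- paste(c(seed, ...), collapse = "\r")
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Scientific notation with 6 significant digits for reproducible CSV diffs.
.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.5e", x))
}

.writeNumericCSV <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
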