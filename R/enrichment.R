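#' @include slscan.R
NULL

#' Ranked SL-partner list for one driver gene
#'
#' Collects the driver's tested partner genes with their t statistics and
#' appends the driver itself with score equal to the arithmetic mean of the
#' partner t statistics. The list is sorted by descending absolute score;
#' ties break by larger raw score first, then lexicographic gene id.
#'
#' @param driver driver gene id.
#' @param table an \linkS4class{SLResultTable}.
#' @return data.frame with columns \code{gene}, \code{score} and attribute
#'   \code{"driver"}.
#' @export
buildRankedList <- function(driver, table) {
  stopifnot(is(table, "SLResultTable"))
  r <- table@results
  r <- r[r$driver == driver, , drop = FALSE]
  if (!nrow(r))
    stop(sprintf("driver '%s' has no tested pairs in the table", driver),
         call. = FALSE)
  r <- r[r$ko_gene != driver, , drop = FALSE]  # self-pair would duplicate
  df <- data.frame(gene = c(r$ko_gene, driver),
                   score = c(r$t, mean(r$t)),
                   stringsAsFactors = FALSE)
  ord <- order(-abs(df$score), -df$score, df$gene)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "driver") <- driver
  df
}

## Weighted Kolmogorov-Smirnov enrichment score, weight exponent 1:
## hits advance the running sum by |score| / sum of hit |score|s, misses
## retreat by 1 / (N - N_hits); ES is the extreme deviation (signed).
.gseaES <- function(scores, isHit) {
  N <- length(scores)
  nHit <- sum(isHit)
  w <- abs(scores)
  hitSum <- sum(w[isHit])
  inc <- numeric(N)
  inc[isHit] <- if (hitSum > 0) w[isHit] / hitSum else 1 / nHit
  inc[!isHit] <- -1 / (N - nHit)
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov statistic (weight = |score|, exponent 1) on
#' a ranked gene list, with a gene-label permutation null: p is the
#' fraction of \code{nPerm} seeded permutations whose |ES| reaches the
#' observed |ES|. Sets overlapping the list in fewer than
#' \code{minSetSize} genes are skipped, as are sets covering the whole
#' list (the miss increment is undefined). Per-set permutation seeds derive
#' from (\code{seed}, set name), so results do not depend on collection
#' order.
#'
#' @param ranked data.frame from \code{\link{buildRankedList}} (columns
#'   \code{gene}, \code{score}, sorted by descending |score|).
#' @param sets named list of character vectors (e.g. from
#'   \code{\link{readGeneSetsGMT}}).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer master seed.
#' @param minSetSize minimum overlap with the ranked list (default 2).
#' @return data.frame with one row per scored set: \code{set},
#'   \code{size} (overlap), \code{ES}, \code{p}; skipped sets are recorded
#'   in attribute \code{"skipped"}.
#' @export
prerankedGsea <- function(ranked, sets, nPerm = 1000L, seed = 1L,
                          minSetSize = 2L) {
  stopifnot(is.data.frame(ranked),
            all(c("gene", "score") %in% colnames(ranked)),
            !anyDuplicated(ranked$gene))
  scores <- ranked$score
  N <- length(scores)
  rows <- list(); skipped <- character(0)
  for (nm in names(sets)) {
    isHit <- ranked$gene %in% sets[[nm]]
    nHit <- sum(isHit)
    if (nHit < minSetSize || nHit == N) {
      skipped <- c(skipped, nm)
      next
    }
    es <- .gseaES(scores, isHit)
    exceed <- .withSeed(.stableHash("gsea-perm", nm, seed = seed), {
      sum(vapply(seq_len(nPerm), function(k) {
        permHit <- logical(N)
        permHit[sample.int(N, nHit)] <- TRUE
        abs(.gseaES(scores, permHit)) >= abs(es)
      }, NA))
    })
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, size = nHit, ES = es, p = exceed / nPerm,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(set = character(0), size = integer(0),
                         ES = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Cross-driver frequency of enriched processes
#'
#' Counts, for each gene set, the drivers for which it is significant at
#' nominal \code{p <= alpha} (optionally after Benjamini-Hochberg
#' adjustment within each driver).
#'
#' @param results named list (driver -> data.frame from
#'   \code{\link{prerankedGsea}}).
#' @param alpha significance threshold (default 0.05).
#' @param adjust apply BH within each driver before thresholding
#'   (default \code{FALSE}).
#' @return data.frame with columns \code{set}, \code{frequency}, sorted by
#'   descending frequency (ties lexicographic).
#' @export
processFrequency <- function(results, alpha = 0.05, adjust = FALSE) {
  counts <- list()
  for (drv in names(results)) {
    df <- results[[drv]]
    if (!nrow(df)) next
    p <- if (adjust) bhAdjust(df$p) else df$p
    for (s in df$set[p <= alpha])
      counts[[s]] <- (if (is.null(counts[[s]])) 0L else counts[[s]]) + 1L
  }
  if (!length(counts))
    return(data.frame(set = character(0), frequency = integer(0)))
  out <- data.frame(set = names(counts),
                    frequency = unlist(counts, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
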