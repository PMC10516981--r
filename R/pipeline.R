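#' @include validation.R enrichment.R io.R
NULL

.configDefaults <- function() {
  list(
    cancer = "unspecified",
    paths = list(model = NULL, expression = NULL, mutations = NULL,
                 dependency = list(), compound_map = NULL,
                 gene_sets = NULL, tasks = NULL, output_dir = NULL),
    parameters = list(alpha = 0.05, filter_mean = 0.95, noise_lo = 1e-12,
                      noise_hi = 1e-11, seed = 1L, min_mutated_lines = 2L,
                      cutoff = 0.01, epsilon = 0.1, epsilon_task = 1e-4,
                      n_perm = 1000L, grid = NULL))
}

#' Load and validate a pipeline configuration
#'
#' YAML configuration with sections \code{cancer}, \code{paths} (model,
#' expression, mutations, output_dir; optional dependency (named list),
#' compound_map, gene_sets, tasks) and \code{parameters} (alpha,
#' filter_mean, noise_lo, noise_hi, seed, min_mutated_lines, cutoff,
#' epsilon, epsilon_task, n_perm). Missing parameters receive defaults;
#' unknown keys and out-of-range values raise one error listing every
#' violation; referenced input paths must exist.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return validated config list (defaults filled).
#' @export
loadConfig <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- .configDefaults()
  errs <- character(0)
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    errs <- c(errs, sprintf("unknown top-level key(s): %s",
                            paste(bad, collapse = ", ")))
  for (sec in c("paths", "parameters")) {
    bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(bad))
      errs <- c(errs, sprintf("unknown %s key(s): %s", sec,
                              paste(bad, collapse = ", ")))
  }
  out <- def
  out$cancer <- if (!is.null(cfg$cancer)) cfg$cancer else def$cancer
  for (k in intersect(names(cfg$paths), names(def$paths)))
    if (!is.null(cfg$paths[[k]])) out$paths[[k]] <- cfg$paths[[k]]
  for (k in intersect(names(cfg$parameters), names(def$parameters)))
    if (!is.null(cfg$parameters[[k]]))
      out$parameters[[k]] <- cfg$parameters[[k]]
  p <- out$parameters
  chk <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  chk(is.numeric(p$alpha) && p$alpha > 0 && p$alpha <= 1,
      "alpha must lie in (0, 1]")
  chk(is.numeric(p$filter_mean) && p$filter_mean >= 0 && p$filter_mean <= 1,
      "filter_mean must lie in [0, 1]")
  chk(is.numeric(p$cutoff) && p$cutoff > 0 && p$cutoff < 1,
      "cutoff must lie in (0, 1)")
  chk(is.numeric(p$noise_lo) && is.numeric(p$noise_hi) &&
        p$noise_lo >= 0 && p$noise_lo < p$noise_hi,
      "noise bounds must satisfy 0 <= noise_lo < noise_hi")
  chk(is.numeric(p$epsilon) && p$epsilon > 0, "epsilon must be positive")
  chk(is.numeric(p$epsilon_task) && p$epsilon_task > 0,
      "epsilon_task must be positive")
  chk(p$min_mutated_lines >= 1, "min_mutated_lines must be >= 1")
  chk(p$n_perm >= 1, "n_perm must be >= 1")
  if (!is.null(p$grid)) {
    g <- if (is.data.frame(p$grid) &&
               all(c("lb", "ub") %in% colnames(p$grid))) {
      p$grid[, c("lb", "ub")]
    } else if (is.list(p$grid) && all(c("lb", "ub") %in% names(p$grid))) {
      data.frame(lb = unlist(p$grid$lb), ub = unlist(p$grid$ub))
    } else if (is.list(p$grid) && all(vapply(p$grid, function(e)
        is.list(e) && all(c("lb", "ub") %in% names(e)), NA))) {
      do.call(rbind, lapply(p$grid, function(e)
        data.frame(lb = e$lb, ub = e$ub)))
    } else NULL
    chk(!is.null(g), "grid entries must each provide lb and ub")
    if (!is.null(g)) {
      chk(all(g$lb <= g$ub), "grid entries must satisfy lb <= ub")
      out$parameters$grid <- g
    }
  }
  for (k in c("model", "expression", "mutations", "output_dir"))
    chk(!is.null(out$paths[[k]]), sprintf("paths.%s is required", k))
  inputPaths <- c(out$paths[c("model", "expression", "mutations",
                              "compound_map", "gene_sets", "tasks")],
                  out$paths$dependency)
  for (pth in Filter(Negate(is.null), inputPaths))
    chk(file.exists(pth), sprintf("input path does not exist: %s", pth))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  out$parameters$seed <- as.integer(p$seed)
  out$parameters$min_mutated_lines <- as.integer(p$min_mutated_lines)
  out$parameters$n_perm <- as.integer(p$n_perm)
  out
}

#' @rdname loadConfig
#' @param config a validated config list.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.readModelAuto <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) readModelJSON(path)
  else readSBMLModel(path)
}

.logStage <- function(stage, event, quiet) {
  if (!quiet)
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%OS1"),
                    stage, event))
}

#' Run the full prediction pipeline
#'
#' Executes, in order: context-model construction per cell line, KO-score
#' simulation, the mutation-stratified SL scan, screen validation (when
#' dependency matrices are configured) and gene-set enrichment (when a GMT
#' collection is configured). Per-stage CSV outputs land in
#' \code{paths$output_dir} with floats in 6-significant-digit scientific
#' notation; a JSON manifest records parameters, seeds and per-stage row
#' counts. Stages whose outputs already exist are skipped unless
#' \code{force}.
#'
#' @param config validated config from \code{\link{loadConfig}}.
#' @param force rerun stages whose outputs already exist.
#' @param quiet suppress per-stage log lines.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, force = FALSE, quiet = FALSE) {
  cfg <- loadConfig(config)  # re-validate (idempotent on valid configs)
  p <- cfg$parameters
  outDir <- cfg$paths$output_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "metaboSL",
                   version = as.character(utils::packageVersion("metaboSL")),
                   cancer = cfg$cancer, parameters = p, stages = list())
  note <- function(stage, status, rows = NA_integer_) {
    manifest$stages[[stage]] <<- list(status = status, rows = rows)
    .logStage(stage, status, quiet)
  }
  outFile <- function(...) file.path(outDir, ...)

  generic <- .readModelAuto(cfg$paths$model)
  expr <- readExpressionMatrix(cfg$paths$expression)
  maf <- readMutationMAF(cfg$paths$mutations)
  universe <- modelGenes(generic)
  mutations <- mutationMatrixFromMAF(maf, cellLines = colnames(expr),
                                     genes = universe,
                                     source = cfg$paths$mutations)

  ## stage 1: context models -------------------------------------------------
  modelsDir <- outFile("models")
  buildCsv <- outFile("build_summary.csv")
  if (file.exists(buildCsv) && !force) {
    note("build-models", "skipped (outputs up to date)")
    builds <- NULL
  } else {
    builds <- buildContextModels(generic, expr, grid = p$grid, epsilon = p$epsilon)
    dir.create(modelsDir, showWarnings = FALSE)
    summ <- do.call(rbind, lapply(names(builds), function(cl) {
      writeModelJSON(builds[[cl]]$model,
                     file.path(modelsDir, paste0(cl, ".json")))
      data.frame(cell_line = cl,
                 n_reactions = length(reactionIds(builds[[cl]]$model)),
                 lb = builds[[cl]]$thresholds$lb,
                 ub = builds[[cl]]$thresholds$ub,
                 grid_index = builds[[cl]]$index,
                 biomass = builds[[cl]]$objective,
                 stringsAsFactors = FALSE)
    }))
    .writeNumericCSV(summ, buildCsv)
    note("build-models", "completed", nrow(summ))
  }

  ## stage 2: KO-score matrix ------------------------------------------------
  koCsv <- outFile("ko_scores.csv")
  if (file.exists(koCsv) && !force) {
    note("ko-scan", "skipped (outputs up to date)")
    scores <- readExpressionMatrix(koCsv)
  } else {
    if (is.null(builds))
      builds <- buildContextModels(generic, expr, grid = p$grid, epsilon = p$epsilon)
    ko <- buildKoScoreMatrix(lapply(builds, `[[`, "model"), universe)
    scores <- koScores(ko)
    df <- data.frame(gene = rownames(scores), scores, check.names = FALSE)
    .writeNumericCSV(df, koCsv)
    note("ko-scan", "completed", nrow(scores))
  }

  ## stage 3: SL scan --------------------------------------------------------
  slCsv <- outFile("sl_scan.csv")
  if (file.exists(slCsv) && !force) {
    note("slscan", "skipped (outputs up to date)")
    slTab <- .slTableFromCSV(slCsv, p, cfg$cancer)
  } else {
    slTab <- slScan(scores, mutations, alpha = p$alpha, seed = p$seed,
                    filterMean = p$filter_mean, noiseLo = p$noise_lo,
                    noiseHi = p$noise_hi,
                    minMutatedLines = p$min_mutated_lines,
                    cancer = cfg$cancer)
    df <- cbind(cancer = cfg$cancer, scanResults(slTab))
    .writeNumericCSV(df, slCsv)
    note("slscan", "completed", nrow(scanResults(slTab)))
  }

  ## stage 4: screen validation ----------------------------------------------
  depPaths <- cfg$paths$dependency
  if (!length(depPaths)) {
    note("validate", "skipped (no dependency matrices configured)")
  } else if (file.exists(outFile("concordance.csv")) && !force) {
    note("validate", "skipped (outputs up to date)")
  } else {
    compoundMap <- if (!is.null(cfg$paths$compound_map))
      readCompoundTargetMap(cfg$paths$compound_map) else NULL
    rows <- list()
    for (kind in names(depPaths)) {
      dep <- readDependencyMatrix(depPaths[[kind]], kind = kind)
      st <- screenSlScan(dep, mutations, alpha = p$alpha,
                         minMutatedLines = p$min_mutated_lines,
                         compoundTargets = if (kind == "prism")
                           compoundMap else NULL,
                         cancer = cfg$cancer)
      .writeNumericCSV(cbind(cancer = cfg$cancer, scanResults(st)),
                       outFile(sprintf("screen_%s.csv", kind)))
      cc <- concordance(slTab, st, alpha = p$alpha)
      rows[[kind]] <- data.frame(
        cancer = cfg$cancer, screen = kind,
        p = hypergeometricEnrichment(cc)$p,
        n_method = cc@nMethod, n_screen = cc@nScreen,
        overlap = cc@overlap, universe = cc@universe,
        stringsAsFactors = FALSE)
    }
    .writeNumericCSV(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                     outFile("concordance.csv"))
    note("validate", "completed", length(rows))
  }

  ## stage 5: enrichment ------------------------------------------------------
  if (is.null(cfg$paths$gene_sets)) {
    note("enrich", "skipped (no gene sets configured)")
  } else if (file.exists(outFile("process_frequency.csv")) && !force) {
    note("enrich", "skipped (outputs up to date)")
  } else {
    sets <- readGeneSetsGMT(cfg$paths$gene_sets)
    res <- scanResults(slTab)
    gsea <- list()
    for (drv in unique(res$driver)) {
      ranked <- buildRankedList(drv, slTab)
      gsea[[drv]] <- prerankedGsea(ranked, sets, nPerm = p$n_perm,
                                   seed = p$seed)
    }
    flat <- do.call(rbind, lapply(names(gsea), function(d)
      if (nrow(gsea[[d]])) cbind(driver = d, gsea[[d]]) else NULL))
    if (!is.null(flat)) .writeNumericCSV(flat, outFile("gsea.csv"))
    freq <- processFrequency(gsea, alpha = p$alpha)
    .writeNumericCSV(freq, outFile("process_frequency.csv"))
    note("enrich", "completed",
         if (is.null(flat)) 0L else nrow(flat))
  }

  jsonlite::write_json(manifest, outFile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## rebuild an SLResultTable from a pipeline CSV (resume path)
.slTableFromCSV <- function(path, p, cancer) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$cancer <- NULL
  df$filtered <- as.logical(df$filtered)
  df$significant <- as.logical(df$significant)
  new("SLResultTable", results = df,
      metadata = list(alpha = p$alpha, seed = p$seed, cancer = cancer,
                      resumed = TRUE))
}
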