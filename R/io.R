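#' @include model.R
NULL

## ---------------------------------------------------------------------------
## Model serialisation: a JSON dialect and SBML Level 3 + FBC.

#' Read / write a metabolic model in JSON
#'
#' The JSON dialect has top-level fields \code{id}, \code{metabolites}
#' (array of \{id, name?, compartment?, formula?\}), \code{reactions}
#' (array of \{id, metabolites (id -> coefficient map), lower_bound,
#' upper_bound, gene_reaction_rule, objective_coefficient\}) and
#' \code{genes} (array of ids). Writing then reading reproduces the model.
#'
#' @param path file path.
#' @return \code{readModelJSON}: a \linkS4class{MetabolicModel}.
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rxns <- list()
  for (r in j$reactions) {
    st <- unlist(r$metabolites)
    rxns[[r$id]] <- list(
      metabolites = if (length(st)) st else stats::setNames(numeric(0),
                                                            character(0)),
      lb = r$lower_bound, ub = r$upper_bound,
      gpr = if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
      objective = if (is.null(r$objective_coefficient)) 0
                  else r$objective_coefficient)
  }
  metData <- do.call(rbind, lapply(j$metabolites, function(m)
    data.frame(met = m$id,
               name = if (is.null(m$name)) NA_character_ else m$name,
               compartment = if (is.null(m$compartment)) NA_character_
                             else m$compartment,
               formula = if (is.null(m$formula)) NA_character_
                         else m$formula,
               stringsAsFactors = FALSE)))
  if (is.null(metData))
    metData <- data.frame(met = character(0), stringsAsFactors = FALSE)
  id <- if (is.null(j$id)) tools::file_path_sans_ext(basename(path)) else j$id
  MetabolicModel(id, rxns, metData = metData)
}

#' @rdname readModelJSON
#' @param model a \linkS4class{MetabolicModel}.
#' @return \code{writeModelJSON}: \code{path}, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "MetabolicModel"))
  mets <- lapply(seq_along(model@mets), function(i) {
    out <- list(id = model@mets[i])
    md <- model@metData
    if (nrow(md) && model@mets[i] %in% md$met) {
      row <- md[md$met == model@mets[i], , drop = FALSE][1, ]
      for (f in c("name", "compartment", "formula"))
        if (f %in% colnames(row) && !is.na(row[[f]])) out[[f]] <- row[[f]]
    }
    out
  })
  S <- model@S
  rxns <- lapply(seq_along(model@rxns), function(j) {
    nz <- which(S[, j] != 0)
    list(id = model@rxns[j],
         metabolites = as.list(stats::setNames(as.numeric(S[nz, j]),
                                               model@mets[nz])),
         lower_bound = model@lb[j], upper_bound = model@ub[j],
         gene_reaction_rule = model@gpr[j],
         objective_coefficient = model@obj[j])
  })
  jsonlite::write_json(
    list(id = model@id, metabolites = mets, reactions = rxns,
         genes = as.list(modelGenes(model))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## SBML ids may not contain dots etc.; gene identity is carried by
## fbc:label, the id is a sanitised mirror.
.sbmlSanitize <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

#' Read / write a metabolic model in SBML Level 3 with the FBC extension
#'
#' Covers the subset of SBML L3V1 + FBC v2 that constraint-based analysis
#' needs: species, reactions with stoichiometry, flux bounds via shared
#' parameters, the active maximisation objective, and gene-product
#' associations (nested fbc:and / fbc:or / fbc:geneProductRef). Gene
#' identity is carried in \code{fbc:label}, so dotted identifiers
#' round-trip unmodified.
#'
#' @param path file path.
#' @return \code{readSBMLModel}: a \linkS4class{MetabolicModel}.
#' @export
readSBMLModel <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  modelNode <- xml2::xml_find_first(doc, ".//s:model", ns)
  id <- xml2::xml_attr(modelNode, "id")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct",
                            ns)
  glabel <- stats::setNames(xml2::xml_attr(gps, "label"),
                            xml2::xml_attr(gps, "id"))
  spNodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  metData <- data.frame(
    met = xml2::xml_attr(spNodes, "id"),
    name = xml2::xml_attr(spNodes, "name"),
    compartment = xml2::xml_attr(spNodes, "compartment"),
    stringsAsFactors = FALSE)
  ## objective coefficients
  fluxObj <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  objCoef <- stats::setNames(
    as.numeric(xml2::xml_attr(fluxObj, "coefficient")),
    xml2::xml_attr(fluxObj, "reaction"))
  gprFromNode <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      g <- glabel[[gid]]
      if (is.null(g) || is.na(g)) g <- gid
      return(g)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gprFromNode, "")
    if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else paste0("(", paste(parts, collapse = " or "), ")")
  }
  rxNodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- list()
  for (node in rxNodes) {
    rid <- xml2::xml_attr(node, "id")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node,
                                 sprintf("./s:%s/s:speciesReference", side),
                                 ns)
      if (!length(refs)) next
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      if (side == "listOfReactants") coef <- -coef
      st <- c(st, stats::setNames(coef, xml2::xml_attr(refs, "species")))
    }
    lbp <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ubp <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else gprFromNode(gpa)
    oc <- objCoef[rid]
    rxns[[rid]] <- list(
      metabolites = st,
      lb = unname(pval[lbp]), ub = unname(pval[ubp]),
      gpr = gpr,
      objective = if (is.na(oc)) 0 else unname(oc))
  }
  MetabolicModel(if (is.na(id)) "model" else id, rxns, metData = metData)
}

#' @rdname readSBMLModel
#' @param model a \linkS4class{MetabolicModel}.
#' @return \code{writeSBMLModel}: \code{path}, invisibly.
#' @export
writeSBMLModel <- function(model, path) {
  stopifnot(is(model, "MetabolicModel"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  genes <- modelGenes(model)
  gid <- stats::setNames(paste0("G_", .sbmlSanitize(genes)), genes)
  ## GPR tree -> nested fbc elements
  gprXml <- function(nd, indent) {
    pad <- strrep(" ", indent)
    switch(nd$op,
      gene = sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     pad, gid[[nd$gene]]),
      and = paste0(pad, "<fbc:and>\n",
                   paste(vapply(nd$args, gprXml, "", indent = indent + 2),
                         collapse = "\n"),
                   "\n", pad, "</fbc:and>"),
      or = paste0(pad, "<fbc:or>\n",
                  paste(vapply(nd$args, gprXml, "", indent = indent + 2),
                        collapse = "\n"),
                  "\n", pad, "</fbc:or>"))
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/',
           'fbc/version2" level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model@id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>')
  if (length(model@mets)) {
    lines <- c(lines, "    <listOfSpecies>")
    for (i in seq_along(model@mets)) {
      md <- model@metData
      comp <- "c"; nm <- NULL
      if (nrow(md) && model@mets[i] %in% md$met) {
        row <- md[md$met == model@mets[i], , drop = FALSE][1, ]
        if ("compartment" %in% colnames(row) && !is.na(row$compartment))
          comp <- row$compartment
        if ("name" %in% colnames(row) && !is.na(row$name)) nm <- row$name
      }
      lines <- c(lines, sprintf(
        paste0('      <species id="%s"%s compartment="%s" ',
               'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
               'constant="false"/>'),
        esc(model@mets[i]),
        if (is.null(nm)) "" else sprintf(' name="%s"', esc(nm)),
        esc(comp)))
    }
    lines <- c(lines, "    </listOfSpecies>")
  }
  ## one shared parameter per distinct bound value
  vals <- sort(unique(c(model@lb, model@ub)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)),
                         sprintf("%.17g", vals))
  lines <- c(lines, "    <listOfParameters>",
             sprintf(paste0('      <parameter id="%s" value="%s" ',
                            'constant="true"/>'),
                     pid, sprintf("%.17g", vals)),
             "    </listOfParameters>")
  if (length(genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
               sprintf(paste0('      <fbc:geneProduct fbc:id="%s" ',
                              'fbc:label="%s"/>'),
                       gid, esc(genes)),
               "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "    <listOfReactions>")
  for (j in seq_along(model@rxns)) {
    nz <- which(model@S[, j] != 0)
    coefs <- as.numeric(model@S[nz, j])
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(model@rxns[j]), tolower(model@lb[j] < 0),
      pid[[sprintf("%.17g", model@lb[j])]],
      pid[[sprintf("%.17g", model@ub[j])]]))
    reac <- nz[coefs < 0]; prod <- nz[coefs > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(model@mets[reac]),
                         format(-coefs[coefs < 0], digits = 17)),
                 "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf(paste0('          <speciesReference species="%s" ',
                                'stoichiometry="%s" constant="true"/>'),
                         esc(model@mets[prod]),
                         format(coefs[coefs > 0], digits = 17)),
                 "        </listOfProducts>")
    }
    if (nzchar(model@gpr[j])) {
      lines <- c(lines, "        <fbc:geneProductAssociation>",
                 gprXml(model@gprTree[[j]], 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
             '    <fbc:listOfObjectives fbc:activeObjective="obj">',
             '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
             "        <fbc:listOfFluxObjectives>")
  for (j in which(model@obj != 0)) {
    lines <- c(lines, sprintf(
      paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
             'fbc:coefficient="%s"/>'),
      esc(model@rxns[j]), format(model@obj[j], digits = 17)))
  }
  lines <- c(lines, "        </fbc:listOfFluxObjectives>",
             "      </fbc:objective>",
             "    </fbc:listOfObjectives>",
             "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Tabular inputs.

#' Read a gene x cell-line expression matrix
#'
#' CSV with the gene identifier in the first column and one column per
#' cell line; values are log2 TPM.
#'
#' @param path CSV file path.
#' @return numeric matrix with gene rownames and cell-line colnames.
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname readExpressionMatrix
#' @param expression numeric matrix with dimnames.
#' @export
writeExpressionMatrix <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.damagingClassesDefault <- c(
  "Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
  "Splice_Site", "Nonstop_Mutation", "De_novo_Start_OutOfFrame")

#' Read a MAF-like mutation table
#'
#' Accepts comma- or tab-separated tables with columns \code{Hugo_Symbol}
#' (or \code{Entrez_Gene_Id}), \code{Tumor_Sample_Barcode},
#' \code{Variant_Classification} and optionally \code{isDeleterious}.
#' Genomic coordinates are ignored; the analysis is gene-level.
#'
#' @param path file path.
#' @return data.frame of the table.
#' @export
readMutationMAF <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  geneCol <- intersect(c("Hugo_Symbol", "Entrez_Gene_Id"), colnames(df))
  need <- c("Tumor_Sample_Barcode", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (!length(geneCol) || length(miss))
    stop("MAF table lacks required columns: ",
         paste(c(if (!length(geneCol)) "Hugo_Symbol/Entrez_Gene_Id", miss),
               collapse = ", "), call. = FALSE)
  df
}

#' Build a MutationMatrix from a MAF-like table
#'
#' A variant is damaging if its \code{isDeleterious} flag is true; in the
#' absence of that column (or where it is NA) the variant classification
#' decides, via membership in \code{damagingClasses}.
#'
#' @param maf data.frame from \code{\link{readMutationMAF}}.
#' @param cellLines cell lines of the matrix (columns); default: all lines
#'   seen in the table.
#' @param genes genes of the matrix (rows); default: all genes seen.
#' @param damagingClasses variant classifications counted as damaging.
#' @param source label recorded in the provenance.
#' @return a \linkS4class{MutationMatrix}.
#' @export
mutationMatrixFromMAF <- function(maf, cellLines = NULL, genes = NULL,
                                  damagingClasses = .damagingClassesDefault,
                                  source = "maf") {
  geneCol <- if ("Hugo_Symbol" %in% colnames(maf)) "Hugo_Symbol"
             else "Entrez_Gene_Id"
  g <- as.character(maf[[geneCol]])
  cl <- as.character(maf$Tumor_Sample_Barcode)
  dam <- maf$Variant_Classification %in% damagingClasses
  if ("isDeleterious" %in% colnames(maf)) {
    flag <- maf$isDeleterious
    if (is.character(flag)) flag <- toupper(flag) %in% c("TRUE", "T", "1")
    dam <- ifelse(is.na(flag), dam, flag)
  }
  if (is.null(genes)) genes <- sort(unique(g))
  if (is.null(cellLines)) cellLines <- sort(unique(cl))
  calls <- matrix(FALSE, length(genes), length(cellLines),
                  dimnames = list(genes, cellLines))
  keep <- dam & g %in% genes & cl %in% cellLines
  if (any(keep)) calls[cbind(g[keep], cl[keep])] <- TRUE
  new("MutationMatrix", calls = calls,
      provenance = list(source = source,
                        damagingClasses = damagingClasses,
                        usedDeleteriousFlag =
                          "isDeleterious" %in% colnames(maf)))
}

#' @rdname accessors
#' @export
setMethod("mutationCalls", "MutationMatrix", function(object) object@calls)

setMethod("show", "MutationMatrix", function(object) {
  cat(sprintf("MutationMatrix: %d genes x %d cell lines, %d damaging calls\n",
              nrow(object@calls), ncol(object@calls), sum(object@calls)))
})

#' Read a dependency / viability matrix
#'
#' CSV with the entity (gene or compound) identifier in the first column
#' and one column per cell line; values are CRISPR gene effects, shRNA
#' ATARiS scores or drug-response log-fold-changes (lower = stronger
#' killing). Missing values are allowed.
#'
#' @param path CSV file path.
#' @param kind optional tag ("crispr", "shrna", "prism", ...) stored as an
#'   attribute.
#' @return numeric matrix with a \code{"kind"} attribute.
#' @export
readDependencyMatrix <- function(path, kind = NA_character_) {
  m <- readExpressionMatrix(path)
  attr(m, "kind") <- kind
  m
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> member genes);
#'   descriptions in attribute \code{"description"}.
#' @export
readGeneSetsGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (any(!lengths(sets)))
    stop("GMT file contains an empty gene set", call. = FALSE)
  attr(sets, "description") <- vapply(parts, `[`, "", 2L)
  sets
}

#' @rdname readGeneSetsGMT
#' @param sets named list of character vectors.
#' @param descriptions optional descriptions (recycled "" if missing).
#' @export
writeGeneSetsGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    ""), path)
  invisible(path)
}

#' Read a functionality-task table
#'
#' CSV or JSON with fields \code{id}, \code{inputs} (semicolon-separated
#' metabolite ids) and \code{target}.
#'
#' @param path file path (.csv or .json).
#' @return data.frame with columns id, inputs, target.
#' @export
readTasks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(j, function(t)
      data.frame(id = t$id,
                 inputs = paste(unlist(t$inputs), collapse = ";"),
                 target = t$target, stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "inputs", "target") %in% colnames(df)))
  df
}

#' Read a compound-to-target-gene map
#'
#' CSV with columns \code{compound_id}, \code{gene_id}; used to annotate
#' drug-perturbation results with the targeted gene.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readCompoundTargetMap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "gene_id") %in% colnames(df)))
  df
}
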