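# Model and table input/output.
#
# Two model dialects: the community JSON schema (ids, per-reaction
# metabolite stoichiometries, bounds, gene_reaction_rule) and SBML Level 3
# with the FBC package (flux bounds as parameters, GPRs as
# geneProductAssociation trees).  Regulons and interaction gold standards
# travel as TSV; pathway definitions as GMT.

#' Read a metabolic model
#'
#' @param path file path.
#' @param format "sbml", "json", or "auto" (by extension).
#' @return a \code{\link{metabolic_model}}.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(format, sbml = read_sbml(path), json = read_model_json(path))
}

#' Write a metabolic model
#'
#' @param model a \code{\link{metabolic_model}}.
#' @param path output file path.
#' @param format "sbml", "json", or "auto" (by extension).
#' @export
write_model <- function(model, path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml" else "json"
  }
  switch(format, sbml = write_sbml(model, path),
         json = write_model_json(model, path))
  invisible(path)
}

## ---- JSON dialect -------------------------------------------------------

read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$metabolites) || is.null(j$reactions))
    stop("malformed model JSON: missing 'metabolites' or 'reactions' in ", path)
  mets <- vapply(j$metabolites, function(m) as.character(m$id), character(1))
  formulas <- vapply(j$metabolites, function(m)
    if (!is.null(m$formula)) as.character(m$formula) else NA_character_,
    character(1))
  names(formulas) <- mets
  if (all(is.na(formulas))) formulas <- NULL
  nr <- length(j$reactions)
  rxns <- character(nr); lb <- ub <- numeric(nr); gpr <- character(nr)
  S <- matrix(0, length(mets), nr, dimnames = list(mets, NULL))
  biomass <- NA_character_
  for (k in seq_len(nr)) {
    rx <- j$reactions[[k]]
    if (is.null(rx$id)) stop("malformed model JSON: reaction ", k, " has no id")
    rxns[k] <- rx$id
    rev <- isTRUE(rx$reversible)
    if (is.null(rx$lower_bound) || is.null(rx$upper_bound)) {
      warning("reaction ", rx$id, ": missing bounds, defaulting to ",
              if (rev) "[-1000, 1000]" else "[0, 1000]")
      lb[k] <- if (rev) -FLUX_BOUND else 0
      ub[k] <- FLUX_BOUND
    } else {
      lb[k] <- as.numeric(rx$lower_bound); ub[k] <- as.numeric(rx$upper_bound)
    }
    gpr[k] <- if (!is.null(rx$gene_reaction_rule)) rx$gene_reaction_rule else ""
    for (met in names(rx$metabolites)) {
      if (!met %in% mets)
        stop("malformed model JSON: reaction ", rx$id,
             " references unknown metabolite ", met)
      S[met, k] <- as.numeric(rx$metabolites[[met]])
    }
    oc <- rx$objective_coefficient
    if (!is.null(oc) && as.numeric(oc) != 0) biomass <- rx$id
  }
  metabolic_model(mets, rxns, S, lb, ub, gpr, biomass_id = biomass,
                  formulas = formulas)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_along(model$mets), function(i) {
    m <- list(id = model$mets[i])
    if (!is.null(model$formulas) && !is.na(model$formulas[model$mets[i]]))
      m$formula <- unname(model$formulas[model$mets[i]])
    m
  })
  rxns <- lapply(seq_along(model$rxns), function(k) {
    nz <- which(model$S[, k] != 0)
    r <- list(id = model$rxns[k],
              metabolites = as.list(stats::setNames(model$S[nz, k],
                                                    model$mets[nz])),
              lower_bound = model$lb[k], upper_bound = model$ub[k],
              gene_reaction_rule = model$gpr[k])
    if (!is.na(model$biomass_id) && model$rxns[k] == model$biomass_id)
      r$objective_coefficient <- 1
    r
  })
  genes <- lapply(model_genes(model), function(g) list(id = g))
  jsonlite::write_json(list(id = "model", metabolites = mets,
                            reactions = rxns, genes = genes),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## ---- SBML Level 3 + FBC -------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# attribute lookup tolerant of namespace prefixes
xattr <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- match(name, sub("^.*:", "", names(at)))
  if (is.na(hit)) NA_character_ else unname(at[hit])
}

strip_prefix <- function(ids, prefix) {
  hit <- startsWith(ids, prefix)
  ids[hit] <- substring(ids[hit], nchar(prefix) + 1L)
  ids
}

read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SBML in ", path, ": ", conditionMessage(e)))
  find <- function(node, what)
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  sp <- find(doc, "species")
  if (!length(sp)) stop("malformed SBML: no species elements in ", path)
  met_sid <- vapply(sp, xattr, character(1), "id")
  mets <- strip_prefix(met_sid, "M_")
  formulas <- vapply(sp, xattr, character(1), "chemicalFormula")
  names(formulas) <- mets
  if (all(is.na(formulas))) formulas <- NULL
  # bound parameters
  pars <- find(doc, "parameter")
  pval <- stats::setNames(as.numeric(vapply(pars, xattr, character(1), "value")),
                          vapply(pars, xattr, character(1), "id"))
  # gene products: id -> label
  gps <- find(doc, "geneProduct")
  glabel <- stats::setNames(vapply(gps, xattr, character(1), "label"),
                            vapply(gps, xattr, character(1), "id"))
  rx_nodes <- find(doc, "reaction")
  if (!length(rx_nodes)) stop("malformed SBML: no reaction elements in ", path)
  nr <- length(rx_nodes)
  rxn_sid <- vapply(rx_nodes, xattr, character(1), "id")
  rxns <- strip_prefix(rxn_sid, "R_")
  S <- matrix(0, length(mets), nr, dimnames = list(met_sid, NULL))
  lb <- ub <- numeric(nr); gpr <- character(nr)
  for (k in seq_len(nr)) {
    node <- rx_nodes[[k]]
    for (ref in xml2::xml_find_all(node,
        "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']")) {
      sid <- xattr(ref, "species")
      if (!sid %in% met_sid)
        stop("malformed SBML: reaction ", rxn_sid[k],
             " references unknown species ", sid)
      S[sid, k] <- S[sid, k] - as.numeric(xattr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node,
        "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']")) {
      sid <- xattr(ref, "species")
      if (!sid %in% met_sid)
        stop("malformed SBML: reaction ", rxn_sid[k],
             " references unknown species ", sid)
      S[sid, k] <- S[sid, k] + as.numeric(xattr(ref, "stoichiometry"))
    }
    lbid <- xattr(node, "lowerFluxBound"); ubid <- xattr(node, "upperFluxBound")
    rev <- identical(xattr(node, "reversible"), "true")
    if (is.na(lbid) || is.na(ubid) || is.na(pval[lbid]) || is.na(pval[ubid])) {
      warning("reaction ", rxns[k], ": missing flux bounds, defaulting to ",
              if (rev) "[-1000, 1000]" else "[0, 1000]")
      lb[k] <- if (rev) -FLUX_BOUND else 0; ub[k] <- FLUX_BOUND
    } else {
      lb[k] <- pval[lbid]; ub[k] <- pval[ubid]
    }
    gpa <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']")
    if (!inherits(gpa, "xml_missing")) {
      child <- xml2::xml_find_first(gpa, "./*")
      gpr[k] <- gpr_to_string(sbml_gpa_tree(child, glabel))
    }
  }
  rownames(S) <- mets
  biomass <- NA_character_
  fo <- find(doc, "fluxObjective")
  if (length(fo)) {
    rid <- xattr(fo[[1]], "reaction")
    biomass <- strip_prefix(rid, "R_")
  }
  metabolic_model(mets, rxns, S, lb, ub, gpr, biomass_id = biomass,
                  formulas = formulas)
}

sbml_gpa_tree <- function(node, glabel) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xattr(node, "geneProduct")
    lab <- glabel[gid]
    if (is.na(lab)) lab <- strip_prefix(gid, "G_")
    return(list(op = "gene", gene = unname(lab)))
  }
  if (!nm %in% c("and", "or"))
    stop("malformed SBML gene association node: ", nm)
  list(op = nm,
       args = lapply(xml2::xml_find_all(node, "./*"), sbml_gpa_tree, glabel))
}

sbml_sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "true")
  cmp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(cmp, "compartment", id = "c", constant = "true")
  msid <- paste0("M_", sbml_sanitize(model$mets))
  rsid <- paste0("R_", sbml_sanitize(model$rxns))
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_along(model$mets)) {
    at <- list(id = msid[i], name = model$mets[i], compartment = "c",
               hasOnlySubstanceUnits = "false", boundaryCondition = "false",
               constant = "false")
    if (!is.null(model$formulas) && !is.na(model$formulas[model$mets[i]]))
      at[["fbc:chemicalFormula"]] <- unname(model$formulas[model$mets[i]])
    do.call(xml2::xml_add_child, c(list(los, "species"), at))
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (k in seq_along(model$rxns)) {
    xml2::xml_add_child(lop, "parameter", id = paste0("lb_", rsid[k]),
                        value = format(model$lb[k]), constant = "true")
    xml2::xml_add_child(lop, "parameter", id = paste0("ub_", rsid[k]),
                        value = format(model$ub[k]), constant = "true")
  }
  genes <- model_genes(model)
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_along(model$rxns)) {
    rx <- xml2::xml_add_child(lor, "reaction", id = rsid[k],
      name = model$rxns[k],
      reversible = if (model$lb[k] < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = paste0("lb_", rsid[k]),
      "fbc:upperFluxBound" = paste0("ub_", rsid[k]))
    nz <- which(model$S[, k] != 0)
    rea <- nz[model$S[nz, k] < 0]; pro <- nz[model$S[nz, k] > 0]
    if (length(rea)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in rea)
        xml2::xml_add_child(lr, "speciesReference", species = msid[i],
                            stoichiometry = format(-model$S[i, k]),
                            constant = "true")
    }
    if (length(pro)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in pro)
        xml2::xml_add_child(lp, "speciesReference", species = msid[i],
                            stoichiometry = format(model$S[i, k]),
                            constant = "true")
    }
    tree <- parse_gpr(model$gpr[k])
    if (!is.null(tree)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      sbml_write_gpa(gpa, tree)
    }
  }
  if (length(genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes)
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", sbml_sanitize(g)),
                          "fbc:label" = g)
  }
  if (!is.na(model$biomass_id)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sbml_sanitize(model$biomass_id)),
      "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

sbml_write_gpa <- function(parent, tree) {
  if (tree$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", sbml_sanitize(tree$gene)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", tree$op))
    for (a in tree$args) sbml_write_gpa(node, a)
  }
  invisible(parent)
}

## ---- tables -------------------------------------------------------------

#' Read a regulon table
#'
#' TSV with columns \code{tf} and \code{gene}; one row per regulatory
#' interaction.
#' @param path file path.
#' @return named list (class \code{regulon}) mapping TF ids to gene sets.
#' @export
read_regulon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "gene") %in% names(df)))
    stop("regulon TSV must have columns 'tf' and 'gene'")
  structure(lapply(split(df$gene, df$tf), unique), class = "regulon")
}

#' Write a regulon table
#' @param regulon named list of gene sets.
#' @param path output file path.
#' @export
write_regulon <- function(regulon, path) {
  df <- data.frame(tf = rep(names(regulon), lengths(regulon)),
                   gene = unlist(regulon, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction-pair table
#'
#' TSV with columns \code{id_a} and \code{id_b}; order within a pair is not
#' meaningful.
#' @param path file path.
#' @return data.frame with columns \code{id_a}, \code{id_b}.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b") %in% names(df)))
    stop("interaction TSV must have columns 'id_a' and 'id_b'")
  df[, c("id_a", "id_b")]
}

#' Read GMT pathway definitions
#' @param path GMT file (pathway id, description, then member ids,
#'   tab-separated).
#' @return named list of member-id vectors; descriptions in attribute
#'   \code{description}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 3L]
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  attr(out, "description") <- vapply(parts, `[[`, character(1), 2L)
  out
}

#' Write GMT pathway definitions
#' @param sets named list of member-id vectors.
#' @param path output file path.
#' @param description optional per-set description vector.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pathway matrix as TSV and JSON
#'
#' TSV rows are reactions and columns pathway identifiers; the JSON form
#' lists each pathway as a reaction-to-coefficient map.
#'
#' @param pm a \code{\link{pathway_matrix}}.
#' @param tsv,json output paths (either may be \code{NULL} to skip).
#' @export
write_pathways <- function(pm, tsv = NULL, json = NULL) {
  M <- pm$P
  if (!is.null(tsv)) {
    df <- data.frame(rxn = rownames(M), M, check.names = FALSE)
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    lst <- lapply(seq_len(ncol(M)), function(j) {
      nz <- which(M[, j] != 0)
      as.list(stats::setNames(M[nz, j], rownames(M)[nz]))
    })
    names(lst) <- colnames(M)
    jsonlite::write_json(lst, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(pm)
}

#' Read a pathway matrix from TSV
#' @param path TSV written by \code{\link{write_pathways}}.
#' @param provenance provenance label to attach.
#' @return a \code{\link{pathway_matrix}}.
#' @export
read_pathways <- function(path, provenance = "minspan") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df[[1]]
  pathway_matrix(M, provenance)
}
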