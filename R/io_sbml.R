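# SBML Level 3 + FBC v2 input/output.
#
# Scope: the subset of SBML that constraint-based models use — species,
# reactions with reactant/product stoichiometry, flux-bound parameters
# referenced through fbc attributes, gene-product associations, and the
# active fbc objective. Ids follow the COBRA convention (M_/R_/G_ prefixes,
# stripped on read, added on write). GPR strings are additionally written
# verbatim into a legacy GENE_ASSOCIATION notes paragraph so that a
# write/read cycle preserves them byte-for-byte; on read the notes string is
# preferred, the fbc association tree is the fallback, and a notes-only file
# triggers a warning.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

strip_prefix <- function(x, prefix) {
  sub(paste0("^", prefix, "_"), "", x)
}

sbml_safe_id <- function(x, what) {
  bad <- grepl("[^A-Za-z0-9_]", x)
  if (any(bad))
    stop("cannot write SBML: ", what, " id(s) contain characters outside ",
         "[A-Za-z0-9_]: ", paste(x[bad], collapse = ", "),
         "; use COBRA-JSON for these ids", call. = FALSE)
  x
}

num_attr <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "INF" else "-INF")
  sprintf("%.17g", x)
}

parse_sbml_number <- function(x) {
  if (x %in% c("INF", "inf", "Inf")) return(Inf)
  if (x %in% c("-INF", "-inf", "-Inf")) return(-Inf)
  as.numeric(x)
}

#' Read an SBML Level 3 (+FBC) model
#'
#' Flux bounds and the objective are taken from the FBC package attributes;
#' GPR rules come from a `GENE_ASSOCIATION` notes paragraph when present
#' (preserved verbatim), otherwise they are rendered from the
#' `fbc:geneProductAssociation` tree. A file carrying GPRs only in notes and
#' no FBC association raises a warning, as does a reaction without FBC bound
#' attributes (bounds then default by reversibility to (-1000, 1000) or
#' (0, 1000)).
#'
#' @param path path to an `.xml`/`.sbml` file.
#' @return a [gem].
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not parseable as SBML: ",
                                           conditionMessage(e), call. = FALSE))
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    stop("SBML format error: no <model> element", call. = FALSE)
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- "model"

  # flux-bound parameters
  params <- xml2::xml_find_all(model,
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_vals <- stats::setNames(
    vapply(xml2::xml_attr(params, "value"), parse_sbml_number, numeric(1)),
    xml2::xml_attr(params, "id"))

  # gene products: map fbc id -> label (verbatim gene name)
  gps <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfGeneProducts']/*[local-name()='geneProduct']")
  gp_label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           strip_prefix(xml2::xml_attr(gps, "id"), "G"),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  species <- xml2::xml_find_all(model,
    "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_ids <- xml2::xml_attr(species, "id")
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  met_ids <- strip_prefix(sp_ids[!boundary], "M")
  sp_map <- stats::setNames(strip_prefix(sp_ids, "M"), sp_ids)

  rx_nodes <- xml2::xml_find_all(model,
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L)
    stop("SBML structural error: model has no reactions", call. = FALSE)

  notes_only_gpr <- FALSE
  missing_fbc_bounds <- FALSE

  rxns <- lapply(rx_nodes, function(node) {
    rid_raw <- xml2::xml_attr(node, "id")
    if (is.na(rid_raw))
      stop("SBML format error: reaction without id", call. = FALSE)
    rid <- strip_prefix(rid_raw, "R")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")

    side <- function(list_name, sign) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", list_name))
      if (length(refs) == 0L) return(numeric(0))
      sp <- xml2::xml_attr(refs, "species")
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      keep <- !(sp %in% sp_ids[boundary])
      stats::setNames(sign * coef[keep],
                      ifelse(is.na(sp_map[sp[keep]]),
                             strip_prefix(sp[keep], "M"), sp_map[sp[keep]]))
    }
    st <- c(side("listOfReactants", -1), side("listOfProducts", +1))
    if (length(st) == 0L)
      stop("SBML structural error: reaction '", rid,
           "' has no stoichiometry", call. = FALSE)
    st <- tapply(st, names(st), sum)  # merge duplicated species refs
    st <- stats::setNames(as.numeric(st), names(st))

    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref)) {
      missing_fbc_bounds <<- TRUE
      lb <- if (rev) -1000 else 0
      ub <- 1000
    } else {
      lb <- par_vals[[lb_ref]]
      ub <- par_vals[[ub_ref]]
      if (is.null(lb) || is.null(ub))
        stop("SBML format error: reaction '", rid,
             "' references undeclared bound parameter", call. = FALSE)
    }

    # GPR: verbatim notes string preferred, fbc association as fallback
    notes_p <- xml2::xml_find_all(node,
      ".//*[local-name()='notes']//*[local-name()='p']")
    gpr <- NA_character_
    for (p in notes_p) {
      txt <- xml2::xml_text(p)
      if (grepl("^\\s*GENE_ASSOCIATION:", txt)) {
        gpr <- trimws(sub("^\\s*GENE_ASSOCIATION:", "", txt))
        if (!nzchar(gpr)) gpr <- NA_character_
        break
      }
    }
    assoc <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']")
    if (is.na(gpr) && !inherits(assoc, "xml_missing")) {
      kids <- xml2::xml_find_all(assoc, "./*")
      if (length(kids)) gpr <- render_fbc_association(kids[[1]], gp_label)
    } else if (!is.na(gpr) && inherits(assoc, "xml_missing")) {
      notes_only_gpr <<- TRUE
    }

    list(id = rid, lower_bound = lb, upper_bound = ub, gpr = gpr,
         objective_coefficient = 0, stoich = st)
  })

  if (notes_only_gpr)
    warning("GPR rules read from legacy GENE_ASSOCIATION notes ",
            "(no fbc:geneProductAssociation present)", call. = FALSE)
  if (missing_fbc_bounds)
    warning("reaction(s) without fbc flux-bound attributes; bounds ",
            "defaulted by reversibility", call. = FALSE)

  # active fbc objective
  obj_nodes <- xml2::xml_find_all(model, paste0(
    ".//*[local-name()='listOfObjectives']/*[local-name()='objective']",
    "/*[local-name()='listOfFluxObjectives']/*[local-name()='fluxObjective']"))
  if (length(obj_nodes)) {
    orids <- strip_prefix(xml2::xml_attr(obj_nodes, "reaction"), "R")
    ocoef <- as.numeric(xml2::xml_attr(obj_nodes, "coefficient"))
    rids <- vapply(rxns, `[[`, character(1), "id")
    for (k in seq_along(orids)) {
      hit <- match(orids[k], rids)
      if (!is.na(hit)) rxns[[hit]]$objective_coefficient <- ocoef[k]
    }
  }

  mets <- if (length(met_ids)) met_ids else NULL
  gem(rxns, metabolites = mets, model_id = strip_prefix(model_id, "M"))
}

# Render an fbc association subtree back into a GPR string.
render_fbc_association <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- gp_label[[ref]]
    return(if (is.null(lab) || is.na(lab)) strip_prefix(ref, "G") else lab)
  }
  kids <- xml2::xml_find_all(node, "./*")
  parts <- vapply(kids, render_fbc_association, character(1),
                  gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a model as SBML Level 3 + FBC v2
#'
#' Bounds become shared flux-bound parameters, the objective an fbc
#' `maximize` objective, and each GPR both an `fbc:geneProductAssociation`
#' tree and a verbatim `GENE_ASSOCIATION` notes paragraph (so the exact rule
#' string survives a round trip).
#'
#' @param g a [gem].
#' @param path output path.
#' @return `path`, invisibly. Warns when the objective is empty.
#' @export
write_sbml_model <- function(g, path) {
  validate_gem(g)
  if (all(g$reactions$objective_coefficient == 0))
    warning("writing model with empty objective", call. = FALSE)
  sbml_safe_id(g$metabolites, "metabolite")
  sbml_safe_id(g$reactions$id, "reaction")

  gprs <- g$reactions$gpr
  parsed <- lapply(gprs, function(r) if (is.na(r)) NULL else parse_gpr(r))
  genes <- sort(unique(unlist(lapply(parsed, function(p)
    if (is.null(p)) character(0) else gpr_genes(p)))))
  gene_xmlid <- stats::setNames(
    paste0("G_", gsub("[^A-Za-z0-9_]", "_", genes)), genes)
  if (anyDuplicated(gene_xmlid))
    stop("gene ids collide after SBML sanitisation", call. = FALSE)

  bounds <- sort(unique(c(g$reactions$lower_bound, g$reactions$upper_bound)))
  bound_id <- stats::setNames(paste0("fb_", seq_along(bounds)),
                              vapply(bounds, num_attr, character(1)))
  bid <- function(x) bound_id[[num_attr(x)]]

  doc <- xml2::xml_new_root(
    "sbml",
    "xmlns" = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  model <- xml2::xml_add_child(doc, "model", id = g$model_id,
                               "fbc:strict" = "true")

  comps <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "c", constant = "true")

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (m in g$metabolites)
    xml2::xml_add_child(los, "species", id = paste0("M_", m), name = m,
                        compartment = "c", hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")

  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (k in seq_along(bounds))
    xml2::xml_add_child(lop, "parameter", id = paste0("fb_", k),
                        value = num_attr(bounds[k]), constant = "true")

  if (length(genes)) {
    logp <- xml2::xml_add_child(model, "fbc:listOfGeneProducts")
    for (gn in genes)
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = gene_xmlid[[gn]], "fbc:label" = gn)
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(g$reactions))) {
    node <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", g$reactions$id[i]),
      reversible = if (g$reactions$lower_bound[i] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid(g$reactions$lower_bound[i]),
      "fbc:upperFluxBound" = bid(g$reactions$upper_bound[i]))
    if (!is.na(gprs[i])) {
      notes <- xml2::xml_add_child(node, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p",
                          paste0("GENE_ASSOCIATION: ", gprs[i]))
    }
    st <- stats::setNames(as.numeric(g$S[, i]), g$metabolites)
    st <- st[st != 0]
    reactants <- st[st < 0]
    products <- st[st > 0]
    if (length(reactants)) {
      lr <- xml2::xml_add_child(node, "listOfReactants")
      for (m in names(reactants))
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = num_attr(-reactants[[m]]),
                            constant = "true")
    }
    if (length(products)) {
      lp <- xml2::xml_add_child(node, "listOfProducts")
      for (m in names(products))
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", m),
                            stoichiometry = num_attr(products[[m]]),
                            constant = "true")
    }
    if (!is.null(parsed[[i]])) {
      assoc <- xml2::xml_add_child(node, "fbc:geneProductAssociation")
      add_fbc_association(assoc, parsed[[i]], gene_xmlid)
    }
  }

  obj_idx <- which(g$reactions$objective_coefficient != 0)
  if (length(obj_idx)) {
    loo <- xml2::xml_add_child(model, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    obj <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                               "fbc:type" = "maximize")
    lofo <- xml2::xml_add_child(obj, "fbc:listOfFluxObjectives")
    for (i in obj_idx)
      xml2::xml_add_child(
        lofo, "fbc:fluxObjective",
        "fbc:reaction" = paste0("R_", g$reactions$id[i]),
        "fbc:coefficient" = num_attr(g$reactions$objective_coefficient[i]))
  }

  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop("cannot write to ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

add_fbc_association <- function(parent, expr, gene_xmlid) {
  if (expr$kind == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = gene_xmlid[[expr$gene]])
  } else {
    node <- xml2::xml_add_child(parent,
                                if (expr$kind == "and") "fbc:and" else "fbc:or")
    for (ch in expr$children) add_fbc_association(node, ch, gene_xmlid)
  }
  invisible(parent)
}
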