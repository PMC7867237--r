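#' Read a COBRA-JSON model
#'
#' Parses the community JSON schema used by COBRApy (`id`, `metabolites`,
#' `reactions` with `metabolites` stoichiometry maps, bounds,
#' `gene_reaction_rule`, `objective_coefficient`).
#'
#' @param path path to a `.json` model file.
#' @return a [gem].
#' @export
read_json_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("not parseable as COBRA-JSON: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(doc$reactions))
    stop("COBRA-JSON structural error: no 'reactions' array", call. = FALSE)
  mets <- vapply(doc$metabolites, function(m) as.character(m$id), character(1))
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id))
      stop("COBRA-JSON format error: reaction without 'id'", call. = FALSE)
    if (is.null(r$metabolites) || length(r$metabolites) == 0L)
      stop("COBRA-JSON structural error: reaction '", r$id,
           "' has no stoichiometry", call. = FALSE)
    st <- unlist(r$metabolites)
    list(
      id = r$id,
      lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
      upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
      gpr = if (is.null(r$gene_reaction_rule) ||
                !nzchar(r$gene_reaction_rule)) NA_character_
            else r$gene_reaction_rule,
      objective_coefficient = if (is.null(r$objective_coefficient)) 0
                              else r$objective_coefficient,
      stoich = st
    )
  })
  gem(rxns, metabolites = if (length(mets)) mets else NULL,
      model_id = if (is.null(doc$id)) "model" else doc$id)
}

#' Write a model as COBRA-JSON
#'
#' @param g a [gem].
#' @param path output path.
#' @return `path`, invisibly. Warns (and still writes) when the objective is
#'   empty.
#' @export
write_json_model <- function(g, path) {
  validate_gem(g)
  if (all(g$reactions$objective_coefficient == 0))
    warning("writing model with empty objective", call. = FALSE)
  genes <- sort(unique(unlist(lapply(
    g$reactions$gpr[!is.na(g$reactions$gpr)],
    function(r) gpr_genes(parse_gpr(r))
  ))))
  doc <- list(
    id = g$model_id,
    metabolites = lapply(g$metabolites, function(m)
      list(id = m, name = m, compartment = "c")),
    reactions = lapply(seq_len(nrow(g$reactions)), function(i) {
      st <- stats::setNames(as.numeric(g$S[, i]), g$metabolites)
      st <- st[st != 0]
      r <- list(
        id = g$reactions$id[i],
        name = g$reactions$id[i],
        metabolites = as.list(st),
        lower_bound = g$reactions$lower_bound[i],
        upper_bound = g$reactions$upper_bound[i],
        gene_reaction_rule = if (is.na(g$reactions$gpr[i])) ""
                             else g$reactions$gpr[i],
        objective_coefficient = g$reactions$objective_coefficient[i]
      )
      r
    }),
    genes = lapply(genes, function(x) list(id = x, name = x)),
    compartments = list(c = "cytosol"),
    version = "1"
  )
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), con)
  invisible(path)
}
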