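#' Construct a genome-scale metabolic model (GEM)
#'
#' A `gem` holds the stoichiometric network: a sparse stoichiometry matrix
#' `S` (metabolites x reactions), per-reaction flux bounds, optional
#' gene-protein-reaction (GPR) rule strings, and the objective coefficient
#' vector `c`. Models are value objects: every operation that modifies bounds
#' returns a new copy, so condition-specific variants never alias.
#'
#' @param reactions a list of reaction descriptions; each element is a list
#'   with fields `id` (character), `lower_bound`, `upper_bound` (numeric),
#'   `stoich` (named numeric: metabolite id -> coefficient), and optionally
#'   `gpr` (character GPR rule or `NA`) and `objective_coefficient`
#'   (numeric, default 0).
#' @param metabolites optional character vector of metabolite ids fixing the
#'   row order of `S`; defaults to order of first appearance in `stoich`.
#' @param model_id model identifier string.
#' @return an object of class `gem` with components `model_id`,
#'   `metabolites` (character), `reactions` (data.frame with columns `id`,
#'   `lower_bound`, `upper_bound`, `gpr`, `objective_coefficient`), and `S`
#'   (a `dgCMatrix`, metabolites in rows, reactions in columns).
#' @examples
#' g <- gem(list(
#'   list(id = "EX_a", lower_bound = -5, upper_bound = 0,
#'        stoich = c(a = -1)),
#'   list(id = "R1", lower_bound = 0, upper_bound = 1000,
#'        stoich = c(a = -1, b = 1), gpr = "gA and gB"),
#'   list(id = "BIOMASS_toy", lower_bound = 0, upper_bound = 1000,
#'        stoich = c(b = -1), objective_coefficient = 1)
#' ), model_id = "toy")
#' g
#' @export
gem <- function(reactions, metabolites = NULL, model_id = "model") {
  if (!is.list(reactions) || length(reactions) == 0L)
    stop("`reactions` must be a non-empty list", call. = FALSE)
  ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  lb <- vapply(reactions, function(r) as.numeric(r$lower_bound), numeric(1))
  ub <- vapply(reactions, function(r) as.numeric(r$upper_bound), numeric(1))
  gpr <- vapply(reactions, function(r) {
    g <- r$gpr
    if (is.null(g) || length(g) == 0L || is.na(g) || !nzchar(trimws(g))) NA_character_
    else as.character(g)
  }, character(1))
  obj <- vapply(reactions, function(r) {
    o <- r$objective_coefficient
    if (is.null(o)) 0 else as.numeric(o)
  }, numeric(1))

  stoichs <- lapply(reactions, function(r) {
    s <- r$stoich
    if (is.null(s)) s <- numeric(0)
    s[s != 0]
  })
  if (is.null(metabolites))
    metabolites <- unique(unlist(lapply(stoichs, names), use.names = FALSE))
  metabolites <- as.character(metabolites)

  i <- unlist(lapply(stoichs, function(s) match(names(s), metabolites)),
              use.names = FALSE)
  j <- rep(seq_along(stoichs), lengths(stoichs))
  x <- unlist(stoichs, use.names = FALSE)
  if (anyNA(i))
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(unique(unlist(lapply(stoichs, names))[is.na(match(
           unlist(lapply(stoichs, names)), metabolites))]), collapse = ", "),
         call. = FALSE)
  S <- Matrix::sparseMatrix(
    i = i, j = j, x = as.numeric(x),
    dims = c(length(metabolites), length(ids)),
    dimnames = list(metabolites, ids)
  )

  g <- structure(
    list(
      model_id = as.character(model_id),
      metabolites = metabolites,
      reactions = data.frame(
        id = ids, lower_bound = lb, upper_bound = ub, gpr = gpr,
        objective_coefficient = obj, stringsAsFactors = FALSE
      ),
      S = S
    ),
    class = "gem"
  )
  validate_gem(g)
  g
}

#' Validate a GEM against its structural invariants
#'
#' Checks id uniqueness, bound ordering (`lower_bound <= upper_bound`), and
#' consistency between `S` and the declared metabolites/reactions. Called by
#' the constructor and by every reader; integration operations revalidate
#' their outputs.
#'
#' @param g a `gem`.
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_gem <- function(g) {
  if (!inherits(g, "gem")) stop("not a gem object", call. = FALSE)
  rx <- g$reactions
  if (anyDuplicated(rx$id))
    stop("duplicate reaction id(s): ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(g$metabolites))
    stop("duplicate metabolite id(s): ",
         paste(unique(g$metabolites[duplicated(g$metabolites)]), collapse = ", "),
         call. = FALSE)
  bad <- which(rx$lower_bound > rx$upper_bound)
  if (length(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rx$id[bad], collapse = ", "), call. = FALSE)
  if (!all(dim(g$S) == c(length(g$metabolites), nrow(rx))))
    stop("S dimensions do not match metabolite/reaction counts", call. = FALSE)
  if (!identical(rownames(g$S), g$metabolites) ||
      !identical(colnames(g$S), rx$id))
    stop("S dimnames do not match declared metabolite/reaction ids",
         call. = FALSE)
  if (any(!is.finite(rx$lower_bound) & rx$lower_bound > -Inf) ||
      any(!is.finite(rx$upper_bound) & rx$upper_bound < Inf))
    stop("NaN flux bound(s)", call. = FALSE)
  invisible(g)
}

#' @export
print.gem <- function(x, ...) {
  rep <- model_report(x)
  cat(sprintf("<gem> %s: %d reactions, %d metabolites\n",
              x$model_id, rep$n_reactions, rep$n_metabolites))
  cat(sprintf("  GPR-bearing: %d | exchange: %d | biomass: %s\n",
              rep$n_gpr_reactions, rep$n_exchange,
              ifelse(is.na(rep$biomass_id), "<none>", rep$biomass_id)))
  for (w in rep$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Logical vector flagging exchange (boundary) reactions
#'
#' A reaction is an exchange iff it touches exactly one metabolite with
#' nonzero coefficient (the COBRA boundary convention; compartment tags are
#' ignored). Negative flux through an exchange is uptake, positive is
#' secretion.
#'
#' @param g a `gem`.
#' @return logical vector along `g$reactions`.
#' @export
is_exchange_reaction <- function(g) {
  validate_gem(g)
  Matrix::colSums(g$S != 0) == 1L
}

#' Exchange reaction ids of a model
#'
#' @param g a `gem`.
#' @return character vector of exchange reaction ids in model order (possibly
#'   empty).
#' @export
exchange_reactions <- function(g) {
  g$reactions$id[is_exchange_reaction(g)]
}

#' Locate the biomass (objective) reaction
#'
#' Returns the unique reaction with nonzero objective coefficient. When the
#' objective is empty, falls back to matching reaction ids against `hint`
#' (case-insensitive substring, default `"biomass"`). Zero or multiple
#' candidates raise an error listing them.
#'
#' @param g a `gem`.
#' @param hint substring used for the id fallback.
#' @return a single reaction id.
#' @export
find_biomass_reaction <- function(g, hint = "biomass") {
  validate_gem(g)
  obj <- which(g$reactions$objective_coefficient != 0)
  if (length(obj) == 1L) return(g$reactions$id[obj])
  if (length(obj) > 1L)
    stop("multiple reactions carry nonzero objective coefficients: ",
         paste(g$reactions$id[obj], collapse = ", "), call. = FALSE)
  cand <- grep(hint, g$reactions$id, ignore.case = TRUE, fixed = FALSE)
  if (length(cand) == 1L) return(g$reactions$id[cand])
  if (length(cand) == 0L)
    stop("no objective set and no reaction id matches hint '", hint, "'",
         call. = FALSE)
  stop("no objective set and multiple reaction ids match hint '", hint,
       "': ", paste(g$reactions$id[cand], collapse = ", "), call. = FALSE)
}

#' Structural summary of a model
#'
#' @param g a `gem`.
#' @return a list with `n_reactions`, `n_metabolites`, `n_gpr_reactions`,
#'   `n_exchange`, `biomass_id` (`NA` if undeterminable) and `warnings`.
#' @export
model_report <- function(g) {
  validate_gem(g)
  warnings <- character(0)
  biomass <- tryCatch(find_biomass_reaction(g),
                      error = function(e) {
                        warnings <<- c(warnings, conditionMessage(e))
                        NA_character_
                      })
  if (all(g$reactions$objective_coefficient == 0))
    warnings <- c(warnings, "model has an empty objective")
  list(
    n_reactions = nrow(g$reactions),
    n_metabolites = length(g$metabolites),
    n_gpr_reactions = sum(!is.na(g$reactions$gpr)),
    n_exchange = sum(is_exchange_reaction(g)),
    biomass_id = biomass,
    warnings = unique(warnings)
  )
}

# Internal: return a copy of g with new bounds for the given reaction indices.
set_bounds <- function(g, idx, lower = NULL, upper = NULL) {
  if (!is.null(lower)) g$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) g$reactions$upper_bound[idx] <- upper
  validate_gem(g)
  g
}
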