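#' Parse a gene-protein-reaction (GPR) rule string
#'
#' GPR rules link genes to reactions: `AND` joins subunits of an enzyme
#' complex (all required), `OR` joins isozymes (any sufficient). The grammar
#' accepts `and`/`or` case-insensitively as well as `&&`, `||`, `&`, `|`,
#' parentheses, and gene-id tokens. Without parentheses `AND` binds tighter
#' than `OR`. Same-operator chains are flattened, so every `AND`/`OR` node
#' carries at least two children and a bare gene parses to a leaf.
#'
#' @param rule a single non-empty GPR string.
#' @return a `gpr_expression`: nested lists with `kind` one of `"gene"`
#'   (field `gene`), `"and"`, `"or"` (field `children`).
#' @examples
#' parse_gpr("(gA and gB) or gC")
#' @export
parse_gpr <- function(rule) {
  if (!is.character(rule) || length(rule) != 1L || is.na(rule) ||
      !nzchar(trimws(rule)))
    stop("GPR rule must be a single non-empty string", call. = FALSE)
  toks <- gpr_tokenize(rule)
  st <- list(pos = 1L, toks = toks, rule = rule)
  res <- gpr_parse_or(st)
  st <- res$state
  if (st$pos <= length(st$toks))
    gpr_error(st, "unexpected token")
  structure(res$node, class = "gpr_expression")
}

gpr_tokenize <- function(rule) {
  toks <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, offset = i)
      i <- i + 1L
      next
    }
    if (ch %in% c("&", "|")) {
      two <- substr(rule, i, min(i + 1L, n))
      op <- if (substr(two, 2, 2) == ch) two else ch
      toks[[length(toks) + 1L]] <- list(
        type = if (ch == "&") "AND" else "OR", text = op, offset = i)
      i <- i + nchar(op)
      next
    }
    m <- regmatches(substr(rule, i, n),
                    regexpr("^[^()&|[:space:]]+", substr(rule, i, n)))
    if (length(m) == 0L)
      stop(sprintf("GPR parse error at character %d: unexpected '%s'", i, ch),
           call. = FALSE)
    type <- if (tolower(m) == "and") "AND"
            else if (tolower(m) == "or") "OR"
            else "GENE"
    toks[[length(toks) + 1L]] <- list(type = type, text = m, offset = i)
    i <- i + nchar(m)
  }
  toks
}

gpr_error <- function(st, msg) {
  off <- if (st$pos <= length(st$toks)) st$toks[[st$pos]]$offset
         else nchar(st$rule) + 1L
  stop(sprintf("GPR parse error at character %d: %s in '%s'", off, msg,
               st$rule), call. = FALSE)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NULL else st$toks[[st$pos]]
}

# or-expr := and-expr (OR and-expr)*
gpr_parse_or <- function(st) {
  res <- gpr_parse_and(st)
  st <- res$state
  children <- list(res$node)
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "OR") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_and(st)
    st <- res$state
    children[[length(children) + 1L]] <- res$node
  }
  node <- if (length(children) == 1L) children[[1L]]
          else list(kind = "or", children = gpr_flatten(children, "or"))
  list(node = node, state = st)
}

# and-expr := factor (AND factor)*
gpr_parse_and <- function(st) {
  res <- gpr_parse_factor(st)
  st <- res$state
  children <- list(res$node)
  while (!is.null(tk <- gpr_peek(st)) && tk$type == "AND") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_factor(st)
    st <- res$state
    children[[length(children) + 1L]] <- res$node
  }
  node <- if (length(children) == 1L) children[[1L]]
          else list(kind = "and", children = gpr_flatten(children, "and"))
  list(node = node, state = st)
}

# factor := GENE | '(' or-expr ')'
gpr_parse_factor <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk)) gpr_error(st, "dangling operator (expression expected)")
  if (tk$type == "GENE") {
    st$pos <- st$pos + 1L
    return(list(node = list(kind = "gene", gene = tk$text), state = st))
  }
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    res <- gpr_parse_or(st)
    st <- res$state
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")")
      gpr_error(st, "unbalanced parentheses (')' expected)")
    st$pos <- st$pos + 1L
    return(list(node = res$node, state = st))
  }
  gpr_error(st, sprintf("operator '%s' where a gene or '(' was expected",
                        tk$text))
}

# merge same-operator grandchildren so chains are n-ary, not nested pairs
gpr_flatten <- function(children, kind) {
  out <- list()
  for (ch in children) {
    if (identical(ch$kind, kind)) out <- c(out, ch$children)
    else out[[length(out) + 1L]] <- ch
  }
  out
}

#' Genes referenced by a GPR expression
#'
#' @param expr a `gpr_expression` (or internal node).
#' @return character vector of unique gene ids, in first-appearance order.
#' @export
gpr_genes <- function(expr) {
  if (expr$kind == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes), use.names = FALSE))
}

#' Render a GPR expression back to a rule string
#'
#' Canonical form: lower-case operators, compound children parenthesised.
#'
#' @param expr a `gpr_expression`.
#' @return a GPR string.
#' @export
deparse_gpr <- function(expr) {
  if (expr$kind == "gene") return(expr$gene)
  parts <- vapply(expr$children, function(ch) {
    s <- deparse_gpr(ch)
    if (ch$kind != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = if (expr$kind == "and") " and " else " or ")
}

#' @export
print.gpr_expression <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR expression into a Reaction Activity Score
#'
#' The numeric GPR semantics of reaction activity scoring: a gene leaf
#' evaluates to its expression abundance, `AND` to the minimum of its
#' children (the scarcest complex subunit limits the enzyme), `OR` to the sum
#' (isozyme abundances add). Genes absent from `em` are handled by policy:
#' `"skip"` drops them from their operator (a node whose children are all
#' undefined is itself undefined), `"zero"` treats them as abundance 0. An
#' undefined result is returned as `NA` and means the reaction should be left
#' unconstrained.
#'
#' @param expr a `gpr_expression`.
#' @param em named numeric vector of non-negative gene abundances.
#' @param missing_policy `"skip"` or `"zero"`.
#' @return a non-negative number, or `NA_real_` when undefined.
#' @examples
#' e <- parse_gpr("(gA and gB) or gC")
#' evaluate_ras(e, c(gA = 5, gB = 3, gC = 2))  # min(5,3) + 2 = 5
#' @export
evaluate_ras <- function(expr, em, missing_policy = c("skip", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (any(em < 0, na.rm = TRUE))
    stop("expression abundances must be non-negative", call. = FALSE)
  eval_node <- function(node) {
    if (node$kind == "gene") {
      if (!(node$gene %in% names(em)) || is.na(em[[node$gene]]))
        return(if (missing_policy == "zero") 0 else NA_real_)
      return(unname(em[[node$gene]]))
    }
    vals <- vapply(node$children, eval_node, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (node$kind == "and") min(vals) else sum(vals)
  }
  eval_node(expr)
}
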