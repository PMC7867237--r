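# Independent reference implementations used as oracles.

# ---- random GPR trees -------------------------------------------------------
# Trees are built in their own representation (list(type=..)), rendered to a
# rule string with randomised operator spellings/extra parentheses, and
# evaluated by a reference recursion that never touches the package parser.

random_gpr_tree <- function(max_depth = 5, max_genes = 8) {
  pool <- sprintf("gene%02d", seq_len(max_genes))
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.4)
      return(list(type = "g", name = sample(pool, 1L)))
    op <- sample(c("and", "or"), 1L)
    n_children <- sample(2:3, 1L)
    list(type = op, children = lapply(seq_len(n_children),
                                      function(i) build(depth + 1L)))
  }
  build(1L)
}

# spell operators in random accepted forms; parenthesise children whenever
# precedence demands it, plus occasionally when it does not
render_gpr_tree <- function(node) {
  if (node$type == "g") return(node$name)
  spell <- if (node$type == "and") sample(c("and", "AND", "And", "&", "&&"), 1L)
           else sample(c("or", "OR", "Or", "|", "||"), 1L)
  parts <- vapply(node$children, function(ch) {
    s <- render_gpr_tree(ch)
    # always parenthesise compound children: preserves tree shape exactly
    if (ch$type != "g") paste0("(", s, ")") else s
  }, character(1))
  extra <- stats::runif(1) < 0.2
  out <- paste(parts, collapse = paste0(" ", spell, " "))
  if (extra) paste0("(", out, ")") else out
}

reference_eval_gpr <- function(node, em, policy) {
  if (node$type == "g") {
    if (node$name %in% names(em)) return(em[[node$name]])
    return(if (policy == "zero") 0 else NA_real_)
  }
  vals <- vapply(node$children, reference_eval_gpr, numeric(1),
                 em = em, policy = policy)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (node$type == "and") min(vals) else sum(vals)
}

tree_genes <- function(node) {
  if (node$type == "g") return(node$name)
  unique(unlist(lapply(node$children, tree_genes)))
}

# ---- exhaustive vertex-enumeration LP oracle --------------------------------
# Enumerates the vertices of { v : S v = 0, lb <= v <= ub [, a'v >= d] } by
# solving every full-rank system of the equalities plus (n - rank(S)) active
# inequality constraints, then optimises any linear objective over the vertex
# set. Valid for bounded polytopes (all test networks use finite bounds).

enumerate_vertices <- function(S, lb, ub, ge = NULL, tol = 1e-7) {
  S <- as.matrix(S)
  n <- length(lb)
  # candidate inequality rows as a'v <= b
  rows <- list()
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    rows[[length(rows) + 1L]] <- list(a = e, b = ub[i])
    rows[[length(rows) + 1L]] <- list(a = -e, b = -lb[i])
  }
  if (!is.null(ge))
    rows[[length(rows) + 1L]] <- list(a = -ge$a, b = -ge$b)

  r <- qr(S)$rank
  k <- n - r
  verts <- list()
  feasible <- function(v) {
    all(abs(S %*% v) <= tol) &&
      all(v >= lb - tol) && all(v <= ub + tol) &&
      (is.null(ge) || sum(ge$a * v) >= ge$b - tol)
  }
  if (k == 0L) {
    sol <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(sol) && feasible(sol)) verts[[1L]] <- sol
  } else {
    combos <- utils::combn(length(rows), k, simplify = FALSE)
    for (cmb in combos) {
      M <- rbind(S, t(vapply(rows[cmb], `[[`, numeric(n), "a")))
      rhs <- c(rep(0, nrow(S)), vapply(rows[cmb], `[[`, numeric(1), "b"))
      qrM <- qr(M)
      if (qrM$rank < n) next
      v <- tryCatch(qr.coef(qrM, rhs)[seq_len(n)], error = function(e) NULL)
      if (is.null(v) || anyNA(v)) next
      if (feasible(v)) verts[[length(verts) + 1L]] <- as.numeric(v)
    }
  }
  if (length(verts) == 0L) return(NULL)
  V <- unique(round(do.call(rbind, verts), 9))
  V
}

oracle_fba <- function(obj, S, lb, ub) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) return(list(status = "infeasible", Z = NA_real_))
  vals <- as.numeric(V %*% obj)
  list(status = "optimal", Z = max(vals))
}

oracle_fva <- function(S, lb, ub, obj, gamma, Z0) {
  ge <- if (gamma > 0) list(a = obj, b = gamma * Z0) else NULL
  V <- enumerate_vertices(S, lb, ub, ge = ge)
  if (is.null(V)) return(NULL)
  list(min = apply(V, 2L, min), max = apply(V, 2L, max))
}

# random small network as a gem, with finite bounds so the polytope is bounded
random_toy_network <- function(allow_infeasible = FALSE) {
  n <- sample(2:6, 1L)
  m <- sample(1:5, 1L)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 0, 1, 1, 2), m * n, replace = TRUE),
                m, n)
    if (any(S != 0)) break
  }
  lb <- sample(c(-10, -5, 0), n, replace = TRUE)
  ub <- sample(c(0, 5, 10), n, replace = TRUE)
  swap <- lb > ub
  tmp <- lb[swap]; lb[swap] <- ub[swap]; ub[swap] <- tmp
  if (allow_infeasible && stats::runif(1) < 0.3) {
    i <- sample(n, 1L)
    lb[i] <- 2; ub[i] <- max(ub[i], 4)
  }
  obj <- numeric(n)
  obj[sample(n, 1L)] <- 1
  mets <- sprintf("m%d", seq_len(m))
  rxns <- lapply(seq_len(n), function(j) {
    st <- S[, j]
    names(st) <- mets
    list(id = sprintf("R%d", j), lower_bound = lb[j], upper_bound = ub[j],
         stoich = st[st != 0], objective_coefficient = obj[j])
  })
  g <- gem(rxns, metabolites = mets, model_id = "rand")
  list(gem = g, S = S, lb = lb, ub = ub, obj = obj)
}
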