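# Flux balance analysis and flux variability analysis.
#
# Both are linear programs over the steady-state flux polytope
#   { v : S v = 0, v_l <= v <= v_u }.
# solve_lp() shifts fluxes by their lower bounds (x = v - v_l >= 0), turns
# upper bounds into explicit slack rows and hands the standard-form program
# to the in-package two-phase simplex (simplex.R). Bland's rule makes every
# solve deterministic: identical inputs give identical pivots, hence
# identical solutions.

# Large-but-finite stand-in for infinite bounds. A flux pinned to it in an
# optimum flags the problem as unbounded in that direction.
LP_BIG <- 1e6
LP_FEAS_TOL <- 1e-9
LP_REPORT_TOL <- 1e-6

# Solve max/min obj'v s.t. S v = 0, lb <= v <= ub, and optionally one extra
# inequality a'v >= b (the FVA objective-retention row). Returns
# list(status, value, v).
solve_lp <- function(obj, S, lb, ub, maximize = TRUE, ge = NULL) {
  n <- length(obj)
  lb_inf <- !is.finite(lb)
  ub_inf <- !is.finite(ub)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  Sd <- as.matrix(S)
  m <- nrow(Sd)
  has_ge <- !is.null(ge)

  # standard form over z = (x, s[, t]):  x = v - lb,  x + s = ub - lb,
  # and optionally a'x - t = ge$b - a'lb  (t >= 0 the surplus of the
  # objective-retention row)
  ncols <- 2L * n + has_ge
  A <- matrix(0, m + n + has_ge, ncols)
  A[seq_len(m), seq_len(n)] <- Sd
  A[m + seq_len(n), seq_len(n)] <- diag(n)
  A[m + seq_len(n), n + seq_len(n)] <- diag(n)
  bvec <- c(as.numeric(-Sd %*% lb), ub - lb)
  if (has_ge) {
    A[m + n + 1L, seq_len(n)] <- ge$a
    A[m + n + 1L, ncols] <- -1
    bvec <- c(bvec, ge$b - sum(ge$a * lb))
  }
  cost <- c(if (maximize) -obj else obj, rep(0, n + has_ge))

  res <- simplex_solve(cost, A, bvec)
  if (res$status == "infeasible")
    return(list(status = "infeasible", value = NA_real_,
                v = rep(NA_real_, n)))
  if (res$status != "optimal")
    return(list(status = "solver_error", value = NA_real_,
                v = rep(NA_real_, n)))
  v <- res$z[seq_len(n)] + lb
  # a flux pressed against the stand-in cap of an infinite bound means the
  # LP is unbounded in that direction
  unbounded <- any((ub_inf & v >= LP_BIG * (1 - 1e-9)) |
                   (lb_inf & v <= -LP_BIG * (1 - 1e-9)))
  list(status = if (unbounded) "unbounded" else "optimal",
       value = sum(obj * v), v = v)
}

# Objective vector of a model, falling back to the biomass id heuristic.
objective_vector <- function(g) {
  obj <- g$reactions$objective_coefficient
  if (all(obj == 0)) {
    bio <- find_biomass_reaction(g)  # errors if not identifiable
    obj[match(bio, g$reactions$id)] <- 1
  }
  obj
}

#' Flux balance analysis
#'
#' Maximises the model objective `c'v` (biomass synthesis flux by
#' convention) subject to steady-state mass balance `S v = 0` and the flux
#' bounds. Negative flux through an exchange reaction is uptake, positive is
#' secretion. When the model carries no nonzero objective coefficient, the
#' biomass reaction is located by id ([find_biomass_reaction()]).
#'
#' The optimal objective value `Z` is unique, but the flux vector attaining
#' it generally is not (degenerate optima); treat per-reaction fluxes as one
#' witness and use [fva()] for reproducible ranges.
#'
#' @param g a [gem].
#' @return an `fba_result`: list with `status` (`"optimal"`/`"infeasible"`/
#'   `"solver_error"`), `objective_value` (`Z`, `NA` unless optimal) and
#'   `fluxes` (named numeric).
#' @export
fba <- function(g) {
  validate_gem(g)
  obj <- objective_vector(g)
  sol <- solve_lp(obj, g$S, g$reactions$lower_bound,
                  g$reactions$upper_bound, maximize = TRUE)
  structure(list(status = sol$status,
                 objective_value = sol$value,
                 fluxes = stats::setNames(sol$v, g$reactions$id)),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat(sprintf("<fba_result> status=%s Z=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Flux variability analysis
#'
#' For each queried reaction, minimises and maximises its flux over the
#' steady-state polytope with the additional requirement that the objective
#' retains at least the fraction `gamma` of its FBA optimum `Z0`
#' (`c'v >= gamma * Z0`). `gamma = 1` (default) explores only flux
#' distributions supporting the maximal biomass production rate; `gamma = 0`
#' drops the requirement entirely. A feasibility slack of `1e-9 *
#' max(1, |Z0|)` is subtracted from the retention threshold so the optimal
#' face itself is never cut off by rounding. Fractional retention assumes a
#' non-negative optimum (the biomass convention); with `Z0 < 0` and
#' `gamma < 1` the retention region is empty and the subproblems error.
#'
#' @param g a [gem].
#' @param reaction_ids reactions to query; default all exchange reactions.
#' @param gamma objective-retention fraction in \[0, 1\].
#' @return an `fva_result`: list with `gamma`, `Z0`, and `ranges` — a
#'   data.frame (`reaction`, `min_flux`, `max_flux`).
#' @export
fva <- function(g, reaction_ids = NULL, gamma = 1) {
  validate_gem(g)
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop("gamma must be a single number in [0, 1]", call. = FALSE)
  if (is.null(reaction_ids)) reaction_ids <- exchange_reactions(g)
  unknown <- setdiff(reaction_ids, g$reactions$id)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  obj <- objective_vector(g)
  base <- fba(g)
  if (base$status != "optimal")
    stop("FVA base problem not optimal (status: ", base$status, ")",
         call. = FALSE)
  Z0 <- base$objective_value
  ge <- if (gamma > 0)
          list(a = obj, b = gamma * Z0 - LP_FEAS_TOL * max(1, abs(Z0)))
        else NULL

  n <- nrow(g$reactions)
  lims <- vapply(reaction_ids, function(rid) {
    e <- numeric(n)
    e[match(rid, g$reactions$id)] <- 1
    lo <- solve_lp(e, g$S, g$reactions$lower_bound, g$reactions$upper_bound,
                   maximize = FALSE, ge = ge)
    hi <- solve_lp(e, g$S, g$reactions$lower_bound, g$reactions$upper_bound,
                   maximize = TRUE, ge = ge)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA subproblem for '", rid, "' not optimal", call. = FALSE)
    c(lo$value, hi$value)
  }, numeric(2))

  structure(list(
    gamma = gamma, Z0 = Z0,
    ranges = data.frame(reaction = reaction_ids,
                        min_flux = lims[1L, ],
                        max_flux = lims[2L, ],
                        row.names = NULL,
                        stringsAsFactors = FALSE)),
    class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat(sprintf("<fva_result> gamma=%g Z0=%s, %d reactions\n", x$gamma,
              format(x$Z0), nrow(x$ranges)))
  invisible(x)
}
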