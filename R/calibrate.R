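# Calibration of the scale factor alpha against observed growth.
#
# Biomass flux units are arbitrary (mM/48 h of a pseudo-metabolite), while
# growth observables are reciprocal doubling times (1/h); only the shape
# across conditions can be matched. The default metric therefore
# least-squares-scales predictions onto observations before taking the RMSE.

#' Log-uniform alpha grid
#'
#' @param from,to positive grid endpoints (defaults: the canonical scan
#'   range 1e-6 to 1).
#' @param n number of points.
#' @return strictly increasing numeric vector of length `n`.
#' @export
alpha_grid <- function(from = 1e-6, to = 1, n = 25L) {
  stopifnot(from > 0, to > from, n >= 2L)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Scan alpha over a grid of condition models
#'
#' For every grid alpha and every condition, builds the requested model
#' variant and records the FBA biomass optimum. An infeasible solve is
#' recorded as biomass 0 with `feasible = FALSE` rather than aborting the
#' scan. Within each condition the biomass column is non-decreasing in
#' alpha: growing alpha only relaxes the RAS caps.
#'
#' @param g the base [gem].
#' @param condition_profiles named list per condition: `list(ras = , mur =
#'   )` (either may be `NULL` if the variant ignores it).
#' @param grid strictly increasing positive alphas (default
#'   [alpha_grid()]).
#' @param variant `"ras_mur"`, `"ras"` or `"mur"`; for `"mur"` the scan is
#'   flat in alpha by construction.
#' @param ... further arguments to [integration_config()].
#' @return a `calibration_table`: data.frame (`alpha`, `condition`,
#'   `biomass_flux`, `feasible`) with the grid in attribute `"grid"`.
#' @export
scan_alpha <- function(g, condition_profiles, grid = alpha_grid(),
                       variant = c("ras_mur", "ras", "mur"), ...) {
  variant <- match.arg(variant)
  if (any(diff(grid) <= 0) || any(grid <= 0))
    stop("grid must be strictly increasing and positive", call. = FALSE)
  if (is.null(names(condition_profiles)))
    stop("condition_profiles must be a named list", call. = FALSE)
  rows <- list()
  for (a in grid) {
    cfg <- integration_config(alpha = a, variant = variant, ...)
    for (cn in names(condition_profiles)) {
      p <- condition_profiles[[cn]]
      m <- build_condition_model(
        g,
        ras = if (variant %in% c("ras", "ras_mur")) p$ras else NULL,
        mur = if (variant %in% c("mur", "ras_mur")) p$mur else NULL,
        cfg = cfg)
      sol <- fba(m)
      ok <- sol$status == "optimal"
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = a, condition = cn,
        biomass_flux = if (ok) sol$objective_value else 0,
        feasible = ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "grid") <- grid
  attr(out, "variant") <- variant
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Agreement between predicted biomass fluxes and observed growth
#'
#' `metric = "scaled_rmse"`: predictions are scaled by the least-squares
#' factor `s = sum(p*y) / sum(p^2)` onto the observations and the root mean
#' squared residual is returned (0 = perfectly proportional; lower is
#' better). `metric = "pearson"`: the correlation across conditions (higher
#' is better); constant predictions make it undefined and raise an error.
#' Conditions without an observation (no measurable growth) are excluded.
#'
#' @param predicted named numeric: condition -> biomass flux.
#' @param observed data.frame `condition`, `reciprocal_doubling_time` (`NA`
#'   = absent).
#' @param metric `"scaled_rmse"` or `"pearson"`.
#' @return a single number.
#' @export
match_score <- function(predicted, observed,
                        metric = c("scaled_rmse", "pearson")) {
  metric <- match.arg(metric)
  obs <- observed[!is.na(observed$reciprocal_doubling_time), , drop = FALSE]
  common <- intersect(names(predicted), obs$condition)
  if (length(common) < 2L)
    stop("match_score needs at least 2 conditions with observations",
         call. = FALSE)
  p <- as.numeric(predicted[common])
  y <- obs$reciprocal_doubling_time[match(common, obs$condition)]
  if (metric == "pearson") {
    if (stats::sd(p) == 0 || stats::sd(y) == 0)
      stop("pearson undefined: zero variance across conditions",
           call. = FALSE)
    return(stats::cor(p, y))
  }
  s <- if (sum(p^2) == 0) 0 else sum(p * y) / sum(p^2)
  sqrt(mean((s * p - y)^2))
}

#' Select the best-matching alpha from a calibration scan
#'
#' Scores every grid alpha with [match_score()] and returns the optimiser
#' (minimum scaled RMSE or maximum Pearson correlation). Ties — within a
#' relative 1e-9 of the best score — are broken toward the smaller alpha
#' (the tighter model). Alphas whose score is undefined (e.g. constant
#' predictions under Pearson) are skipped; if none remains, an error is
#' raised.
#'
#' @param table a `calibration_table` from [scan_alpha()].
#' @param observed data.frame `condition`, `reciprocal_doubling_time`.
#' @param metric `"scaled_rmse"` or `"pearson"`.
#' @return list with `alpha` (the selected value), `metric`, and `scores`
#'   (data.frame `alpha`, `score`).
#' @export
select_alpha <- function(table, observed,
                         metric = c("scaled_rmse", "pearson")) {
  metric <- match.arg(metric)
  if (!inherits(table, "calibration_table"))
    stop("`table` must come from scan_alpha()", call. = FALSE)
  grid <- attr(table, "grid")
  if (all(!table$feasible))
    stop("all (alpha, condition) solves infeasible; nothing to select",
         call. = FALSE)
  scores <- vapply(grid, function(a) {
    sub <- table[table$alpha == a, ]
    pred <- stats::setNames(sub$biomass_flux, sub$condition)
    tryCatch(match_score(pred, observed, metric),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(scores)))
    stop("score undefined on every grid point", call. = FALSE)
  val <- if (metric == "scaled_rmse") scores else -scores
  best <- min(val, na.rm = TRUE)
  tol <- 1e-9 * max(1, abs(best))
  cand <- which(!is.na(val) & val <= best + tol)
  sel <- grid[min(cand)]  # tie -> smaller alpha (grid is increasing)
  list(alpha = sel, metric = metric,
       scores = data.frame(alpha = grid, score = scores))
}
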