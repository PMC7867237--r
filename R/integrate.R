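# Condition-specific model variants: GEM-RAS, GEM-MUR, GEM-RAS-MUR.
#
# Both rewrites only ever tighten: a bound is moved toward zero, never past
# its original value. This keeps the condition model's feasible set a subset
# of the base model's (so adding data can only restrict predictions) and
# makes the RAS and MUR rewrites commute.

#' Integration configuration
#'
#' @param alpha positive scale factor mapping activity scores to flux units
#'   (flux cap of reaction i is `alpha * RAS_i`).
#' @param variant which data to integrate: `"ras"`, `"mur"` or `"ras_mur"`.
#' @param ras_zero_policy `"block"` closes a reaction whose RAS is 0 (both
#'   bounds 0, the literal `alpha * 0` cap); `"leave"` keeps its original
#'   bounds.
#' @param unmapped_exchange_policy `"leave"` keeps default bounds on exchange
#'   reactions without a MUR (serum components, unquantified micronutrients);
#'   `"close"` forbids their uptake (lower bound 0).
#' @return an `integration_config` list.
#' @export
integration_config <- function(alpha = 1,
                               variant = c("ras_mur", "ras", "mur"),
                               ras_zero_policy = c("block", "leave"),
                               unmapped_exchange_policy = c("leave", "close")) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  structure(list(alpha = alpha,
                 variant = match.arg(variant),
                 ras_zero_policy = match.arg(ras_zero_policy),
                 unmapped_exchange_policy = match.arg(unmapped_exchange_policy)),
            class = "integration_config")
}

#' Rescale flux bounds of GPR reactions by activity scores
#'
#' For each reaction with a defined RAS, the flux cap is `v_i = alpha *
#' RAS_i`: a negative lower bound is raised to `-v_i` (backward direction)
#' and a positive upper bound lowered to `+v_i` (forward direction). A bound
#' that is already 0 stays 0 — the impossible direction of an irreversible
#' reaction is never opened — and a bound already tighter than the cap is
#' kept (bounds only tighten). Reactions without a score are untouched. The
#' input model is not modified.
#'
#' @param g a [gem].
#' @param ras a `ras_profile` computed on the same model.
#' @param alpha positive scale factor.
#' @param ras_zero_policy `"block"` or `"leave"` (see
#'   [integration_config()]).
#' @return a new [gem] with rewritten bounds.
#' @export
apply_ras_bounds <- function(g, ras, alpha,
                             ras_zero_policy = c("block", "leave")) {
  ras_zero_policy <- match.arg(ras_zero_policy)
  validate_gem(g)
  if (!inherits(ras, "ras_profile")) stop("`ras` must be a ras_profile",
                                          call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single positive number", call. = FALSE)
  unknown <- setdiff(names(ras$ras), g$reactions$id)
  if (length(unknown))
    stop("RAS profile names reaction(s) absent from the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (rid in names(ras$ras)) {
    v <- alpha * ras$ras[[rid]]
    if (v == 0 && ras_zero_policy == "leave") next
    i <- match(rid, g$reactions$id)
    lb <- g$reactions$lower_bound[i]
    ub <- g$reactions$upper_bound[i]
    if (lb < 0) g$reactions$lower_bound[i] <- max(lb, -v)
    if (ub > 0) g$reactions$upper_bound[i] <- min(ub, v)
  }
  validate_gem(g)
  g
}

#' Cap exchange uptake by maximal uptake rates
#'
#' Each profiled exchange reaction's lower bound is raised to `-MUR_j`
#' (uptake cannot exceed availability); its upper (secretion) bound is never
#' modified. An exchange whose uptake is already forbidden (lower bound 0)
#' stays closed. Unprofiled exchanges follow `policy`: `"leave"` keeps model
#' defaults, `"close"` sets their lower bound to 0.
#'
#' @param g a [gem].
#' @param mur a `mur_profile`.
#' @param policy unmapped-exchange policy, `"leave"` or `"close"`.
#' @return a new [gem] with rewritten exchange lower bounds.
#' @export
apply_mur_bounds <- function(g, mur, policy = c("leave", "close")) {
  policy <- match.arg(policy)
  validate_gem(g)
  if (!inherits(mur, "mur_profile")) stop("`mur` must be a mur_profile",
                                          call. = FALSE)
  ex <- exchange_reactions(g)
  offenders <- setdiff(names(mur$mur), ex)
  if (length(offenders))
    stop("MUR profile names non-exchange or unknown reaction(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  for (rid in names(mur$mur)) {
    i <- match(rid, g$reactions$id)
    g$reactions$lower_bound[i] <-
      max(g$reactions$lower_bound[i], -mur$mur[[rid]])
  }
  if (policy == "close") {
    for (rid in setdiff(ex, names(mur$mur))) {
      i <- match(rid, g$reactions$id)
      g$reactions$lower_bound[i] <-
        min(max(g$reactions$lower_bound[i], 0), g$reactions$upper_bound[i])
    }
  }
  validate_gem(g)
  g
}

#' Build a condition-specific model variant
#'
#' Composes the RAS and MUR bound rewrites according to the configured
#' variant (`"ras"`, `"mur"`, `"ras_mur"`). Because both rewrites only
#' tighten bounds (max/min against the cap), the composition is
#' order-independent; RAS is applied first by convention.
#'
#' @param g the base [gem].
#' @param ras a `ras_profile`, required for variants `"ras"`/`"ras_mur"`.
#' @param mur a `mur_profile`, required for variants `"mur"`/`"ras_mur"`.
#' @param cfg an [integration_config()].
#' @return a new condition-specific [gem].
#' @export
build_condition_model <- function(g, ras = NULL, mur = NULL,
                                  cfg = integration_config()) {
  if (!inherits(cfg, "integration_config"))
    stop("`cfg` must be an integration_config", call. = FALSE)
  need_ras <- cfg$variant %in% c("ras", "ras_mur")
  need_mur <- cfg$variant %in% c("mur", "ras_mur")
  if (need_ras && is.null(ras))
    stop("variant '", cfg$variant, "' requires a RAS profile", call. = FALSE)
  if (need_mur && is.null(mur))
    stop("variant '", cfg$variant, "' requires a MUR profile", call. = FALSE)
  if (!need_ras && !is.null(ras))
    stop("variant '", cfg$variant, "' does not take a RAS profile",
         call. = FALSE)
  if (!need_mur && !is.null(mur))
    stop("variant '", cfg$variant, "' does not take a MUR profile",
         call. = FALSE)
  out <- g
  if (need_ras)
    out <- apply_ras_bounds(out, ras, cfg$alpha, cfg$ras_zero_policy)
  if (need_mur)
    out <- apply_mur_bounds(out, mur, cfg$unmapped_exchange_policy)
  out
}
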