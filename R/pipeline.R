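# End-to-end profiling: model + per-condition expression/media/growth ->
# calibrated alpha -> variant biomass fluxes -> FVA uptake/secretion ranges.

#' Assemble and validate a profiling run configuration
#'
#' @param model a [gem] or path to an SBML/COBRA-JSON model file.
#' @param conditions named list, one element per condition, each a list with
#'   `expression` (gene x replicate matrix or table path), `media`
#'   (measurement data.frame or media-table path; a shared table is filtered
#'   by its `condition` column) and optional `observed` (reciprocal doubling
#'   time, 1/h; `NULL`/`NA` when the condition did not grow).
#' @param alpha a positive number, or `"calibrate"` to select it from the
#'   observations via [scan_alpha()] / [select_alpha()].
#' @param variants subset of `"ras_mur"`, `"ras"`, `"mur"`,
#'   `"ras_donor_mur"` (the last pairs every condition's MUR with the RAS of
#'   the `ras_from` donor condition).
#' @param fva_reactions reactions for the FVA step (`NULL` = all exchanges).
#' @param gamma FVA objective-retention fraction.
#' @param grid alpha grid used when calibrating.
#' @param metric calibration metric (see [match_score()]).
#' @param normalization,combine expression aggregation options
#'   (see [aggregate_expression()]).
#' @param missing_policy GPR missing-gene policy (see [evaluate_ras()]).
#' @param ras_from donor condition name for variant `"ras_donor_mur"`.
#' @param out_dir directory for TSV/JSON outputs (`NULL` = in-memory only).
#' @param seed integer recorded in provenance (the pipeline itself is
#'   deterministic; the seed matters when the inputs were generated).
#' @return a validated `run_config` list.
#' @export
run_config <- function(model, conditions, alpha = "calibrate",
                       variants = "ras_mur", fva_reactions = NULL,
                       gamma = 1, grid = alpha_grid(),
                       metric = "scaled_rmse",
                       normalization = "cpm", combine = "mean",
                       missing_policy = "skip", ras_from = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.character(model) && !file.exists(model))
    stop("config invalid: model file not found: ", model, call. = FALSE)
  if (!is.list(conditions) || length(conditions) == 0L ||
      is.null(names(conditions)) || any(!nzchar(names(conditions))))
    stop("config invalid: `conditions` must be a non-empty named list",
         call. = FALSE)
  for (cn in names(conditions)) {
    cd <- conditions[[cn]]
    for (f in c("expression", "media")) {
      if (is.null(cd[[f]]))
        stop("config invalid: condition '", cn, "' lacks `", f, "`",
             call. = FALSE)
      if (is.character(cd[[f]]) && !file.exists(cd[[f]]))
        stop("config invalid: condition '", cn, "' ", f, " file not found: ",
             cd[[f]], call. = FALSE)
    }
  }
  bad <- setdiff(variants, c("ras_mur", "ras", "mur", "ras_donor_mur"))
  if (length(bad))
    stop("config invalid: unknown variant(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if ("ras_donor_mur" %in% variants &&
      (is.null(ras_from) || !ras_from %in% names(conditions)))
    stop("config invalid: variant 'ras_donor_mur' needs `ras_from` naming ",
         "a configured condition", call. = FALSE)
  if (!(identical(alpha, "calibrate") ||
        (is.numeric(alpha) && length(alpha) == 1L && alpha > 0)))
    stop("config invalid: `alpha` must be a positive number or 'calibrate'",
         call. = FALSE)
  structure(list(model = model, conditions = conditions, alpha = alpha,
                 variants = variants, fva_reactions = fva_reactions,
                 gamma = gamma, grid = grid, metric = metric,
                 normalization = normalization, combine = combine,
                 missing_policy = missing_policy, ras_from = ras_from,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a profiling configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `conditions` is a
#' map of condition name to `expression`, `media`, `observed`. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (is.character(p) && !file.exists(p))
    file.path(base, p) else p
  conds <- lapply(y$conditions, function(cd) {
    list(expression = resolve(cd$expression), media = resolve(cd$media),
         observed = cd$observed)
  })
  args <- y[setdiff(names(y), c("conditions", "model"))]
  do.call(run_config, c(list(model = resolve(y$model), conditions = conds),
                        args))
}

load_condition_inputs <- function(cfg, g) {
  profiles <- list()
  for (cn in names(cfg$conditions)) {
    cd <- cfg$conditions[[cn]]
    counts <- if (is.character(cd$expression))
      read_expression_table(cd$expression) else cd$expression
    em <- aggregate_expression(counts, normalization = cfg$normalization,
                               combine = cfg$combine)
    media <- if (is.character(cd$media)) read_media_table(cd$media)
             else as.data.frame(cd$media)
    if ("condition" %in% colnames(media) && any(media$condition == cn))
      media <- media[media$condition == cn, , drop = FALSE]
    profiles[[cn]] <- list(
      ras = compute_ras_profile(g, em, condition = cn,
                                missing_policy = cfg$missing_policy),
      mur = build_mur_profile(cn, media, g))
  }
  profiles
}

#' Run the full integrated profiling pipeline
#'
#' Loads the model, computes per-condition RAS and MUR profiles, fixes or
#' calibrates alpha, solves FBA for every requested variant and condition,
#' and runs FVA on the RAS-MUR models. One infeasible condition degrades to
#' a flagged row, not an abort. Output is deterministic given the inputs.
#'
#' @param cfg a `run_config` (or YAML path).
#' @return a `profiling_report`: list with `biomass` (data.frame
#'   `condition`, `variant`, `biomass_flux`, `status`), `fva` (data.frame
#'   `condition`, `reaction`, `min_flux`, `max_flux`; fluxes in mM per
#'   window, negative = uptake, positive = secretion), `calibration`
#'   (selection result or `NULL`), and `provenance`.
#' @export
run_profile <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config"))
    stop("config invalid: not a run_config", call. = FALSE)
  g <- if (is.character(cfg$model)) read_model(cfg$model) else cfg$model
  validate_gem(g)
  profiles <- load_condition_inputs(cfg, g)

  observed <- data.frame(
    condition = names(cfg$conditions),
    reciprocal_doubling_time = vapply(cfg$conditions, function(cd) {
      if (is.null(cd$observed) || is.na(cd$observed)) NA_real_
      else as.numeric(cd$observed)
    }, numeric(1)),
    stringsAsFactors = FALSE)

  calibration <- NULL
  alpha <- cfg$alpha
  if (identical(alpha, "calibrate")) {
    tab <- scan_alpha(g, profiles, grid = cfg$grid, variant = "ras_mur")
    calibration <- select_alpha(tab, observed, metric = cfg$metric)
    calibration$table <- tab
    alpha <- calibration$alpha
  }

  donor_ras <- if (!is.null(cfg$ras_from)) profiles[[cfg$ras_from]]$ras

  biomass <- list()
  ras_mur_models <- list()
  for (variant in cfg$variants) {
    for (cn in names(profiles)) {
      p <- profiles[[cn]]
      eff_variant <- if (variant == "ras_donor_mur") "ras_mur" else variant
      ras <- switch(variant, ras_donor_mur = donor_ras,
                    mur = NULL, p$ras)
      mur <- if (eff_variant %in% c("mur", "ras_mur")) p$mur else NULL
      m <- build_condition_model(
        g, ras = ras, mur = mur,
        cfg = integration_config(alpha = alpha, variant = eff_variant))
      sol <- fba(m)
      if (variant == "ras_mur") ras_mur_models[[cn]] <- m
      biomass[[length(biomass) + 1L]] <- data.frame(
        condition = cn, variant = variant,
        biomass_flux = if (sol$status == "optimal") sol$objective_value
                       else 0,
        status = sol$status, stringsAsFactors = FALSE)
    }
  }
  biomass <- do.call(rbind, biomass)

  fva_tab <- NULL
  if (length(ras_mur_models)) {
    fva_rows <- lapply(names(ras_mur_models), function(cn) {
      m <- ras_mur_models[[cn]]
      res <- tryCatch(fva(m, reaction_ids = cfg$fva_reactions,
                          gamma = cfg$gamma),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      cbind(condition = cn, res$ranges, stringsAsFactors = FALSE)
    })
    fva_rows <- fva_rows[!vapply(fva_rows, is.null, logical(1))]
    if (length(fva_rows)) fva_tab <- do.call(rbind, fva_rows)
  }

  report <- structure(list(
    biomass = biomass,
    fva = fva_tab,
    calibration = calibration,
    provenance = list(
      model_id = g$model_id,
      alpha = alpha,
      gamma = cfg$gamma,
      seed = cfg$seed,
      variants = cfg$variants,
      units = "mM per window (negative exchange flux = uptake)",
      package_version = as.character(utils::packageVersion("gemflux")))),
    class = "profiling_report")

  if (!is.null(cfg$out_dir)) write_profiling_report(report, cfg$out_dir)
  report
}

#' @export
print.profiling_report <- function(x, ...) {
  cat(sprintf("<profiling_report> alpha=%g, %d biomass rows, %s FVA rows\n",
              x$provenance$alpha, nrow(x$biomass),
              if (is.null(x$fva)) "no" else nrow(x$fva)))
  invisible(x)
}

#' Write a profiling report to disk
#'
#' Emits `biomass.tsv`, `fva.tsv` (if present), `calibration.tsv` (if
#' calibrated) and `report.json` (provenance + everything) into `dir`.
#'
#' @param report a `profiling_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_profiling_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$biomass, file.path(dir, "biomass.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$fva))
    utils::write.table(report$fva, file.path(dir, "fva.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$calibration))
    utils::write.table(report$calibration$scores,
                       file.path(dir, "calibration.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(provenance = report$provenance,
               biomass = report$biomass,
               fva = report$fva,
               calibration_scores = if (!is.null(report$calibration))
                 report$calibration$scores)
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", pretty = TRUE, null = "null"),
             file.path(dir, "report.json"))
  invisible(dir)
}
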