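# Nutrient availability -> Maximal Uptake Rates for exchange reactions.

#' Maximal uptake rate from a medium measurement
#'
#' The MUR of a substrate is the absolute concentration change over the
#' culture window, `|S_F - S_I| / (t_F - t_I)`, rescaled to the reporting
#' window (default: the measurement's own window, so a 4 mM glutamine stock
#' fully consumed between 0 and 48 h gives MUR = 4 mM/48 h). In
#' availability-only mode the final concentration is taken as 0: the nutrient
#' may be consumed completely.
#'
#' @param measurement a list or one-row data.frame with fields `s_initial`,
#'   `s_final` (mM), `t_initial`, `t_final` (h). A missing/`NA` `s_final`
#'   means availability-only and defaults to 0.
#' @param window reporting window in hours; `NULL` uses
#'   `t_final - t_initial`.
#' @return non-negative MUR, in mM per `window`.
#' @examples
#' compute_mur(list(s_initial = 4, s_final = 0, t_initial = 0, t_final = 48))
#' @export
compute_mur <- function(measurement, window = NULL) {
  si <- as.numeric(measurement$s_initial)
  sf <- measurement$s_final
  sf <- if (is.null(sf) || length(sf) == 0L || is.na(sf)) 0 else as.numeric(sf)
  ti <- as.numeric(measurement$t_initial)
  tf <- as.numeric(measurement$t_final)
  if (is.na(si) || si < 0 || sf < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (!is.finite(ti) || !is.finite(tf) || tf <= ti)
    stop("time window invalid: t_final must exceed t_initial", call. = FALSE)
  rate <- abs(sf - si) / (tf - ti)
  if (is.null(window)) window <- tf - ti
  rate * window
}

#' Read a media / spent-medium measurement table
#'
#' Expected columns: `condition`, `metabolite`, `exchange_id`,
#' `conc_initial_mM`, optionally `conc_final_mM` (blank/NA =
#' availability-only) and `t_hours` (window length, default 48).
#'
#' @param path TSV/CSV file.
#' @param sep field separator; `NULL` infers from the extension.
#' @return data.frame of measurements, one row per (condition, metabolite).
#' @export
read_media_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("condition", "metabolite", "exchange_id", "conc_initial_mM")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("media table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"conc_final_mM" %in% colnames(df)) df$conc_final_mM <- NA_real_
  if (!"t_hours" %in% colnames(df)) df$t_hours <- 48
  df
}

#' Build a MUR profile for one condition
#'
#' One MUR per measured exchange reaction; unmeasured exchange reactions are
#' absent from the profile (their bounds are left untouched downstream).
#' Measurements naming ids that are not exchange reactions of the model are
#' an error.
#'
#' @param condition condition label.
#' @param measurements data.frame with columns `exchange_id`,
#'   `conc_initial_mM`, optionally `conc_final_mM` (NA = availability-only,
#'   final concentration 0) and `t_hours` (default 48).
#' @param g a [gem].
#' @param window reporting window (h) passed to [compute_mur()]; `NULL` uses
#'   each measurement's own window.
#' @return a `mur_profile`: list with `condition` and `mur` (named
#'   non-negative numeric, exchange reaction id -> mM per window).
#' @examples
#' # Glc10Gln4-style medium: 10 mM glucose + 4 mM glutamine, fully available
#' @export
build_mur_profile <- function(condition, measurements, g, window = NULL) {
  validate_gem(g)
  ex <- exchange_reactions(g)
  if (is.null(measurements) || nrow(as.data.frame(measurements)) == 0L)
    return(structure(list(condition = condition, mur = numeric(0)),
                     class = "mur_profile"))
  measurements <- as.data.frame(measurements)
  ids <- as.character(measurements$exchange_id)
  offenders <- setdiff(ids, ex)
  if (length(offenders))
    stop("not exchange reaction(s) of the model: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  if (!"conc_final_mM" %in% colnames(measurements))
    measurements$conc_final_mM <- NA_real_
  if (!"t_hours" %in% colnames(measurements)) measurements$t_hours <- 48
  mur <- vapply(seq_len(nrow(measurements)), function(k) {
    compute_mur(list(
      s_initial = measurements$conc_initial_mM[k],
      s_final = measurements$conc_final_mM[k],
      t_initial = 0,
      t_final = measurements$t_hours[k]), window = window)
  }, numeric(1))
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate exchange_id in one condition: ",
         paste(unique(ids[dup]), collapse = ", "), call. = FALSE)
  structure(list(condition = condition,
                 mur = stats::setNames(mur, ids)),
            class = "mur_profile")
}

#' @export
print.mur_profile <- function(x, ...) {
  cat(sprintf("<mur_profile> %s: %d exchange reactions\n",
              x$condition, length(x$mur)))
  invisible(x)
}

#' Write a MUR profile as TSV
#'
#' @param profile a `mur_profile`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_mur_profile <- function(profile, path) {
  df <- data.frame(exchange_id = names(profile$mur),
                   mur_mM_per_window = as.numeric(profile$mur))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
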