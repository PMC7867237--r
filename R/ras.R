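# Expression aggregation and per-reaction activity scoring.

#' Read a gene-expression count table
#'
#' Accepts a plain TSV/CSV (first column gene id, remaining columns
#' replicates) or featureCounts output (leading `#` comment lines skipped;
#' the `Chr`, `Start`, `End`, `Strand`, `Length` annotation columns dropped).
#'
#' @param path expression table file.
#' @param sep field separator; `NULL` picks `\t` vs `,` from the extension.
#' @return numeric matrix, genes in rows (rownames = gene ids), replicates in
#'   columns.
#' @export
read_expression_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty expression table: ", path, call. = FALSE)
  fc_cols <- c("Chr", "Start", "End", "Strand", "Length")
  drop <- intersect(fc_cols, colnames(df))
  if (length(drop)) df <- df[, setdiff(colnames(df), drop), drop = FALSE]
  ids <- as.character(df[[1L]])
  counts <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- ids
  counts
}

#' Aggregate replicate counts into one abundance per gene
#'
#' Optionally normalises each replicate to counts-per-million (CPM) and then
#' combines replicates by mean or median. Gene ids are matched after
#' stripping trailing version suffixes (`".N"`); duplicated ids after
#' stripping are summed (transcript-level rows of one gene).
#'
#' @param counts numeric matrix or data.frame, genes x replicates, with gene
#'   ids as rownames (or a first character column).
#' @param normalization `"none"` or `"cpm"`.
#' @param combine `"mean"` or `"median"`.
#' @param strip_versions drop trailing `.N` from gene ids before matching.
#' @return an expression map: named non-negative numeric vector, one value
#'   per gene.
#' @examples
#' m <- matrix(c(10, 20, 30), nrow = 1, dimnames = list("g1", NULL))
#' aggregate_expression(m)  # 20
#' @export
aggregate_expression <- function(counts,
                                 normalization = c("cpm", "none"),
                                 combine = c("mean", "median"),
                                 strip_versions = TRUE) {
  normalization <- match.arg(normalization)
  combine <- match.arg(combine)
  if (is.data.frame(counts)) {
    if (is.character(counts[[1L]]) || is.factor(counts[[1L]])) {
      rn <- as.character(counts[[1L]])
      counts <- as.matrix(counts[, -1L, drop = FALSE])
      rownames(counts) <- rn
    } else counts <- as.matrix(counts)
  }
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("counts must be a non-empty gene x replicate matrix", call. = FALSE)
  if (is.null(rownames(counts)))
    stop("counts must carry gene ids as rownames", call. = FALSE)
  if (any(counts < 0))
    stop("negative count(s) in expression table", call. = FALSE)

  ids <- rownames(counts)
  if (strip_versions) ids <- sub("\\.[0-9]+$", "", ids)
  if (anyDuplicated(ids))
    counts <- rowsum(counts, group = ids, reorder = FALSE)
  else rownames(counts) <- ids

  if (normalization == "cpm") {
    libsize <- colSums(counts)
    libsize[libsize == 0] <- 1  # an empty replicate stays all-zero
    counts <- sweep(counts, 2L, libsize, "/") * 1e6
  }
  fun <- if (combine == "mean") rowMeans
         else function(m) apply(m, 1L, stats::median)
  out <- fun(counts)
  stats::setNames(as.numeric(out), rownames(counts))
}

#' Compute a Reaction Activity Score profile for one condition
#'
#' Evaluates every GPR-bearing reaction of the model against an expression
#' map ([evaluate_ras()]: AND = min, OR = sum). Reactions without a GPR are
#' absent from the profile; reactions whose evaluation is undefined under
#' `missing_policy = "skip"` are likewise absent and will be left
#' unconstrained downstream. A RAS of 0 is a legitimate value (transcribed
#' support fully silent), distinct from undefined.
#'
#' @param g a [gem].
#' @param em expression map from [aggregate_expression()].
#' @param condition condition label carried in the profile.
#' @param missing_policy `"skip"` or `"zero"` (see [evaluate_ras()]).
#' @return a `ras_profile`: list with `condition`, `ras` (named non-negative
#'   numeric, reaction id -> score) and `coverage` (fraction of GPR reactions
#'   with at least one measured gene).
#' @export
compute_ras_profile <- function(g, em, condition = "condition",
                                missing_policy = c("skip", "zero")) {
  missing_policy <- match.arg(missing_policy)
  validate_gem(g)
  has_gpr <- which(!is.na(g$reactions$gpr))
  ras <- numeric(0)
  measured <- 0L
  for (i in has_gpr) {
    rid <- g$reactions$id[i]
    expr <- tryCatch(parse_gpr(g$reactions$gpr[i]),
                     error = function(e)
                       stop("reaction '", rid, "': ", conditionMessage(e),
                            call. = FALSE))
    if (any(gpr_genes(expr) %in% names(em))) measured <- measured + 1L
    val <- evaluate_ras(expr, em, missing_policy)
    if (!is.na(val)) ras[rid] <- val
  }
  structure(
    list(condition = condition, ras = ras,
         coverage = if (length(has_gpr)) measured / length(has_gpr) else NA_real_),
    class = "ras_profile")
}

#' @export
print.ras_profile <- function(x, ...) {
  cat(sprintf("<ras_profile> %s: %d reactions scored (coverage %.2f)\n",
              x$condition, length(x$ras),
              ifelse(is.na(x$coverage), NaN, x$coverage)))
  invisible(x)
}

#' Write / read a RAS profile as TSV
#'
#' Two columns, `reaction_id` and `ras` — the same shape as deposited RAS
#' score files.
#'
#' @param profile a `ras_profile`.
#' @param path TSV file path.
#' @return `path` (write) or a `ras_profile` (read).
#' @export
write_ras_profile <- function(profile, path) {
  df <- data.frame(reaction_id = names(profile$ras),
                   ras = as.numeric(profile$ras))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ras_profile
#' @param condition condition label for the profile read back.
#' @export
read_ras_profile <- function(path, condition = "condition") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(
    list(condition = condition,
         ras = stats::setNames(as.numeric(df$ras),
                               as.character(df$reaction_id)),
         coverage = NA_real_),
    class = "ras_profile")
}
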