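#' Read a metabolic model from SBML or COBRA-JSON
#'
#' @param path model file.
#' @param format `"sbml"`, `"json"`, or `"auto"` (decide by extension, with a
#'   content sniff as fallback).
#' @return a [gem].
#' @seealso [read_sbml_model()], [read_json_model()], [write_model()]
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xml", "sbml")) "sbml"
              else if (ext == "json") "json"
              else {
                head <- readChar(path, 200L, useBytes = TRUE)
                if (grepl("^\\s*\\{", head)) "json" else "sbml"
              }
  }
  switch(format,
         sbml = read_sbml_model(path),
         json = read_json_model(path))
}

#' Write a metabolic model to SBML or COBRA-JSON
#'
#' The written file read back with [read_model()] reproduces reaction ids,
#' bounds (to 1e-9), the stoichiometry and GPR strings byte-for-byte.
#'
#' @param g a [gem].
#' @param path output file.
#' @param format `"sbml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(g, path, format = c("sbml", "json")) {
  format <- match.arg(format)
  switch(format,
         sbml = write_sbml_model(g, path),
         json = write_json_model(g, path))
}
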