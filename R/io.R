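# Plain-text interchange formats: TSV edge lists and attribute tables,
# flat taxonomy code files, covariate tables, and JSON fit serialization.

#' Read / write a DDI edge list
#'
#' TSV with header `drug_a`, `drug_b`, `severity`, `type_label`; one row
#' per interaction record; UTF-8. Writing then reading a network's edges
#' is the identity on (pair, severity, type_label).
#'
#' @param path File path.
#' @return `read_edge_list`: data frame of interaction records.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  req <- c("drug_a", "drug_b")
  if (!all(req %in% names(df)))
    stop("edge list must have columns drug_a, drug_b")
  df
}

#' @rdname read_edge_list
#' @param net A `ddi_network` (its deduplicated edges are written).
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a drug attribute table
#'
#' TSV with header `drug_id`, `atc_codes`, `substructures`; multi-valued
#' fields are semicolon-separated.
#'
#' @param path File path.
#' @return `read_drug_attributes`: data frame usable by [build_network()].
#' @export
read_drug_attributes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (!"drug_id" %in% names(df))
    stop("attribute table must have a drug_id column")
  df
}

#' @rdname read_drug_attributes
#' @param net A `ddi_network`.
#' @export
write_drug_attributes <- function(net, path) {
  df <- data.frame(
    drug_id = net$drugs$drug_id,
    atc_codes = vapply(net$drugs$atc_codes, paste, character(1),
                       collapse = ";"),
    substructures = vapply(net$drugs$substructures, paste, character(1),
                           collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxonomy from a flat file of full codes
#'
#' One full code per line (comments with `#` and blank lines ignored).
#'
#' @param path File path.
#' @param level_prefixes Per-level cumulative prefix lengths; see
#'   [atc_taxonomy()].
#' @return An `atc_taxonomy`.
#' @export
read_taxonomy <- function(path, level_prefixes = c(1L, 3L, 4L, 5L, 7L)) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  atc_taxonomy(lines, level_prefixes)
}

#' Read / write a pair covariate table
#'
#' @param path File path.
#' @return `read_covariate_table`: the covariate data frame.
#' @export
read_covariate_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname read_covariate_table
#' @param table Covariate table from [build_covariate_table()].
#' @export
write_covariate_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize / restore a fitted model as JSON
#'
#' Coefficients, standard errors, p-values, AIC, convergence metadata and
#' (for mixed models) the variance component and per-drug intercepts.
#'
#' @param fit A `ppin_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  for (f in c("coefficients", "se", "p_values", "ranef"))
    if (!is.null(x[[f]])) x[[f]] <- as.list(x[[f]])  # keep names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @return `read_fit_json`: the restored `ppin_fit`.
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("coefficients", "se", "p_values", "ranef"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  x$covariates <- as.character(x$covariates)
  if (is.null(x$ranef)) x$ranef <- NULL
  if (is.null(x$varcomp)) x$varcomp <- NA_real_
  structure(x[c("model_class", "covariates", "coefficients", "se",
                "p_values", "aic", "loglik", "converged", "diagnostic",
                "varcomp", "ranef", "n_rows")],
            class = "ppin_fit")
}
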