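#' Construct an expression matrix
#'
#' The pipeline's central container: a numeric matrix of spot intensities
#' (relative fluorescence units, RFU) or derived quantities with samples in
#' rows and proteins in columns, tagged with a `provenance` attribute that
#' records which processing stage produced it.
#'
#' @param values Numeric matrix, rows = samples, columns = proteins. Must
#'   carry row and column names (the sample and protein registries).
#' @param provenance One of `"net"`, `"aggregated"`, `"normalized"`,
#'   `"fold_change"`, `"combat"`.
#' @return The matrix with class `expr_matrix` and a `provenance` attribute.
#' @export
expr_matrix <- function(values,
                        provenance = c("net", "aggregated", "normalized",
                                       "fold_change", "combat")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix requires sample (row) and protein (column) names")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (provenance %in% c("net", "aggregated", "normalized") && any(values < 0))
    stop("negative intensities are not allowed for provenance '",
         provenance, "'")
  structure(values, provenance = provenance, class = c("expr_matrix", "matrix"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d samples x %d proteins\n",
              provenance(x), nrow(x), ncol(x)))
  invisible(x)
}

#' @export
as.matrix.expr_matrix <- function(x, ...) unwrap(x)

#' Provenance of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character scalar.
#' @export
provenance <- function(m) {
  p <- attr(m, "provenance")
  if (is.null(p)) NA_character_ else p
}

# strip class/attr for raw matrix math
unwrap <- function(m) {
  attr(m, "provenance") <- NULL
  class(m) <- "matrix"
  m[, , drop = FALSE]
}

#' Write an expression matrix as wide TSV
#'
#' First column `sample_id`, remaining columns one per protein. Values are
#' written at full double precision so round trips are lossless.
#'
#' @param m An `expr_matrix`.
#' @param path Output file path.
#' @export
write_expr_matrix <- function(m, path) {
  dt <- data.table::data.table(sample_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(unwrap(m)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a wide TSV expression matrix
#'
#' @param path File written by [write_expr_matrix()].
#' @param provenance Provenance tag to assign (not stored in the TSV).
#' @return An `expr_matrix`.
#' @export
read_expr_matrix <- function(path, provenance = "aggregated") {
  dt <- data.table::fread(path, sep = "\t")
  if (!"sample_id" %in% names(dt))
    stop("expression matrix file lacks a 'sample_id' column: ", path)
  v <- as.matrix(dt[, -1])
  rownames(v) <- as.character(dt$sample_id)
  storage.mode(v) <- "double"
  expr_matrix(v, provenance)
}
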