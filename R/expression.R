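#' Expression matrix container
#'
#' A light container for a gene-by-sample expression matrix with a unit tag.
#' Values must be a numeric matrix with unique, non-empty row (gene) and
#' column (sample) names, free of missing values; counts and TPM matrices
#' must be non-negative.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames set.
#' @param unit one of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `unit`.
#' @export
expr_matrix <- function(values, unit = c("counts", "tpm", "log2tpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (unit %in% c("counts", "tpm") && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s' not allowed for unit '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]], unit))
  }
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expr_matrix
#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an `expr_matrix`.
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes not present in matrix: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("samples not present in matrix: ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expr_matrix(v, x$unit)
}

#' Log2-transform a TPM matrix
#'
#' Applies `log2(tpm + 1)`, the transform used upstream of subtype discovery
#' and classification. Values stay non-negative so the result remains a valid
#' input for non-negative factorization.
#'
#' @param x an `expr_matrix` with unit `"tpm"` (a `"counts"` matrix is
#'   refused; convert with [counts_to_tpm()] first).
#' @return An `expr_matrix` with unit `"log2tpm"`.
#' @export
log2_tpm <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit == "log2tpm") return(x)
  if (x$unit != "tpm") stop("log2_tpm() expects a 'tpm' matrix; got '", x$unit, "'")
  expr_matrix(log2(x$values + 1), "log2tpm")
}
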