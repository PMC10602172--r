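#' Expression matrix with a declared normalization
#'
#' Container for an entities-by-genes numeric matrix (cells, bulk samples, or
#' spatial spots in rows; genes in columns) carrying a normalization tag that
#' downstream calling rules check before applying themselves:
#'
#' * `ln_cpm1` — natural-log counts-per-million-plus-one; non-negative.
#' * `zscore`  — per-gene standardized expression; may be negative.
#' * `counts`  — raw counts; non-negative.
#'
#' @param values Numeric matrix with entity identifiers as row names and gene
#'   identifiers as column names. Sparse `Matrix` inputs are densified.
#' @param normalization One of `"ln_cpm1"`, `"zscore"`, `"counts"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `normalization`.
#' @examples
#' m <- matrix(c(3, 0, 2.6, 0.1), 2, dimnames = list(c("c1", "c2"),
#'                                                   c("KLRD1", "KLRC1")))
#' expression_matrix(m, "ln_cpm1")
#' @export
expression_matrix <- function(values,
                              normalization = c("ln_cpm1", "zscore", "counts")) {
  normalization <- match.arg(normalization)
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (nrow(values) == 0L) stop("no entities in expression matrix")
  if (ncol(values) == 0L) stop("no genes in expression matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("entity and gene identifiers are required as dimnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate entity identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate gene identifiers")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (normalization != "zscore" && any(values < 0)) {
    stop(sprintf("negative values are not allowed under '%s' normalization",
                 normalization))
  }
  structure(list(values = values, normalization = normalization),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d entities x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' Entity and gene identifiers of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
entity_ids <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  rownames(x$values)
}

#' @rdname entity_ids
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  colnames(x$values)
}

#' Extract expression values for one or more genes
#'
#' @param x An `ExpressionMatrix`.
#' @param gene Gene identifier(s); absent genes raise an error.
#' @return A named numeric vector (single gene) or entity-by-gene matrix.
#' @export
gene_values <- function(x, gene) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  absent <- setdiff(gene, colnames(x$values))
  if (length(absent)) {
    stop("gene(s) absent from expression matrix: ",
         paste(absent, collapse = ", "))
  }
  x$values[, gene, drop = length(gene) == 1L]
}

#' Read an expression matrix from disk
#'
#' Accepts a sparse matrix-exchange (`.mtx`) file or a dense tab-separated
#' matrix, with line-aligned gene and entity annotation files (one identifier
#' per line; extra tab-separated columns after the first are ignored). The
#' matrix is stored entities-by-genes.
#'
#' @param matrix_path Path to the `.mtx` or dense TSV matrix (rows = entities).
#' @param genes_path Path to the gene identifier file.
#' @param entities_path Path to the entity (cell/sample/spot) identifier file.
#' @param normalization Normalization tag, see [expression_matrix()].
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(matrix_path, genes_path, entities_path,
                            normalization = c("ln_cpm1", "zscore", "counts")) {
  normalization <- match.arg(normalization)
  read_ids <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  }
  genes <- read_ids(genes_path)
  entities <- read_ids(entities_path)
  if (grepl("\\.mtx$", matrix_path)) {
    m <- as.matrix(Matrix::readMM(matrix_path))
  } else {
    m <- as.matrix(utils::read.table(matrix_path, sep = "\t"))
  }
  if (nrow(m) == 0L || length(entities) == 0L) stop("no entities")
  if (nrow(m) != length(entities) || ncol(m) != length(genes)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but annotations give %d entities and %d genes",
      nrow(m), ncol(m), length(entities), length(genes)))
  }
  dimnames(m) <- list(entities, genes)
  expression_matrix(m, normalization)
}

#' Write an expression matrix to disk
#'
#' Writes the sparse matrix-exchange representation plus line-aligned gene and
#' entity identifier files, the inverse of [read_expression()].
#'
#' @param x An `ExpressionMatrix`.
#' @param matrix_path,genes_path,entities_path Output paths; `matrix_path`
#'   must end in `.mtx`.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, matrix_path, genes_path, entities_path) {
  stopifnot(inherits(x, "ExpressionMatrix"), grepl("\\.mtx$", matrix_path))
  Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), matrix_path)
  writeLines(colnames(x$values), genes_path)
  writeLines(rownames(x$values), entities_path)
  invisible(x)
}
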