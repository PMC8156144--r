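#' Read a gene expression matrix from a delimited text file
#'
#' Expression files are expected genes-in-rows (the dominant orientation of
#' public series matrices): the first column carries the gene or probe
#' identifier and the header row carries sample identifiers. Values are
#' assumed to be on the log2 scale already (see [log2_transform()] when they
#' are not). Duplicate gene rows (multiple probes per gene) are retained
#' verbatim; collapsing them is a separate, explicit step
#' ([collapse_probes()]).
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect Field separator convention, `"tsv"` (default) or `"csv"`.
#' @param transpose If `TRUE`, the file is samples-in-rows and is transposed
#'   after reading.
#' @return A numeric matrix, genes in rows (rownames = gene/probe ids),
#'   samples in columns (colnames = sample ids).
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"),
                                   transpose = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) {
    stop("malformed expression header in ", path,
         ": need an id column plus at least one sample column")
  }
  ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(values) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric expression value '%s' at row %d (%s), column %d (%s) of %s",
                 cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], ids[bad[1L, 1L]],
                 bad[1L, 2L], colnames(cells)[bad[1L, 2L]], path))
  }
  if (anyNA(values)) {
    na <- which(is.na(values), arr.ind = TRUE)
    stop(sprintf("missing expression value at row %d (%s), column %d of %s; missing values are not supported",
                 na[1L, 1L], ids[na[1L, 1L]], na[1L, 2L], path))
  }
  dimnames(values) <- list(ids, colnames(cells))
  if (transpose) values <- t(values)
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids in ", path)
  }
  values
}

#' Write an expression matrix to a delimited text file
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param id_column Header label for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, dialect = c("tsv", "csv"),
                                    id_column = "gene_id") {
  dialect <- match.arg(dialect)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  sep <- if (dialect == "tsv") "\t" else ","
  out <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c(id_column, colnames(m))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse multi-probe genes by averaging
#'
#' Rows sharing a gene id (multiple probes mapping to one gene) are replaced
#' by their arithmetic per-sample mean, the conventional probe-collapsing rule
#' for array data. Rows with unique ids pass through unchanged; row order of
#' first appearance is preserved. Idempotent.
#'
#' @param m Numeric matrix with (possibly duplicated) gene ids as rownames.
#' @param mapping Optional two-column data.frame (probe id, gene symbol)
#'   applied to rownames before collapsing; probes absent from the mapping
#'   keep their own id.
#' @return Matrix with one row per unique gene id.
#' @export
collapse_probes <- function(m, mapping = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  ids <- rownames(m)
  if (!is.null(mapping)) {
    stopifnot(ncol(mapping) >= 2L)
    idx <- match(ids, as.character(mapping[[1L]]))
    ids <- ifelse(is.na(idx), ids, as.character(mapping[[2L]])[idx])
  }
  if (!anyDuplicated(ids)) {
    rownames(m) <- ids
    return(m)
  }
  groups <- factor(ids, levels = unique(ids))
  collapsed <- rowsum(m, group = groups, reorder = FALSE) /
    as.vector(table(groups))
  rownames(collapsed) <- levels(groups)
  collapsed
}

#' Log2-transform an expression matrix
#'
#' Applies `log2(value + offset)` elementwise and marks the matrix so the
#' transform is never applied twice. [unlog2_transform()] inverts it.
#'
#' @param m Numeric matrix.
#' @param offset Non-negative pseudo-count added before taking logs.
#' @return Transformed matrix carrying attribute `log2_transformed = TRUE`.
#' @export
log2_transform <- function(m, offset = 0) {
  stopifnot(is.matrix(m), is.numeric(offset), length(offset) == 1L, offset >= 0)
  if (isTRUE(attr(m, "log2_transformed"))) {
    stop("matrix is already log2-transformed; refusing to transform twice")
  }
  shifted <- m + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("log2 transform undefined: value %g + offset %g <= 0 at gene '%s', sample '%s'",
                 m[bad[1L], bad[2L]], offset,
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]))
  }
  out <- log2(shifted)
  attr(out, "log2_transformed") <- TRUE
  out
}

#' Invert a log2 transform
#'
#' @param m Matrix produced by [log2_transform()].
#' @param offset The offset used in the forward transform.
#' @return Matrix on the original scale.
#' @export
unlog2_transform <- function(m, offset = 0) {
  stopifnot(is.matrix(m))
  out <- 2^m - offset
  attr(out, "log2_transformed") <- NULL
  out
}
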