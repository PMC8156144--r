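#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>symbol1<TAB>symbol2...`. Duplicate symbols within
#' a set are removed with a warning; each set must contain at least one
#' symbol.
#'
#' @param path Path to a `.gmt` file.
#' @return A `gene_set_collection`: a named list of character vectors of gene
#'   symbols, with per-set descriptions in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected at least 3 tab-separated fields, got %d",
                   i, length(fields)))
    }
    name <- fields[[1L]]
    symbols <- fields[-(1:2)]
    symbols <- symbols[nzchar(symbols)]
    if (anyDuplicated(symbols)) {
      warning(sprintf("gene set '%s' (line %d) contains duplicated symbols; deduplicated",
                      name, i))
      symbols <- unique(symbols)
    }
    if (length(symbols) == 0L) {
      stop(sprintf("gene set '%s' (line %d) is empty", name, i))
    }
    sets[[name]] <- symbols
    descriptions[[name]] <- fields[[2L]]
  }
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors (or a `gene_set_collection`).
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions;
#'   defaults to the `"descriptions"` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
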