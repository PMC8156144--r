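#' @keywords internal
.endpoints <- c("OS", "DFS", "DSS")

#' Canonical clinical column names
#' @keywords internal
.clinical_columns <- function() {
  c("sample_id", "response", "subtype", "grade", "stage", "chemotherapy",
    as.vector(t(outer(.endpoints, c("time", "event"), paste, sep = "_"))))
}

#' Read a per-sample clinical annotation table
#'
#' Parses a header-labelled delimited file into the canonical clinical layout:
#' `sample_id`, `response` (pCR / non_pCR / unknown), `subtype`, `grade`,
#' `stage`, `chemotherapy` (yes / no / unknown), and per-endpoint survival
#' columns `OS_time`/`OS_event`, `DFS_time`/`DFS_event`, `DSS_time`/`DSS_event`
#' (times in months, events coded 1 = occurred, 0 = censored). Columns absent
#' from the file become `"unknown"` (categorical) or `NA` (survival); nothing
#' is imputed.
#'
#' @param path Path to a TSV or CSV file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the file's header labels, e.g.
#'   `c(sample_id = "patient", response = "pcr_status")`. Canonical names
#'   found verbatim in the header need no entry.
#' @return A `data.frame` with the canonical columns.
#' @export
read_clinical <- function(path, dialect = c("tsv", "csv"), column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("clinical file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = c("NA", ""))
  canon <- .clinical_columns()
  pick <- function(col) {
    src <- if (!is.null(column_map) && col %in% names(column_map)) {
      column_map[[col]]
    } else col
    if (src %in% colnames(raw)) raw[[src]] else NULL
  }
  sample_id <- pick("sample_id")
  if (is.null(sample_id)) stop("clinical table must contain a sample_id column")
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample_id in clinical table: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  n <- length(sample_id)
  out <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  categorical <- function(x, allowed = NULL) {
    if (is.null(x)) return(rep("unknown", n))
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unknown"
    if (!is.null(allowed)) {
      bad <- setdiff(unique(x), c(allowed, "unknown"))
      if (length(bad)) {
        stop("unexpected value(s) ", paste(bad, collapse = ", "),
             "; expected one of ", paste(allowed, collapse = ", "))
      }
    }
    x
  }
  out$response <- categorical(pick("response"), c("pCR", "non_pCR"))
  out$subtype <- categorical(pick("subtype"))
  out$grade <- categorical(pick("grade"), c("1", "2", "3"))
  out$stage <- categorical(pick("stage"))
  out$chemotherapy <- categorical(pick("chemotherapy"), c("yes", "no"))
  for (ep in .endpoints) {
    tm <- pick(paste0(ep, "_time"))
    ev <- pick(paste0(ep, "_event"))
    tm <- if (is.null(tm)) rep(NA_real_, n) else as.numeric(tm)
    ev <- if (is.null(ev)) rep(NA_real_, n) else as.numeric(ev)
    if (any(tm < 0, na.rm = TRUE)) {
      stop("negative ", ep, "_time in clinical table")
    }
    if (any(!ev %in% c(0, 1) & !is.na(ev))) {
      stop(ep, "_event must be 0 (censored) or 1 (occurred)")
    }
    if (any(!is.na(tm) & is.na(ev))) {
      stop(ep, ": time present without event indicator")
    }
    out[[paste0(ep, "_time")]] <- tm
    out[[paste0(ep, "_event")]] <- ev
  }
  out
}

#' Write a clinical table
#'
#' @param clinical Clinical `data.frame` in the canonical layout (see
#'   [read_clinical()]).
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(clinical, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
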