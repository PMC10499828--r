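#' Read a single-cell feature table
#'
#' Reads and validates the CSV schema used throughout: one row per segmented
#' cell with `cell_id`, `core_id`, position in micrometres, a DAPI QC flag
#' and one mean-intensity column per marker.  Unknown columns are preserved
#' as passthrough.
#'
#' @param path CSV file path.
#' @param markers character vector of marker columns that must be present and
#'   numeric (optional).
#' @return validated data.frame.
#' @export
read_cell_table <- function(path, markers = NULL) {
  if (!file.exists(path)) stop(sprintf("cell table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("cell table is empty: %s", path))
  required <- c("cell_id", "core_id", "x_um", "y_um", "dapi_positive", markers)
  check_columns(df, required, sprintf("cell table '%s'", path))
  for (col in c("x_um", "y_um", markers)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d", col,
                   if (is.na(bad)) 1L else bad))
    }
    if (any(!is.finite(v))) {
      stop(sprintf("non-finite value in column '%s' at data row %d", col,
                   which(!is.finite(v))[1]))
    }
  }
  df$dapi_positive <- as.logical(df$dapi_positive)
  if (any(is.na(df$dapi_positive))) stop("dapi_positive must be logical or 0/1")
  if (anyDuplicated(df[c("core_id", "cell_id")])) {
    stop("(core_id, cell_id) pairs must be unique")
  }
  df
}

#' Write a single-cell feature table
#'
#' @param cells data.frame in the [read_cell_table()] schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a gene x sample count matrix (TSV, header row of sample IDs)
#'
#' @param path TSV path (first column = gene IDs).
#' @return integer matrix, genes x samples.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path))
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(m < 0)) stop("counts must be non-negative")
  m
}

#' @rdname read_counts_tsv
#' @param counts gene x sample matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival records (CSV: time, event, group)
#'
#' @param path CSV path.
#' @return data.frame with `time`, `event`, `group`.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("survival file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("time", "event", "group"), sprintf("survival table '%s'", path))
  df
}
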