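# Labeled-matrix CSV I/O (first column = gene id, header row = DCC ids),
# matching typical fold-change matrix exports.

#' Read a labeled gene x DCC matrix from CSV
#'
#' Expects a header row of DCC identifiers and gene identifiers in the
#' first column; comma separator, "." decimal, UTF-8.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix with gene rownames and DCC colnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (anyDuplicated(rownames(df)) || anyDuplicated(colnames(df))) {
    stop("duplicate gene or DCC identifiers in ", path, call. = FALSE)
  }
  x <- as.matrix(df)
  if (!is.numeric(x)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
    stop("non-numeric column '", colnames(df)[bad], "' in ", path,
         call. = FALSE)
  }
  if (anyNA(x)) stop("missing values in ", path, call. = FALSE)
  x
}

#' Write a labeled matrix to CSV
#'
#' Inverse of [read_matrix_csv()]; values survive a round trip to at
#' least 10 significant digits.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_column Name used for the identifier column header.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path, id_column = "gene") {
  df <- data.frame(rownames(x) %||% paste0("row", seq_len(nrow(x))),
                   x, check.names = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
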