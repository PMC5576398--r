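#' @include synthetic-data.R
NULL

#' Read and write indentation-record CSV files
#'
#' The on-disk exchange format for indentation records: a CSV with
#' header \code{combo,force_N,diameter_mm,replicate,width_mm}.
#'
#' @param records a record data.frame (see [indentationRecords()]).
#' @param path file path.
#' @param combo optional combo filter applied on read.
#' @return \code{writeIndentationCsv}: the path, invisibly;
#'   \code{readIndentationCsv}: a validated record data.frame.
#' @export
writeIndentationCsv <- function(records, path) {
  .validateRecords(records)
  cols <- c("combo", "force_N", "diameter_mm", "replicate", "width_mm")
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeIndentationCsv
#' @export
readIndentationCsv <- function(path, combo = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validateRecords(df)
  if (!is.null(combo)) {
    df <- df[df$combo %in% combo, , drop = FALSE]
    if (nrow(df) == 0L)
      stop("no records for combo(s) ", paste(combo, collapse = ", "),
           " in ", path, call. = FALSE)
    rownames(df) <- NULL
  }
  df
}
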