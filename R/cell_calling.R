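#' Call valid cell barcodes by total read count
#'
#' A barcode is retained iff its tagged-read count reaches `min_reads`
#' (inclusive). The default of 1000 reads suits a ~28-amplicon panel; the
#' threshold should be scaled to the number of amplicons profiled and the
#' desired per-amplicon depth.
#'
#' @param x either a tagged-read data frame (with a `barcode` column) or a
#'   named integer vector of per-barcode read counts.
#' @param min_reads minimum read count (inclusive, default 1000).
#' @return list with `cells` (character vector of retained barcodes) and
#'   `table` (data frame `barcode`, `n_reads`, `pass`).
#' @examples
#' call_cells(c(cellA = 1000L, cellB = 999L))$cells
#' @export
call_cells <- function(x, min_reads = 1000L) {
  stopifnot(min_reads >= 1L)
  counts <- if (is.data.frame(x)) {
    tab <- table(x$barcode)
    setNames(as.integer(tab), names(tab))
  } else {
    stopifnot(is.numeric(x))
    x
  }
  if (length(counts) == 0L)
    return(list(cells = character(0),
                table = data.frame(barcode = character(0),
                                   n_reads = integer(0),
                                   pass = logical(0))))
  tab <- data.frame(barcode = names(counts),
                    n_reads = as.integer(counts),
                    pass = as.integer(counts) >= min_reads,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$n_reads, tab$barcode), , drop = FALSE]
  rownames(tab) <- NULL
  list(cells = tab$barcode[tab$pass], table = tab)
}

#' Write the per-barcode cell-calling table
#'
#' @param calls result of [call_cells()].
#' @param path output TSV path.
#' @export
write_cell_calls <- function(calls, path) {
  write.table(calls$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
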