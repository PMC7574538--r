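#' Classify a read as modified or unmodified within the quantification window
#'
#' A read counts as modified iff any deletion's reference interval intersects
#' the half-open window `[cut - w, cut + w)`, any insertion's inter-base
#' anchor lies in the closed interval `[cut - w, cut + w]`, or -- when
#' `count_substitutions` is on -- any substitution falls inside the half-open
#' window. The asymmetric interval treatment keeps insertions exactly at the
#' cut point inside the window on both sides.
#'
#' @param alignment a `read_alignment` to the amplicon's reference.
#' @param amp the [amplicon()] the read is aligned to (must carry a window).
#' @param count_substitutions whether window substitutions count as edits
#'   (default `FALSE`: NHEJ indels only).
#' @return logical scalar.
#' @export
classify_read <- function(alignment, amp, count_substitutions = FALSE) {
  stopifnot(inherits(alignment, "read_alignment"), inherits(amp, "amplicon"))
  if (is.null(amp$window))
    stop("amplicon '", amp$amplicon_id,
         "' has no quantification window (control)")
  ws <- amp$window[1]; we <- amp$window[2]
  ops <- alignment$ops
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; p <- ops$ref_pos[i]; l <- ops$len[i]
    if (op == "D") {
      if (p < we && p + l > ws) return(TRUE)
    } else if (op == "I") {
      if (p >= ws && p <= we) return(TRUE)
    } else if (op == "X" && count_substitutions) {
      if (p < we && p + l > ws) return(TRUE)
    }
  }
  FALSE
}

#' Window-projected allele sequence of an aligned read
#'
#' Projects the read onto the reference interval `window +/- flank`: matched
#' read bases in place, `-` for deleted reference bases, inserted bases at
#' their anchors, and `.` where the alignment does not cover the interval.
#' This projected string is the allele identity used for allele tabulation,
#' so sequencing errors far from the cut site do not fragment alleles.
#'
#' @inheritParams classify_read
#' @param flank flanking bases on each side of the window (default 10).
#' @return character scalar.
#' @export
window_allele <- function(alignment, amp, flank = 10L) {
  stopifnot(inherits(alignment, "read_alignment"), inherits(amp, "amplicon"))
  if (is.null(amp$window))
    stop("amplicon '", amp$amplicon_id, "' has no quantification window")
  lo <- max(0L, amp$window[1] - flank)
  hi <- min(nchar(amp$ref_seq), amp$window[2] + flank)
  L <- hi - lo
  base <- rep(".", L)
  ins <- rep("", L + 1L)
  q <- strsplit(alignment$read_seq, "")[[1]]
  read_cursor <- 0L
  # walk ops in order, tracking consumed read bases
  ops <- alignment$ops
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; p <- ops$ref_pos[i]; l <- ops$len[i]
    if (op %in% c("M", "X")) {
      for (k in seq_len(l)) {
        rp <- p + k - 1L
        if (rp >= lo && rp < hi) base[rp - lo + 1L] <- q[read_cursor + k]
      }
      read_cursor <- read_cursor + l
    } else if (op == "D") {
      for (k in seq_len(l)) {
        rp <- p + k - 1L
        if (rp >= lo && rp < hi) base[rp - lo + 1L] <- "-"
      }
    } else { # I
      if (p >= lo && p <= hi)
        ins[p - lo + 1L] <- paste0(ins[p - lo + 1L],
                                   paste(q[read_cursor + seq_len(l)],
                                         collapse = ""))
      read_cursor <- read_cursor + l
    }
  }
  paste0(paste0(ins[seq_len(L)], base, collapse = ""), ins[L + 1L])
}

#' Summarize one cell-amplicon: modification rate and top two alleles
#'
#' Groups the cell-amplicon's reads by window-projected allele sequence and
#' reports the number of aligned reads, the percentage of modified reads,
#' and the modification state and frequency of the two most frequent alleles
#' (count ties broken lexicographically by allele sequence). Heterozygosity
#' is the frequency of the second-most-frequent allele, in percent. With
#' fewer than `min_reads` reads the summary is a NO_CALL (`called = FALSE`,
#' statistics `NA`).
#'
#' @param modified logical vector, per-read modification state.
#' @param allele_seq character vector, per-read window-projected allele.
#' @param barcode,amplicon_id identifiers stamped into the output row.
#' @param min_reads minimum reads to emit a call (default 5).
#' @return one-row data frame (`barcode`, `amplicon_id`, `n_reads`,
#'   `called`, `pct_modified`, `allele1_seq`, `allele1_modified`,
#'   `allele1_freq`, `allele2_seq`, `allele2_modified`, `allele2_freq`,
#'   `heterozygosity`).
#' @export
summarize_cell_amplicon <- function(modified, allele_seq, barcode = "cell",
                                    amplicon_id = "amplicon",
                                    min_reads = 5L) {
  stopifnot(length(modified) == length(allele_seq))
  n <- length(modified)
  row <- data.frame(barcode = barcode, amplicon_id = amplicon_id,
                    n_reads = n, called = FALSE,
                    pct_modified = NA_real_,
                    allele1_seq = NA_character_,
                    allele1_modified = NA, allele1_freq = NA_real_,
                    allele2_seq = NA_character_,
                    allele2_modified = NA, allele2_freq = NA_real_,
                    heterozygosity = NA_real_,
                    stringsAsFactors = FALSE)
  if (n < min_reads) return(row)
  tab <- data.frame(allele = allele_seq, modified = modified,
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(count = rep(1L, n), nmod = as.integer(modified))
                          ~ allele, data = tab, FUN = sum)
  agg$modified <- agg$nmod * 2L > agg$count
  agg <- agg[order(-agg$count, agg$allele), , drop = FALSE]
  row$called <- TRUE
  row$pct_modified <- 100 * sum(modified) / n
  row$allele1_seq <- agg$allele[1]
  row$allele1_modified <- agg$modified[1]
  row$allele1_freq <- agg$count[1] / n
  if (nrow(agg) >= 2L) {
    row$allele2_seq <- agg$allele[2]
    row$allele2_modified <- agg$modified[2]
    row$allele2_freq <- agg$count[2] / n
    row$heterozygosity <- 100 * agg$count[2] / n
  } else {
    row$heterozygosity <- 0
  }
  row
}

#' Per-cell, per-amplicon edit quantification
#'
#' The pipeline core: assigns every tagged read to its best panel amplicon,
#' classifies it against the amplicon's quantification window, and
#' summarizes each (cell, amplicon) group -- read count, percent modified,
#' top two alleles -- exactly as [summarize_cell_amplicon()] does, but in a
#' single grouped pass.
#'
#' @param tagged tagged-read data frame (`read_id`, `barcode`, `payload`).
#' @param pan an `amplicon_panel`.
#' @param cells optional character vector of valid cell barcodes (e.g. from
#'   [call_cells()]); reads from other barcodes are dropped first.
#' @param scoring an [alignment_scoring()].
#' @param min_identity minimum alignment identity for assignment.
#' @param min_reads minimum reads per cell-amplicon for a call (default 5).
#' @param count_substitutions whether window substitutions count as edits.
#' @param flank allele-projection flank (default 10).
#' @param prescreen use k-mer prescreening of candidate amplicons
#'   (default `TRUE`; exact rescoring of every amplicon when `FALSE`).
#' @return list of class `cell_edit_calls`: `summaries` (per cell-amplicon
#'   data frame as in [summarize_cell_amplicon()]), `matrix` (an
#'   [edit_matrix]), and `assignment` (read-level tallies).
#' @export
quantify_cells <- function(tagged, pan, cells = NULL,
                           scoring = alignment_scoring(),
                           min_identity = 0.65, min_reads = 5L,
                           count_substitutions = FALSE, flank = 10L,
                           prescreen = TRUE) {
  stopifnot(inherits(pan, "amplicon_panel"))
  if (!is.null(cells)) tagged <- tagged[tagged$barcode %in% cells, ,
                                        drop = FALSE]
  asg <- assign_batch(tagged$payload, pan, scoring, min_identity,
                      count_substitutions, flank, prescreen)
  assignment <- list(
    n_reads = nrow(asg),
    n_assigned = sum(asg$reason == "assigned"),
    n_ambiguous = sum(asg$reason == "ambiguous"),
    n_low_identity = sum(asg$reason == "low_identity"),
    per_amplicon = table(factor(asg$amplicon_id, levels = panel_ids(pan))))
  dt <- data.table::data.table(barcode = tagged$barcode,
                               amplicon_id = asg$amplicon_id,
                               modified = asg$modified,
                               allele = asg$allele)
  dt <- dt[!is.na(amplicon_id)]
  summaries <- summarize_groups(dt, min_reads)
  mat <- build_edit_matrix(summaries,
                           cells = if (is.null(cells)) NULL else cells,
                           pan = pan, min_reads = min_reads)
  structure(list(summaries = summaries, matrix = mat,
                 assignment = assignment),
            class = "cell_edit_calls")
}

# grouped equivalent of summarize_cell_amplicon over a data.table
summarize_groups <- function(dt, min_reads) {
  cov <- dt[, list(n_reads = .N,
                   pct_modified = 100 * mean(modified)),
            by = list(barcode, amplicon_id)]
  al <- dt[!is.na(allele),
           list(count = .N, nmod = sum(modified)),
           by = list(barcode, amplicon_id, allele)]
  data.table::setorder(al, barcode, amplicon_id, -count, allele)
  top <- al[, list(
    allele1_seq = allele[1],
    allele1_modified = if (.N >= 1L) nmod[1] * 2L > count[1] else NA,
    allele1_count = count[1],
    allele2_seq = if (.N >= 2L) allele[2] else NA_character_,
    allele2_modified = if (.N >= 2L) nmod[2] * 2L > count[2] else NA,
    allele2_count = if (.N >= 2L) count[2] else 0L),
    by = list(barcode, amplicon_id)]
  out <- merge(cov, top, by = c("barcode", "amplicon_id"), all.x = TRUE)
  out[, called := n_reads >= min_reads]
  out[, `:=`(allele1_freq = allele1_count / n_reads,
             allele2_freq = allele2_count / n_reads,
             heterozygosity = 100 * allele2_count / n_reads)]
  # amplicons without a window (controls) have NA modified states: coverage
  # only, no modification statistics
  out[is.na(allele1_seq), `:=`(allele1_freq = NA_real_,
                               allele2_freq = NA_real_,
                               heterozygosity = NA_real_)]
  out[called == FALSE, `:=`(pct_modified = NA_real_,
                            allele1_seq = NA_character_,
                            allele1_modified = NA,
                            allele1_freq = NA_real_,
                            allele2_seq = NA_character_,
                            allele2_modified = NA,
                            allele2_freq = NA_real_,
                            heterozygosity = NA_real_)]
  out[, `:=`(allele1_count = NULL, allele2_count = NULL)]
  data.table::setcolorder(out, c("barcode", "amplicon_id", "n_reads",
                                 "called", "pct_modified"))
  as.data.frame(out)
}

#' Edit matrix: cells x amplicons percent-modified with coverage companion
#'
#' Builds the per-cell modification-rate matrix from cell-amplicon
#' summaries. An entry is present iff its coverage reaches `min_reads`;
#' insufficient coverage is an explicit `NA` (MISSING). A parallel coverage
#' matrix holds raw read counts.
#'
#' @param summaries data frame as produced by [quantify_cells()] /
#'   [summarize_cell_amplicon()].
#' @param cells optional row universe (default: barcodes observed).
#' @param pan optional `amplicon_panel` fixing the column universe and
#'   carrying per-amplicon categories.
#' @param min_reads coverage threshold (default 5).
#' @return object of class `edit_matrix`: list with `pct` (numeric matrix,
#'   NA = missing), `coverage` (integer matrix), `categories` (named
#'   character or NULL), `min_reads`.
#' @export
build_edit_matrix <- function(summaries, cells = NULL, pan = NULL,
                              min_reads = 5L) {
  if (anyDuplicated(summaries[, c("barcode", "amplicon_id")]))
    stop("duplicate (barcode, amplicon_id) summary")
  rows <- if (is.null(cells)) sort(unique(summaries$barcode)) else cells
  cols <- if (is.null(pan)) sort(unique(summaries$amplicon_id))
          else panel_ids(pan)
  pct <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(rows, cols))
  cov <- matrix(0L, length(rows), length(cols),
                dimnames = list(rows, cols))
  keep <- summaries$barcode %in% rows & summaries$amplicon_id %in% cols
  s <- summaries[keep, , drop = FALSE]
  idx <- cbind(match(s$barcode, rows), match(s$amplicon_id, cols))
  cov[idx] <- s$n_reads
  called <- s$n_reads >= min_reads
  pct[idx[called, , drop = FALSE]] <- s$pct_modified[called]
  structure(list(pct = pct, coverage = cov,
                 categories = if (is.null(pan)) NULL else panel_categories(pan),
                 min_reads = as.integer(min_reads)),
            class = "edit_matrix")
}

#' @exportS3Method base::print
print.edit_matrix <- function(x, ...) {
  cat("<edit_matrix> ", nrow(x$pct), " cells x ", ncol(x$pct),
      " amplicons, ", sum(is.na(x$pct)), " missing entries (min_reads=",
      x$min_reads, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.edit_matrix <- function(x, ...) x$pct

#' Write an edit matrix as TSV and MatrixMarket
#'
#' Writes `<prefix>_pct.tsv` and `<prefix>_coverage.tsv` (dense, NA for
#' missing), plus `<prefix>_pct.mtx` with `<prefix>_rows.txt` /
#' `<prefix>_cols.txt` index files (sparse; only called entries stored).
#'
#' @param em an `edit_matrix`.
#' @param prefix output path prefix.
#' @export
write_edit_matrix <- function(em, prefix) {
  write.table(data.frame(barcode = rownames(em$pct), em$pct,
                         check.names = FALSE),
              paste0(prefix, "_pct.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(barcode = rownames(em$coverage), em$coverage,
                         check.names = FALSE),
              paste0(prefix, "_coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  present <- which(!is.na(em$pct), arr.ind = TRUE)
  sp <- Matrix::sparseMatrix(i = present[, 1], j = present[, 2],
                             x = em$pct[present],
                             dims = dim(em$pct))
  Matrix::writeMM(sp, paste0(prefix, "_pct.mtx"))
  writeLines(rownames(em$pct), paste0(prefix, "_rows.txt"))
  writeLines(colnames(em$pct), paste0(prefix, "_cols.txt"))
  invisible(prefix)
}

#' Bulk (pooled) edit quantification
#'
#' Treats the whole read set as one pseudo-cell: assigns each read to its
#' best amplicon and applies the same quantification-window rule, yielding
#' per-amplicon percent modified, as in pooled amplicon NGS validation of
#' editing.
#'
#' @param reads data frame with `read_id`, `seq` (amplicon reads, no cell
#'   barcodes).
#' @param pan an `amplicon_panel`.
#' @inheritParams quantify_cells
#' @return data frame `amplicon_id`, `n_reads`, `pct_modified`, `called`.
#' @export
quantify_bulk <- function(reads, pan, scoring = alignment_scoring(),
                          min_identity = 0.65, min_reads = 5L,
                          count_substitutions = FALSE, prescreen = TRUE) {
  if (nrow(reads) == 0L)
    return(data.frame(amplicon_id = character(0), n_reads = integer(0),
                      pct_modified = numeric(0), called = logical(0)))
  asg <- assign_batch(reads$seq, pan, scoring, min_identity,
                      count_substitutions, prescreen = prescreen)
  asg <- asg[!is.na(asg$amplicon_id), , drop = FALSE]
  ids <- panel_ids(pan)
  out <- do.call(rbind, lapply(ids, function(id) {
    sel <- asg$amplicon_id == id
    n <- sum(sel)
    pct <- if (n > 0L && !all(is.na(asg$modified[sel])))
      100 * mean(asg$modified[sel]) else NA_real_
    data.frame(amplicon_id = id, n_reads = n,
               pct_modified = if (n >= min_reads) pct else NA_real_,
               called = n >= min_reads, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
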