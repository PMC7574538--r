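#' Alignment scoring parameters
#'
#' Affine-gap scoring for the semi-global aligner: a gap of length L is
#' penalized `gap_open + L * gap_extend`. Defaults follow the conventions
#' of end-to-end short-read aligners.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (>= 0, applied as a subtraction).
#' @param gap_open gap-opening penalty (>= 0).
#' @param gap_extend per-base gap-extension penalty (>= 0).
#' @return object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2L, mismatch = 3L, gap_open = 5L,
                              gap_extend = 1L) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "alignment_scoring")
}

#' Semi-global pairwise alignment of a read to a reference
#'
#' Optimal affine-gap alignment that is global in the read and free at both
#' reference ends (the read may land anywhere inside the amplicon).
#' Traceback is deterministic (deletion before insertion before diagonal at
#' score ties) and indels are subsequently shifted to their leftmost
#' alignment-equivalent placement, so repeated runs produce identical
#' operation lists.
#'
#' @param read_seq,ref_seq DNA strings (non-empty).
#' @param scoring an [alignment_scoring()].
#' @return object of class `read_alignment`: `score`, 0-based half-open
#'   reference span `ref_start`/`ref_end`, `ops` (data frame `op` in
#'   M/X/I/D, `len`, `ref_pos`), `matches`, `columns` and
#'   `identity = matches / columns`.
#' @examples
#' aln <- align_semiglobal("ACGTAC", "TTACGTACTT")
#' aln$score
#' @export
align_semiglobal <- function(read_seq, ref_seq,
                             scoring = alignment_scoring()) {
  read_seq <- toupper(as.character(read_seq))
  ref_seq <- toupper(as.character(ref_seq))
  stopifnot(nzchar(read_seq), nzchar(ref_seq))
  res <- sg_align_cpp(read_seq, ref_seq, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  res$read_seq <- read_seq
  res$ref_seq <- ref_seq
  res$amplicon_id <- NA_character_
  class(res) <- "read_alignment"
  res
}

#' @exportS3Method base::print
print.read_alignment <- function(x, ...) {
  cat("<read_alignment>", if (!is.na(x$amplicon_id)) x$amplicon_id else "",
      " score=", x$score, " ref[", x$ref_start, ",", x$ref_end,
      ") identity=", round(x$identity, 3), "\n", sep = "")
  cigar <- paste0(x$ops$len, x$ops$op, collapse = "")
  cat("  ", cigar, "\n", sep = "")
  invisible(x)
}

#' Assign a read to its best-matching panel amplicon
#'
#' Scores the read against every amplicon reference in both orientations and
#' keeps the best; the read is `UNASSIGNED` when the best identity falls
#' below `min_identity` or when the best score is tied across two or more
#' amplicons (ambiguous).
#'
#' @param read a payload DNA string (or one row of a tagged-read data
#'   frame).
#' @param pan an `amplicon_panel`.
#' @param scoring an [alignment_scoring()].
#' @param min_identity minimum alignment identity for assignment
#'   (default 0.65).
#' @return list with `amplicon_id` (or `NA`), `reason` (`assigned`,
#'   `ambiguous` or `low_identity`), `strand` and `alignment`
#'   (a `read_alignment` of the read, oriented to the forward reference).
#' @export
assign_amplicon <- function(read, pan, scoring = alignment_scoring(),
                            min_identity = 0.65) {
  stopifnot(inherits(pan, "amplicon_panel"))
  seq <- if (is.data.frame(read)) read$payload[1] else as.character(read)
  seq <- toupper(seq)
  ids <- panel_ids(pan)
  sc_f <- sc_r <- integer(length(ids))
  for (k in seq_along(ids)) {
    ref <- pan$amplicons[[k]]$ref_seq
    sc_f[k] <- sg_score_cpp(seq, ref, scoring$match, scoring$mismatch,
                            scoring$gap_open, scoring$gap_extend)
    sc_r[k] <- sg_score_cpp(seq, revcomp(ref), scoring$match,
                            scoring$mismatch, scoring$gap_open,
                            scoring$gap_extend)
  }
  per_ref <- pmax(sc_f, sc_r)
  best <- max(per_ref)
  winners <- which(per_ref == best)
  if (length(winners) >= 2L)
    return(list(amplicon_id = NA_character_, reason = "ambiguous",
                strand = NA_character_, alignment = NULL))
  k <- winners[1L]
  strand <- if (sc_f[k] >= sc_r[k]) "+" else "-"
  oriented <- if (strand == "+") seq else revcomp(seq)
  aln <- align_semiglobal(oriented, pan$amplicons[[k]]$ref_seq, scoring)
  aln$amplicon_id <- ids[k]
  if (aln$identity < min_identity)
    return(list(amplicon_id = NA_character_, reason = "low_identity",
                strand = strand, alignment = aln))
  list(amplicon_id = ids[k], reason = "assigned", strand = strand,
       alignment = aln)
}

# Batch assignment + window classification used by the pipeline. Works on
# unique payload sequences (droplet amplicon reads are highly redundant) and
# optionally prescreens candidate amplicons by shared 8-mers before the DP.
assign_batch <- function(payloads, pan, scoring = alignment_scoring(),
                         min_identity = 0.65, count_substitutions = FALSE,
                         flank = 10L, prescreen = TRUE) {
  ids <- panel_ids(pan)
  refs <- vapply(pan$amplicons, `[[`, character(1), "ref_seq")
  ws <- vapply(pan$amplicons, function(a)
    if (is.null(a$window)) -1L else a$window[1], integer(1))
  we <- vapply(pan$amplicons, function(a)
    if (is.null(a$window)) -1L else a$window[2], integer(1))
  uq <- unique(payloads)
  res <- assign_reads_cpp(uq, unname(refs), unname(ws), unname(we),
                          as.integer(flank), scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend,
                          min_identity, count_substitutions, prescreen)
  ix <- match(payloads, uq)
  data.frame(amplicon_id = ids[res$amplicon][ix],
             strand = res$strand[ix],
             score = res$score[ix],
             identity = res$identity[ix],
             modified = res$modified[ix],
             allele = res$allele[ix],
             reason = res$reason[ix],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Export read alignments against amplicon references as SAM
#'
#' Writes a minimal SAM file (amplicons as reference sequences) for
#' inspection in standard viewers.
#'
#' @param tagged tagged-read data frame (`read_id`, `barcode`, `payload`).
#' @param pan an `amplicon_panel`.
#' @param path output SAM path.
#' @param scoring an [alignment_scoring()].
#' @param min_identity minimum identity for assignment.
#' @export
write_sam <- function(tagged, pan, path, scoring = alignment_scoring(),
                      min_identity = 0.65) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (a in pan$amplicons)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", a$amplicon_id,
                       nchar(a$ref_seq)), con)
  for (i in seq_len(nrow(tagged))) {
    hit <- assign_amplicon(tagged$payload[i], pan, scoring, min_identity)
    if (is.na(hit$amplicon_id)) {
      writeLines(paste(tagged$read_id[i], 4, "*", 0, 0, "*", "*", 0, 0,
                       tagged$payload[i], "*", sep = "\t"), con)
      next
    }
    aln <- hit$alignment
    ops <- aln$ops
    # SAM M covers both matches and mismatches
    sam_op <- ifelse(ops$op %in% c("M", "X"), "M", ops$op)
    cigar <- paste0(ops$len, sam_op, collapse = "")
    flag <- if (hit$strand == "-") 16L else 0L
    seq_out <- if (hit$strand == "-") revcomp(tagged$payload[i])
               else tagged$payload[i]
    writeLines(paste(tagged$read_id[i], flag, hit$amplicon_id,
                     aln$ref_start + 1L, 60, cigar, "*", 0, 0, seq_out, "*",
                     paste0("BC:Z:", tagged$barcode[i]), sep = "\t"), con)
  }
  invisible(path)
}
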