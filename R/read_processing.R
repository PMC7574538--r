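#' Read structure of the barcoded droplet library
#'
#' Reads carry two 9-nt cell barcode segments interleaved with three constant
#' segments, followed by the amplicon payload:
#' `constant1 + BC1 + constant2 + BC2 + constant3 + payload`.
#' The constant sequences of the commercial library are not public, so the
#' structure is fully configurable; the defaults are the self-consistent
#' placeholders used by the simulator.
#'
#' @param constant1,constant2,constant3 constant segments (DNA strings).
#' @param barcode_len length of each barcode segment (default 9).
#' @param max_constant_mismatches mismatches tolerated per constant segment
#'   (default 0, exact matching).
#' @return object of class `read_structure`.
#' @export
read_structure <- function(constant1 = "TCAGACGTGC",
                           constant2 = "GTACTCGCAG",
                           constant3 = "CTGAGTCGTA",
                           barcode_len = 9L,
                           max_constant_mismatches = 0L) {
  stopifnot(nzchar(constant1), nzchar(constant2), nzchar(constant3),
            barcode_len >= 1L, max_constant_mismatches >= 0L)
  structure(list(constant1 = toupper(constant1),
                 constant2 = toupper(constant2),
                 constant3 = toupper(constant3),
                 barcode_len = as.integer(barcode_len),
                 max_constant_mismatches = as.integer(max_constant_mismatches)),
            class = "read_structure")
}

#' Read a FASTQ file into a read-record data frame
#'
#' @param path FASTQ file, optionally gzip-compressed.
#' @return data frame with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write read records to FASTQ
#'
#' @param reads data frame with `read_id`, `seq` and optionally `qual`
#'   (a flat quality of "I" is written when absent).
#' @param path output path; `.gz` suffix triggers compression.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads) && !anyNA(reads$qual)) reads$qual
          else strrep("I", nchar(reads$seq))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(qual))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  sum(ra[seq_len(n)] != rb[seq_len(n)])
}

# Compare an observed segment to an expected constant; truncated reads are
# compared over the available prefix only.
constant_ok <- function(observed, expected, max_mm) {
  exp_trim <- substr(rep(expected, length(observed)), 1L, nchar(observed))
  ok <- observed == exp_trim
  if (max_mm > 0L && any(!ok)) {
    idx <- which(!ok)
    ok[idx] <- mapply(function(o, e) hamming(o, e) <= max_mm,
                      observed[idx], exp_trim[idx])
  }
  ok
}

#' Extract cell barcodes and trim constant regions
#'
#' Locates the three constant segments at their fixed offsets, extracts the
#' two barcode segments, and trims everything up to the payload. Reads are
#' retained only if the concatenated barcode reaches `min_barcode` bases and
#' the payload reaches `min_payload` bases; all failures are tallied as
#' discard reasons, never errors.
#'
#' @param reads data frame with `read_id`, `seq` (and optionally `qual`).
#' @param structure a [read_structure()].
#' @param min_payload minimum payload length of retained reads (default 46).
#' @param min_barcode minimum combined barcode length (default 18).
#' @return data frame with columns `read_id`, `barcode`, `payload`, `status`
#'   where `status` is one of `ok`, `short_read`, `short_barcode`,
#'   `structure_not_found`.
#' @export
extract_and_trim <- function(reads, structure = read_structure(),
                             min_payload = 46L, min_barcode = 18L) {
  stopifnot(inherits(structure, "read_structure"))
  s <- toupper(reads$seq)
  n1 <- nchar(structure$constant1)
  n2 <- nchar(structure$constant2)
  n3 <- nchar(structure$constant3)
  bl <- structure$barcode_len
  mm <- structure$max_constant_mismatches

  o1 <- 0L
  o_b1 <- n1
  o2 <- n1 + bl
  o_b2 <- n1 + bl + n2
  o3 <- n1 + 2L * bl + n2
  o_pl <- n1 + 2L * bl + n2 + n3

  c1 <- substr(s, o1 + 1L, n1)
  c2 <- substr(s, o2 + 1L, o2 + n2)
  c3 <- substr(s, o3 + 1L, o3 + n3)
  b1 <- substr(s, o_b1 + 1L, o_b1 + bl)
  b2 <- substr(s, o_b2 + 1L, o_b2 + bl)
  payload <- substr(s, o_pl + 1L, nchar(s))

  ok_struct <- constant_ok(c1, structure$constant1, mm) &
    constant_ok(c2, structure$constant2, mm) &
    constant_ok(c3, structure$constant3, mm)
  barcode <- paste0(b1, b2)

  status <- rep("ok", length(s))
  status[nchar(payload) < min_payload] <- "short_read"
  status[nchar(barcode) < min_barcode] <- "short_barcode"
  status[!ok_struct] <- "structure_not_found"

  data.frame(read_id = reads$read_id, barcode = barcode, payload = payload,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter and trim a read stream
#'
#' Applies [extract_and_trim()] to every read and tallies the outcome.
#' Conservation holds by construction: `input = retained + sum(discards)`.
#'
#' @inheritParams extract_and_trim
#' @return list with `tagged` (data frame `read_id`, `barcode`, `payload` of
#'   retained reads) and `stats` (class `filter_stats`: counters `input`,
#'   `retained`, `short_read`, `short_barcode`, `structure_not_found`).
#' @export
filter_reads <- function(reads, structure = read_structure(),
                         min_payload = 46L, min_barcode = 18L) {
  ext <- extract_and_trim(reads, structure, min_payload, min_barcode)
  stats <- structure(list(
    input = nrow(ext),
    retained = sum(ext$status == "ok"),
    short_read = sum(ext$status == "short_read"),
    short_barcode = sum(ext$status == "short_barcode"),
    structure_not_found = sum(ext$status == "structure_not_found")),
    class = "filter_stats")
  list(tagged = ext[ext$status == "ok",
                    c("read_id", "barcode", "payload")],
       stats = stats)
}

#' @exportS3Method base::print
print.filter_stats <- function(x, ...) {
  cat("<filter_stats> input=", x$input, " retained=", x$retained,
      " short_read=", x$short_read, " short_barcode=", x$short_barcode,
      " structure_not_found=", x$structure_not_found, "\n", sep = "")
  invisible(x)
}

#' Write filter statistics as JSON
#'
#' @param stats a `filter_stats` object.
#' @param path output path.
#' @export
write_filter_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE)
  invisible(path)
}

#' Write tagged reads as FASTQ with the barcode in the read name
#'
#' @param tagged data frame with `read_id`, `barcode`, `payload`.
#' @param path output FASTQ path.
#' @param delim delimiter between read id and barcode (default `":BC:"`).
#' @export
write_tagged_fastq <- function(tagged, path, delim = ":BC:") {
  write_fastq(data.frame(read_id = paste0(tagged$read_id, delim,
                                          tagged$barcode),
                         seq = tagged$payload,
                         stringsAsFactors = FALSE),
              path)
}

merge_one <- function(s1, q1, s2rc, q2rc, min_overlap, max_mismatch_frac) {
  n1 <- nchar(s1); n2 <- nchar(s2rc)
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2rc, "")[[1]]
  overlaps <- if (min(n1, n2) >= min_overlap) seq(min(n1, n2), min_overlap)
              else integer(0)
  for (o in overlaps) {
    ov1 <- a[(n1 - o + 1L):n1]
    ov2 <- b[seq_len(o)]
    mism <- which(ov1 != ov2)
    if (length(mism) <= floor(o * max_mismatch_frac)) {
      # consensus: higher-quality base wins at conflicts
      if (length(mism)) {
        qa <- strsplit(q1, "")[[1]][(n1 - o + 1L):n1]
        qb <- strsplit(q2rc, "")[[1]][seq_len(o)]
        take_b <- vapply(mism, function(k)
          utf8ToInt(qb[k]) > utf8ToInt(qa[k]), logical(1))
        ov1[mism[take_b]] <- ov2[mism[take_b]]
      }
      merged <- paste0(substr(s1, 1L, n1 - o),
                       paste(ov1, collapse = ""),
                       substr(s2rc, o + 1L, n2))
      qual <- paste0(substr(q1, 1L, n1 - o),
                     substr(q1, n1 - o + 1L, n1),
                     substr(q2rc, o + 1L, n2))
      return(list(seq = merged, qual = qual, overlap = o))
    }
  }
  # force-merge: no acceptable overlap, concatenate
  list(seq = paste0(s1, s2rc), qual = paste0(q1, q2rc), overlap = 0L)
}

#' Merge a read pair into a single pseudo-read
#'
#' The mate is reverse-complemented and the largest overlap of at least
#' `min_overlap` bases with a mismatch fraction below `max_mismatch_frac` is
#' consumed; at conflicting overlap positions the base with higher quality
#' wins. Pairs with no acceptable overlap are force-merged by concatenation,
#' so every pair yields a read.
#'
#' @param reads1,reads2 data frames with `read_id`, `seq`, optionally `qual`
#'   (R2 in original orientation).
#' @param min_overlap minimum acceptable overlap (default 10).
#' @param max_mismatch_frac maximum fraction of mismatching overlap
#'   positions (default 0.1).
#' @return data frame of merged read records (`read_id`, `seq`, `qual`).
#' @export
merge_pairs <- function(reads1, reads2, min_overlap = 10L,
                        max_mismatch_frac = 0.1) {
  stopifnot(nrow(reads1) == nrow(reads2))
  q1 <- if ("qual" %in% names(reads1)) reads1$qual
        else strrep("I", nchar(reads1$seq))
  q2 <- if ("qual" %in% names(reads2)) reads2$qual
        else strrep("I", nchar(reads2$seq))
  s2rc <- revcomp(reads2$seq)
  q2rc <- vapply(strsplit(q2, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  out <- vector("list", nrow(reads1))
  for (i in seq_len(nrow(reads1))) {
    m <- merge_one(toupper(reads1$seq[i]), q1[i], s2rc[i], q2rc[i],
                   min_overlap, max_mismatch_frac)
    out[[i]] <- data.frame(read_id = reads1$read_id[i], seq = m$seq,
                           qual = m$qual, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
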