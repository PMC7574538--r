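#' Amplicon panel: references, guides, cut sites and quantification windows
#'
#' An amplicon models one entry of a targeted single-cell DNA panel: the
#' reference sequence, its category (`on_target`, `off_target`, `control`),
#' and -- for CRISPR targets -- the guide spacer, its strand, the predicted
#' Cas9 cleavage site and the quantification window around it.
#'
#' Coordinates are 0-based. The cut site is an inter-base index: cleavage
#' occurs between reference positions `cut_site - 1` and `cut_site`, 3 bp
#' 5' of the PAM on the protospacer strand (blunt SpCas9 cut). The
#' quantification window is the half-open interval
#' `[cut_site - window_halfwidth, cut_site + window_halfwidth)`.
#'
#' @param amplicon_id unique identifier.
#' @param ref_seq reference sequence (uppercase ACGTN).
#' @param category one of `"on_target"`, `"off_target"`, `"control"`.
#' @param guide_spacer protospacer sequence as it reads on the guide strand;
#'   `NA` for controls.
#' @param guide_strand `"forward"` or `"reverse"` relative to `ref_seq`;
#'   `NA` to search both strands.
#' @param pam_pattern IUPAC PAM pattern adjacent to the spacer 3' end
#'   (default `"NGG"`, SpCas9).
#' @param window_halfwidth half-width of the quantification window in bases
#'   (default 2, i.e. a 4-bp window).
#' @return an object of class `amplicon` with fields `cut_site`, `pam_start`
#'   and `window` filled in for CRISPR targets.
#' @examples
#' ref <- paste0(strrep("A", 30), "GATTACAGATTACAGATTAC", "TGG", strrep("C", 30))
#' amp <- amplicon("ex", ref, "on_target", "GATTACAGATTACAGATTAC", "forward")
#' amp$cut_site
#' @export
amplicon <- function(amplicon_id, ref_seq,
                     category = c("on_target", "off_target", "control"),
                     guide_spacer = NA_character_,
                     guide_strand = NA_character_,
                     pam_pattern = "NGG",
                     window_halfwidth = 2L) {
  category <- match.arg(category)
  stopifnot(is.character(amplicon_id), length(amplicon_id) == 1L,
            nzchar(amplicon_id))
  ref_seq <- toupper(as.character(ref_seq))
  if (!grepl("^[ACGTN]+$", ref_seq))
    stop("amplicon '", amplicon_id, "': ref_seq must be ACGTN")
  obj <- structure(
    list(amplicon_id = amplicon_id, ref_seq = ref_seq, category = category,
         guide_spacer = NA_character_, guide_strand = NA_character_,
         pam_start = NA_integer_, cut_site = NA_integer_,
         window_halfwidth = as.integer(window_halfwidth),
         window = NULL),
    class = "amplicon")
  if (category == "control") {
    if (!is.na(guide_spacer))
      stop("amplicon '", amplicon_id, "': controls carry no guide")
    return(obj)
  }
  if (is.na(guide_spacer))
    stop("amplicon '", amplicon_id, "': CRISPR target needs a guide_spacer")
  if (nchar(ref_seq) < 40L)
    stop("amplicon '", amplicon_id,
         "': CRISPR target reference must be at least 40 bp")
  obj$guide_spacer <- toupper(guide_spacer)
  hit <- locate_guide(ref_seq, obj$guide_spacer, guide_strand, pam_pattern,
                      amplicon_id)
  obj$guide_strand <- hit$strand
  obj$pam_start <- hit$pam_start
  obj$cut_site <- hit$cut_site
  w <- obj$window_halfwidth
  win <- c(hit$cut_site - w, hit$cut_site + w)
  if (win[1] < 0L || win[2] > nchar(ref_seq))
    stop("amplicon '", amplicon_id, "': quantification window [", win[1], ",",
         win[2], ") lies outside the reference")
  obj$window <- win
  obj
}

iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(chars, function(ch) {
    if (!ch %in% names(map)) stop("invalid IUPAC code: ", ch)
    alt <- map[[ch]]
    if (nchar(alt) == 1L) alt else paste0("[", alt, "]")
  }, character(1)), collapse = "")
}

fixed_positions <- function(haystack, needle) {
  # 0-based start positions of exact occurrences
  out <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(needle, substr(haystack, from, nchar(haystack)), fixed = TRUE)
    if (p < 0) break
    out <- c(out, from + p - 2L)
    from <- from + p
  }
  out
}

# Locate guide + PAM on the reference; returns 0-based pam_start (first PAM
# base on the forward reference) and the inter-base cut site.
locate_guide <- function(ref_seq, spacer, strand = NA_character_,
                         pam_pattern = "NGG", amplicon_id = "?") {
  strands <- if (is.na(strand)) c("forward", "reverse") else strand
  stopifnot(all(strands %in% c("forward", "reverse")))
  L <- nchar(ref_seq)
  sl <- nchar(spacer)
  pl <- nchar(pam_pattern)
  pam_fwd <- paste0("^", iupac_regex(pam_pattern))
  pam_rev <- paste0("^", iupac_regex(revcomp(pam_pattern)))
  hits <- list()
  if ("forward" %in% strands) {
    for (s in fixed_positions(ref_seq, spacer)) {
      p <- s + sl # PAM immediately 3' of the spacer
      if (p + pl <= L &&
          grepl(pam_fwd, substr(ref_seq, p + 1L, p + pl))) {
        hits[[length(hits) + 1L]] <-
          list(strand = "forward", pam_start = p, cut_site = p - 3L)
      }
    }
  }
  if ("reverse" %in% strands) {
    for (s in fixed_positions(ref_seq, revcomp(spacer))) {
      # PAM sits 5' of the reverse-complemented spacer on the forward strand
      p0 <- s - pl
      if (p0 >= 0L &&
          grepl(pam_rev, substr(ref_seq, p0 + 1L, p0 + pl))) {
        q <- s - 1L # last PAM base, 0-based inclusive
        hits[[length(hits) + 1L]] <-
          list(strand = "reverse", pam_start = p0, cut_site = q + 4L)
      }
    }
  }
  if (length(hits) == 0L)
    stop("amplicon '", amplicon_id,
         "': guide spacer not found adjacent to a ", pam_pattern,
         " PAM on the reference")
  if (length(hits) > 1L)
    stop("amplicon '", amplicon_id,
         "': guide spacer matches the reference at multiple PAM-adjacent ",
         "positions")
  hits[[1L]]
}

#' Predicted Cas9 cleavage site of an amplicon
#'
#' Recomputes the inter-base cut index from the guide geometry: 3 bp 5' of
#' the PAM on the protospacer strand. For a forward guide with PAM starting
#' at `p` (0-based) the cut site is `p - 3`; for a reverse guide with PAM
#' ending at `q` (0-based inclusive) it is `q + 4`.
#'
#' @param amp an [amplicon()] with a guide.
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @return integer inter-base cut index.
#' @export
compute_cut_site <- function(amp, pam_pattern = "NGG") {
  stopifnot(inherits(amp, "amplicon"))
  if (amp$category == "control" || is.na(amp$guide_spacer))
    stop("amplicon '", amp$amplicon_id, "' has no guide")
  locate_guide(amp$ref_seq, amp$guide_spacer, amp$guide_strand, pam_pattern,
               amp$amplicon_id)$cut_site
}

#' Construct an amplicon panel
#'
#' @param amplicons list of [amplicon()] objects.
#' @param name panel name.
#' @return object of class `amplicon_panel`.
#' @export
panel <- function(amplicons, name = "panel") {
  stopifnot(is.list(amplicons), length(amplicons) >= 1L)
  ok <- vapply(amplicons, inherits, logical(1), what = "amplicon")
  if (!all(ok)) stop("all panel entries must be amplicon objects")
  ids <- vapply(amplicons, `[[`, character(1), "amplicon_id")
  if (anyDuplicated(ids))
    stop("duplicate amplicon_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(amplicons) <- ids
  structure(list(amplicons = amplicons, name = name), class = "amplicon_panel")
}

#' Read an amplicon panel from a TSV file
#'
#' Expected columns: `amplicon_id`, `ref_seq`, `category`, and for CRISPR
#' targets `guide_spacer` and optionally `guide_strand` (blank or NA to
#' search both strands). Cut sites and quantification windows are computed
#' and validated on load.
#'
#' @param path TSV file with header.
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @param window_halfwidth quantification window half-width (default 2).
#' @param name panel name (defaults to the file name).
#' @return an `amplicon_panel`.
#' @export
read_panel <- function(path, pam_pattern = "NGG", window_halfwidth = 2L,
                       name = basename(path)) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("amplicon_id", "ref_seq", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("panel file lacks columns: ", paste(miss, collapse = ", "))
  if (!"guide_spacer" %in% names(df)) df$guide_spacer <- NA_character_
  if (!"guide_strand" %in% names(df)) df$guide_strand <- NA_character_
  df$guide_spacer[!nzchar(trimws(df$guide_spacer))] <- NA_character_
  df$guide_strand[!nzchar(trimws(df$guide_strand))] <- NA_character_
  amps <- lapply(seq_len(nrow(df)), function(i) {
    amplicon(df$amplicon_id[i], df$ref_seq[i], df$category[i],
             df$guide_spacer[i], df$guide_strand[i],
             pam_pattern = pam_pattern, window_halfwidth = window_halfwidth)
  })
  panel(amps, name = name)
}

#' Write an amplicon panel to a TSV file
#'
#' @param pan an `amplicon_panel`.
#' @param path output path.
#' @export
write_panel <- function(pan, path) {
  stopifnot(inherits(pan, "amplicon_panel"))
  df <- as.data.frame(pan)
  write.table(df[, c("amplicon_id", "ref_seq", "category", "guide_spacer",
                     "guide_strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method base::as.data.frame
as.data.frame.amplicon_panel <- function(x, ...) {
  do.call(rbind, lapply(x$amplicons, function(a) {
    data.frame(amplicon_id = a$amplicon_id,
               ref_seq = a$ref_seq,
               category = a$category,
               guide_spacer = a$guide_spacer,
               guide_strand = a$guide_strand,
               pam_start = a$pam_start,
               cut_site = a$cut_site,
               window_start = if (is.null(a$window)) NA_integer_ else a$window[1],
               window_end = if (is.null(a$window)) NA_integer_ else a$window[2],
               stringsAsFactors = FALSE)
  }))
}

#' @exportS3Method base::print
print.amplicon_panel <- function(x, ...) {
  cats <- table(vapply(x$amplicons, `[[`, character(1), "category"))
  cat("<amplicon_panel> '", x$name, "': ", length(x$amplicons),
      " amplicons (", paste(names(cats), as.integer(cats), sep = "=",
                            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.amplicon <- function(x, ...) {
  cat("<amplicon> ", x$amplicon_id, " [", x$category, "], ",
      nchar(x$ref_seq), " bp", sep = "")
  if (!is.na(x$cut_site))
    cat(", cut@", x$cut_site, " window[", x$window[1], ",", x$window[2], ")",
        sep = "")
  cat("\n")
  invisible(x)
}

panel_ids <- function(pan) names(pan$amplicons)

panel_categories <- function(pan) {
  vapply(pan$amplicons, `[[`, character(1), "category")
}

#' On-target amplicon ids of a panel
#'
#' @param pan an `amplicon_panel`.
#' @return character vector of amplicon ids with category `on_target`.
#' @export
on_targets <- function(pan) {
  names(pan$amplicons)[panel_categories(pan) == "on_target"]
}
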