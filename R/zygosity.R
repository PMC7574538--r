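#' Zygosity classification from modification rate and heterozygosity
#'
#' Classifies each called cell-amplicon into one of four classes from its
#' percent modified reads and its heterozygosity (frequency of the
#' second-most-frequent allele, in percent):
#' \itemize{
#'   \item `pct_modified < lower` -> `WT_WT`
#'   \item `lower <= pct_modified < upper` -> `WT_Mut`
#'   \item `pct_modified >= upper` and `heterozygosity >= lower` -> `Mut_Mut2`
#'   \item `pct_modified >= upper` and `heterozygosity < lower` -> `Mut_Mut`
#' }
#' `NA` inputs (NO_CALL summaries) yield `NO_CALL`.
#'
#' @param pct_modified numeric vector in \[0, 100\].
#' @param heterozygosity numeric vector in \[0, 100\].
#' @param lower lower threshold in percent (default 20).
#' @param upper upper threshold in percent (default 80).
#' @return factor with levels `WT_WT`, `WT_Mut`, `Mut_Mut2`, `Mut_Mut`,
#'   `NO_CALL`.
#' @examples
#' classify_zygosity(c(10, 50, 100, 90), c(0, 50, 0, 45))
#' @export
classify_zygosity <- function(pct_modified, heterozygosity,
                              lower = 20, upper = 80) {
  stopifnot(length(pct_modified) == length(heterozygosity))
  bad <- function(v) !is.na(v) & (v < 0 | v > 100)
  if (any(bad(pct_modified)) || any(bad(heterozygosity)))
    stop("pct_modified and heterozygosity must lie in [0, 100]")
  cls <- rep(NA_character_, length(pct_modified))
  known <- !is.na(pct_modified) & !is.na(heterozygosity)
  p <- pct_modified[known]; h <- heterozygosity[known]
  k <- ifelse(p < lower, "WT_WT",
       ifelse(p < upper, "WT_Mut",
       ifelse(h >= lower, "Mut_Mut2", "Mut_Mut")))
  cls[known] <- k
  cls[!known] <- "NO_CALL"
  factor(cls, levels = c("WT_WT", "WT_Mut", "Mut_Mut2", "Mut_Mut", "NO_CALL"))
}

#' Add zygosity calls to cell-amplicon summaries
#'
#' @param x a `cell_edit_calls` object or a summaries data frame with
#'   `pct_modified` and `heterozygosity` columns.
#' @inheritParams classify_zygosity
#' @return the summaries data frame with a `zygosity` column (CRISPR
#'   amplicons only; coverage-only rows are `NO_CALL`).
#' @export
call_zygosity <- function(x, lower = 20, upper = 80) {
  s <- if (inherits(x, "cell_edit_calls")) x$summaries else x
  s$zygosity <- classify_zygosity(s$pct_modified, s$heterozygosity,
                                  lower, upper)
  s
}

#' Per-target zygosity composition
#'
#' Fractions of the four zygosity classes over called cells per amplicon,
#' plus the edited-only renormalization that omits WT/WT.
#'
#' @param calls data frame with `amplicon_id` and `zygosity` (from
#'   [call_zygosity()]).
#' @return data frame `amplicon_id`, `class`, `n`, `fraction`,
#'   `fraction_edited` (NA for WT_WT); empty when all calls are NO_CALL.
#' @export
zygosity_composition <- function(calls) {
  calls <- calls[calls$zygosity != "NO_CALL", , drop = FALSE]
  if (nrow(calls) == 0L)
    return(data.frame(amplicon_id = character(0), class = character(0),
                      n = integer(0), fraction = numeric(0),
                      fraction_edited = numeric(0)))
  classes <- c("WT_WT", "WT_Mut", "Mut_Mut2", "Mut_Mut")
  out <- do.call(rbind, lapply(split(calls, calls$amplicon_id), function(d) {
    n <- table(factor(as.character(d$zygosity), levels = classes))
    tot <- sum(n)
    ed <- sum(n[classes != "WT_WT"])
    data.frame(amplicon_id = d$amplicon_id[1], class = classes,
               n = as.integer(n),
               fraction = as.numeric(n) / tot,
               fraction_edited = ifelse(classes == "WT_WT", NA_real_,
                                        if (ed > 0) as.numeric(n) / ed
                                        else NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
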