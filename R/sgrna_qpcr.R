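#' Read a long-format single-cell qPCR Cq table
#'
#' Expected TSV columns: `cell`, `assay`, `replicate`, `cq`. A configurable
#' token (default `"999"`) marks reactions with no amplification and is
#' read as `NA`.
#'
#' @param path TSV file.
#' @param no_amp_token no-amplification sentinel (default `"999"`).
#' @param cycles PCR cycle count; finite Cq values must lie in
#'   `(0, cycles]` (default 30).
#' @return object of class `cq_matrix` wrapping the validated long table.
#' @export
read_cq <- function(path, no_amp_token = "999", cycles = 30) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(cq = "character"))
  cq_matrix(df, no_amp_token = no_amp_token, cycles = cycles)
}

#' Construct a Cq matrix from a long-format table
#'
#' @param df data frame with columns `cell`, `assay`, `replicate`, `cq`
#'   (`cq` numeric or character; the sentinel and `NA` mean no
#'   amplification).
#' @inheritParams read_cq
#' @return object of class `cq_matrix`: the long table plus `assays`,
#'   `cells` and `n_replicates`.
#' @export
cq_matrix <- function(df, no_amp_token = "999", cycles = 30) {
  need <- c("cell", "assay", "replicate", "cq")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Cq table lacks columns: ", paste(miss, collapse = ", "))
  cq <- df$cq
  if (is.character(cq)) {
    cq[trimws(cq) == no_amp_token] <- NA_character_
    cq <- suppressWarnings(as.numeric(cq))
  } else {
    cq[!is.na(cq) & cq == as.numeric(no_amp_token)] <- NA_real_
  }
  fin <- !is.na(cq)
  if (any(cq[fin] <= 0 | cq[fin] > cycles))
    stop("finite Cq values must lie in (0, ", cycles, "]")
  df$cq <- cq
  reps <- table(df$cell, df$assay)
  structure(list(data = df,
                 assays = sort(unique(df$assay)),
                 cells = sort(unique(df$cell)),
                 n_replicates = if (length(reps)) max(reps) else 0L,
                 cycles = cycles),
            class = "cq_matrix")
}

#' Call per-cell sgRNA presence from replicate Cq values
#'
#' An sgRNA is called present in a cell iff at least `min_positive_reps` of
#' its assay replicates amplified with `Cq <= cq_max`. Calls are therefore
#' monotone in `cq_max` and anti-monotone in `min_positive_reps`. The
#' replicate count-of-positives rule is robust to the no-amplification
#' dropouts typical of single-cell qPCR.
#'
#' @param cq a [cq_matrix()].
#' @param cq_max maximum quantification cycle for a positive replicate
#'   (default 25).
#' @param min_positive_reps minimum positive replicates (default 4, half of
#'   the usual 8).
#' @param assay_map optional named character vector mapping assay ids to
#'   sgRNA names; unknown assay ids in the data raise an error.
#' @return list of class `sgrna_calls`: `presence` (logical cells x sgRNA
#'   matrix), `multiplicity` (data frame `n_sgrnas`, `n_cells`),
#'   `cooccurrence` (sgRNA x sgRNA count matrix).
#' @export
call_sgrna_presence <- function(cq, cq_max = 25, min_positive_reps = 4L,
                                assay_map = NULL) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (cq_max <= 0 || cq_max > cq$cycles)
    stop("cq_max must lie within the cycle range (0, ", cq$cycles, "]")
  df <- cq$data
  if (!is.null(assay_map)) {
    unknown <- setdiff(unique(df$assay), names(assay_map))
    if (length(unknown))
      stop("unknown assay id: ", paste(unknown, collapse = ", "))
    df$assay <- unname(assay_map[df$assay])
  }
  pos <- !is.na(df$cq) & df$cq <= cq_max
  agg <- stats::aggregate(pos ~ cell + assay, data = df, FUN = sum)
  cells <- sort(unique(df$cell))
  assays <- sort(unique(df$assay))
  presence <- matrix(FALSE, length(cells), length(assays),
                     dimnames = list(cells, assays))
  presence[cbind(match(agg$cell, cells), match(agg$assay, assays))] <-
    agg$pos >= min_positive_reps
  n_per_cell <- rowSums(presence)
  hist <- table(factor(n_per_cell, levels = 0:length(assays)))
  structure(list(
    presence = presence,
    multiplicity = data.frame(n_sgrnas = 0:length(assays),
                              n_cells = as.integer(hist)),
    cooccurrence = crossprod(presence)),
    class = "sgrna_calls")
}

#' @exportS3Method base::print
print.sgrna_calls <- function(x, ...) {
  cat("<sgrna_calls> ", nrow(x$presence), " cells x ", ncol(x$presence),
      " sgRNAs; multiplicity mode at ",
      x$multiplicity$n_sgrnas[which.max(x$multiplicity$n_cells)], "\n",
      sep = "")
  invisible(x)
}
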