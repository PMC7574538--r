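#' Per-cell multi-target edit profiles
#'
#' For each cell, flags every on-target amplicon as edited iff its
#' modification rate is called and reaches `edit_threshold` percent, and
#' counts edited and covered targets. Missing (insufficient-coverage)
#' entries count as unedited for the flags; the per-cell covered-target
#' count is reported alongside so users can filter.
#'
#' @param em an [edit_matrix].
#' @param targets character vector of on-target amplicon ids (default: the
#'   `on_target` amplicons recorded in the matrix).
#' @param edit_threshold percent modified at or above which a site counts
#'   as edited (default 20).
#' @return list of class `cell_edit_profiles`: `edited` and `covered`
#'   (logical cells x targets matrices), `profile` (data frame `barcode`,
#'   `n_edited`, `n_covered`), `histogram` (data frame `n_edited`, `n_cells`
#'   over 0..length(targets)), `edit_threshold`.
#' @export
count_edited_targets <- function(em, targets = NULL, edit_threshold = 20) {
  stopifnot(inherits(em, "edit_matrix"))
  if (is.null(targets)) {
    if (is.null(em$categories))
      stop("no panel categories recorded; supply `targets`")
    targets <- names(em$categories)[em$categories == "on_target"]
  }
  miss <- setdiff(targets, colnames(em$pct))
  if (length(miss))
    stop("targets absent from the matrix: ", paste(miss, collapse = ", "))
  pct <- em$pct[, targets, drop = FALSE]
  edited <- !is.na(pct) & pct >= edit_threshold
  covered <- !is.na(pct)
  n_edited <- rowSums(edited)
  hist <- table(factor(n_edited, levels = 0:length(targets)))
  structure(list(
    edited = edited, covered = covered,
    profile = data.frame(barcode = rownames(pct),
                         n_edited = as.integer(n_edited),
                         n_covered = as.integer(rowSums(covered)),
                         stringsAsFactors = FALSE, row.names = NULL),
    histogram = data.frame(n_edited = 0:length(targets),
                           n_cells = as.integer(hist)),
    edit_threshold = edit_threshold),
    class = "cell_edit_profiles")
}

#' Flag doublets in an admixture experiment
#'
#' In an admixture of singly-edited lines every true cell carries at most
#' one edited on-target site, so a barcode with editing at two or more
#' on-targets betrays a droplet that captured DNA from multiple cells.
#' This flagging is only meaningful in admixture designs; in a multiplexed
#' line multi-edited cells are biology, not artifacts.
#'
#' @param profiles a `cell_edit_profiles` from [count_edited_targets()].
#' @return list of class `doublet_report`: `profile` (with `doublet_flag`),
#'   `n_two` (cells with exactly two edited targets), `n_more` (more than
#'   two), `n_flagged`, `n_cells`, `rate` (= flagged / total).
#' @export
flag_doublets_admixture <- function(profiles) {
  stopifnot(inherits(profiles, "cell_edit_profiles"))
  prof <- profiles$profile
  prof$doublet_flag <- prof$n_edited >= 2L
  structure(list(profile = prof,
                 n_two = sum(prof$n_edited == 2L),
                 n_more = sum(prof$n_edited > 2L),
                 n_flagged = sum(prof$doublet_flag),
                 n_cells = nrow(prof),
                 rate = if (nrow(prof)) sum(prof$doublet_flag) / nrow(prof)
                        else NA_real_),
            class = "doublet_report")
}

#' @exportS3Method base::print
print.doublet_report <- function(x, ...) {
  cat("<doublet_report> ", x$n_flagged, "/", x$n_cells, " barcodes flagged (",
      sprintf("%.2f%%", 100 * x$rate), "): ", x$n_two, " with two edits, ",
      x$n_more, " with more\n", sep = "")
  invisible(x)
}

#' Write a doublet report as JSON
#'
#' @param report a `doublet_report`.
#' @param path output path.
#' @export
write_doublet_report <- function(report, path) {
  jsonlite::write_json(report[c("n_two", "n_more", "n_flagged", "n_cells",
                                "rate")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-gene edited fraction among sufficiently covered cells
#'
#' @param em an [edit_matrix].
#' @param targets on-target amplicon ids (default from the matrix).
#' @param coverage_min minimum reads for a cell to count as covered
#'   (default 5).
#' @param edit_threshold percent modified for the edited numerator
#'   (default 20).
#' @return data frame `amplicon_id`, `edited`, `covered`, `fraction`
#'   (NA when no cell is covered).
#' @export
per_gene_edited_fraction <- function(em, targets = NULL, coverage_min = 5L,
                                     edit_threshold = 20) {
  stopifnot(inherits(em, "edit_matrix"))
  if (is.null(targets)) {
    if (is.null(em$categories))
      stop("no panel categories recorded; supply `targets`")
    targets <- names(em$categories)[em$categories == "on_target"]
  }
  out <- do.call(rbind, lapply(targets, function(g) {
    cov <- em$coverage[, g] >= coverage_min & !is.na(em$pct[, g])
    ed <- cov & em$pct[, g] >= edit_threshold
    data.frame(amplicon_id = g, edited = sum(ed), covered = sum(cov),
               fraction = if (sum(cov) > 0) sum(ed) / sum(cov) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Combinatorial assortment (upset-style) counts of edited targets
#'
#' For every observed subset of on-targets, counts the cells whose edited
#' set equals that subset exactly (intersection size), plus the per-gene
#' marginal set sizes. The subset counts partition the cells: intersection
#' sizes sum to the cell count, and each gene's set size equals the sum of
#' intersection sizes over the subsets containing it.
#'
#' @param profiles a `cell_edit_profiles` (or a logical cells x targets
#'   matrix of edited flags).
#' @return list with `intersections` (data frame `subset` -- gene names
#'   joined by `+`, `"(none)"` for the empty set -- `n_genes`,
#'   `intersection_size`, sorted by decreasing size) and `set_sizes`
#'   (data frame `amplicon_id`, `set_size`).
#' @export
combination_counts <- function(profiles) {
  edited <- if (inherits(profiles, "cell_edit_profiles")) profiles$edited
            else profiles
  stopifnot(is.matrix(edited), is.logical(edited))
  genes <- colnames(edited)
  key <- apply(edited, 1L, function(r)
    if (!any(r)) "(none)" else paste(genes[r], collapse = "+"))
  tab <- table(key)
  inter <- data.frame(subset = names(tab),
                      n_genes = ifelse(names(tab) == "(none)", 0L,
                                       lengths(strsplit(names(tab),
                                                        "+", fixed = TRUE))),
                      intersection_size = as.integer(tab),
                      stringsAsFactors = FALSE, row.names = NULL)
  inter <- inter[order(-inter$intersection_size, inter$subset), ,
                 drop = FALSE]
  rownames(inter) <- NULL
  list(intersections = inter,
       set_sizes = data.frame(amplicon_id = genes,
                              set_size = as.integer(colSums(edited)),
                              stringsAsFactors = FALSE))
}
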