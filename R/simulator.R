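#' Programmed allele edit specification
#'
#' Describes one allele of a genotype relative to an amplicon's cut site,
#' so the same specification transfers across panels: `"del"` removes
#' `len` reference bases starting at `cut_site + offset`; `"ins"` inserts
#' `seq` at the inter-base position `cut_site + offset`; `"ref"` is the
#' unedited allele.
#'
#' @param type `"ref"`, `"del"` or `"ins"`.
#' @param offset 0-based offset from the cut site.
#' @param len deletion length (del only).
#' @param seq inserted sequence (ins only).
#' @return object of class `edit_spec`.
#' @export
edit_spec <- function(type = c("ref", "del", "ins"), offset = 0L, len = 0L,
                      seq = "") {
  type <- match.arg(type)
  if (type == "del") stopifnot(len >= 1L)
  if (type == "ins") stopifnot(nzchar(seq))
  structure(list(type = type, offset = as.integer(offset),
                 len = as.integer(len), seq = toupper(seq)),
            class = "edit_spec")
}

#' A simulated genotype: per-target allele pair
#'
#' @param id genotype identifier.
#' @param edits named list: amplicon id -> list of two [edit_spec()]s (or
#'   the string `"ref"`). Amplicons not listed are reference on both
#'   alleles.
#' @return object of class `sim_genotype`.
#' @export
genotype <- function(id, edits = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  edits <- lapply(edits, function(pair) {
    stopifnot(length(pair) == 2L)
    lapply(pair, function(e) {
      if (identical(e, "ref")) edit_spec("ref") else {
        stopifnot(inherits(e, "edit_spec")); e
      }
    })
  })
  structure(list(id = id, edits = edits), class = "sim_genotype")
}

# Realize an edit on an amplicon reference. The modified flag applies the
# same quantification-window rule the pipeline uses, after left-normalizing
# the indel by direct string comparison (independent of the aligner).
apply_edit <- function(amp, spec) {
  ref <- amp$ref_seq
  L <- nchar(ref)
  if (spec$type == "ref")
    return(list(seq = ref, modified = FALSE))
  if (is.na(amp$cut_site))
    stop("amplicon '", amp$amplicon_id, "' has no cut site; cannot place ",
         "a programmed edit")
  cut <- amp$cut_site
  ws <- amp$window[1]; we <- amp$window[2]
  if (spec$type == "del") {
    start <- cut + spec$offset
    if (start < 0L || start + spec$len > L)
      stop("programmed deletion [", start, ",", start + spec$len,
           ") outside amplicon '", amp$amplicon_id, "'")
    out <- paste0(substr(ref, 1L, start), substr(ref, start + spec$len + 1L, L))
    p <- start
    while (p > 0L &&
           substr(ref, p, p) == substr(ref, p + spec$len, p + spec$len))
      p <- p - 1L
    list(seq = out, modified = p < we && p + spec$len > ws)
  } else { # ins
    pos <- cut + spec$offset
    if (pos < 0L || pos > L)
      stop("programmed insertion at ", pos, " outside amplicon '",
           amp$amplicon_id, "'")
    out <- paste0(substr(ref, 1L, pos), spec$seq, substr(ref, pos + 1L, L))
    p <- pos
    s <- spec$seq
    sl <- nchar(s)
    while (p > 0L && substr(ref, p, p) == substr(s, sl, sl)) {
      s <- paste0(substr(ref, p, p), substr(s, 1L, sl - 1L))
      p <- p - 1L
    }
    list(seq = out, modified = p >= ws && p <= we)
  }
}

# Programmed zygosity class of one genotype at one amplicon.
programmed_class <- function(a1, a2) {
  nmod <- a1$modified + a2$modified
  if (nmod == 0L) "WT_WT"
  else if (nmod == 1L) "WT_Mut"
  else if (a1$seq == a2$seq) "Mut_Mut"
  else "Mut_Mut2"
}

#' Simulation configuration
#'
#' Defines one synthetic droplet run: the panel, the genotype mixture, and
#' the noise regime (doublets, allelic dropout, coverage law, sequencing
#' error). Allele sequences are realized and validated on construction.
#'
#' @param pan an `amplicon_panel`.
#' @param n_barcodes number of cell barcodes.
#' @param population list of [genotype()]s.
#' @param proportions mixture proportions (must sum to 1).
#' @param doublet_rate probability a barcode captures two cells.
#' @param ado_rate per-(cell, amplicon, allele) dropout probability;
#'   published droplet single-cell DNA platforms report roughly 5-10%.
#' @param mean_coverage mean reads per amplicon per cell (default 26,
#'   a typical per-amplicon median for this assay class).
#' @param coverage_dispersion negative-binomial size parameter
#'   (`Inf` = Poisson; default 8, moderate overdispersion).
#' @param sub_error_rate per-base substitution error probability.
#' @param indel_error_rate per-base spurious 1-bp indel probability.
#' @param structure a [read_structure()].
#' @param seed integer seed used by [simulate_reads()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(pan, n_barcodes, population, proportions,
                       doublet_rate = 0, ado_rate = 0, mean_coverage = 26,
                       coverage_dispersion = 8, sub_error_rate = 0,
                       indel_error_rate = 0, structure = read_structure(),
                       seed = 1L) {
  stopifnot(inherits(pan, "amplicon_panel"), n_barcodes >= 1L,
            length(population) >= 1L,
            length(proportions) == length(population))
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("population proportions must sum to 1")
  rates <- c(doublet_rate, ado_rate, sub_error_rate, indel_error_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  stopifnot(mean_coverage > 0)
  ok <- vapply(population, inherits, logical(1), "sim_genotype")
  if (!all(ok)) stop("population entries must be sim_genotype objects")
  gids <- vapply(population, `[[`, character(1), "id")
  if (anyDuplicated(gids)) stop("duplicate genotype ids")
  ids <- panel_ids(pan)
  # realize alleles: alleles[[amp]][[genotype]] = list(seqs, modified)
  alleles <- list()
  gt_class <- list()
  for (a in ids) {
    amp <- pan$amplicons[[a]]
    alleles[[a]] <- lapply(population, function(g) {
      pair <- g$edits[[a]]
      if (is.null(pair)) pair <- list(edit_spec("ref"), edit_spec("ref"))
      r1 <- apply_edit(amp, pair[[1]])
      r2 <- apply_edit(amp, pair[[2]])
      list(seqs = c(r1$seq, r2$seq),
           modified = c(r1$modified, r2$modified))
    })
    names(alleles[[a]]) <- gids
    if (!is.null(amp$window)) {
      gt_class[[a]] <- vapply(gids, function(g) {
        al <- alleles[[a]][[g]]
        programmed_class(list(seq = al$seqs[1], modified = al$modified[1]),
                         list(seq = al$seqs[2], modified = al$modified[2]))
      }, character(1))
    }
  }
  unknown <- setdiff(unlist(lapply(population, function(g) names(g$edits))),
                     ids)
  if (length(unknown))
    stop("genotype edits reference unknown amplicons: ",
         paste(unknown, collapse = ", "))
  structure(list(panel = pan, n_barcodes = as.integer(n_barcodes),
                 population = population, genotype_ids = gids,
                 proportions = proportions, doublet_rate = doublet_rate,
                 ado_rate = ado_rate, mean_coverage = mean_coverage,
                 coverage_dispersion = coverage_dispersion,
                 sub_error_rate = sub_error_rate,
                 indel_error_rate = indel_error_rate,
                 structure = structure, seed = as.integer(seed),
                 alleles = alleles, genotype_class = gt_class),
            class = "sim_config")
}

random_barcodes <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  while (length(out) < n) {
    m <- matrix(sample(bases, (n - length(out)) * len, replace = TRUE),
                ncol = len)
    out <- unique(c(out, do.call(paste0, as.data.frame(m,
                                                       stringsAsFactors = FALSE))))
  }
  out[seq_len(n)]
}

#' Simulate a droplet single-cell amplicon sequencing run
#'
#' For every barcode, draws one genotype (two for doublets), then for every
#' amplicon draws a total coverage from the negative-binomial law, splits
#' reads uniformly across surviving alleles (each allele independently
#' dropped with probability `ado_rate`), constructs each read as
#' `constant1 + BC1 + constant2 + BC2 + constant3 + allele sequence`, and
#' injects substitution and spurious 1-bp indel errors into the payload at
#' the configured per-base rates. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `sc_sim`: `reads` (data frame `read_id`, `seq`),
#'   `truth` (list: `cells`, `alleles` with realized per-allele read counts
#'   and dropout flags, `reads` with per-read source barcode/amplicon/
#'   allele), and `config`.
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pan <- config$panel
  ids <- panel_ids(pan)
  n <- config$n_barcodes
  G <- length(config$population)
  A <- length(ids)

  bl <- config$structure$barcode_len
  bc1 <- random_barcodes(n, bl)
  bc2 <- random_barcodes(n, bl)
  barcode <- paste0(bc1, bc2)
  while (anyDuplicated(barcode)) { # vanishingly rare
    dup <- which(duplicated(barcode))
    bc2[dup] <- random_barcodes(length(dup), bl)
    barcode <- paste0(bc1, bc2)
  }
  prefix <- paste0(config$structure$constant1, bc1,
                   config$structure$constant2, bc2,
                   config$structure$constant3)

  doublet <- runif(n) < config$doublet_rate
  g1 <- sample.int(G, n, replace = TRUE, prob = config$proportions)
  g2 <- rep(NA_integer_, n)
  if (any(doublet))
    g2[doublet] <- sample.int(G, sum(doublet), replace = TRUE,
                              prob = config$proportions)

  covm <- if (is.finite(config$coverage_dispersion)) {
    matrix(rnbinom(n * A, size = config$coverage_dispersion,
                   mu = config$mean_coverage), n, A)
  } else {
    matrix(rpois(n * A, config$mean_coverage), n, A)
  }

  # per-(cell, amplicon, allele) realized counts
  acc <- vector("list", A)
  for (ai in seq_len(A)) {
    amp_alleles <- config$alleles[[ids[ai]]]
    nal <- ifelse(doublet, 4L, 2L)
    total_rows <- sum(nal)
    bc_i <- integer(total_rows); gt_i <- integer(total_rows)
    slot_i <- integer(total_rows); cnt_i <- integer(total_rows)
    drop_i <- logical(total_rows)
    r <- 0L
    for (i in seq_len(n)) {
      k <- nal[i]
      gts <- if (doublet[i]) c(g1[i], g1[i], g2[i], g2[i])
             else c(g1[i], g1[i])
      slots <- if (doublet[i]) c(1L, 2L, 1L, 2L) else c(1L, 2L)
      dropped <- runif(k) < config$ado_rate
      counts <- integer(k)
      tot <- covm[i, ai]
      kept <- which(!dropped)
      if (length(kept) && tot > 0L)
        counts[kept] <- drop(rmultinom(1L, tot,
                                       rep(1 / length(kept), length(kept))))
      idx <- r + seq_len(k)
      bc_i[idx] <- i; gt_i[idx] <- gts; slot_i[idx] <- slots
      cnt_i[idx] <- counts; drop_i[idx] <- dropped
      r <- r + k
    }
    seqs <- vapply(seq_len(total_rows), function(t)
      amp_alleles[[gt_i[t]]]$seqs[slot_i[t]], character(1))
    mods <- vapply(seq_len(total_rows), function(t)
      amp_alleles[[gt_i[t]]]$modified[slot_i[t]], logical(1))
    acc[[ai]] <- data.frame(barcode_i = bc_i, amplicon_i = ai,
                            genotype_i = gt_i, slot = slot_i,
                            allele_seq = seqs, modified = mods,
                            n_reads = cnt_i, dropped = drop_i,
                            stringsAsFactors = FALSE)
  }
  alleles <- do.call(rbind, acc)

  # expand to reads
  rows <- rep(seq_len(nrow(alleles)), alleles$n_reads)
  payload <- alleles$allele_seq[rows]
  src_bc <- alleles$barcode_i[rows]
  N <- length(payload)

  payload <- inject_errors(payload, config$sub_error_rate,
                           config$indel_error_rate)

  read_id <- sprintf("r%08d", seq_len(max(N, 0L)))
  reads <- data.frame(read_id = read_id,
                      seq = paste0(prefix[src_bc], payload),
                      stringsAsFactors = FALSE)
  truth_reads <- data.frame(read_id = read_id,
                            barcode = barcode[src_bc],
                            amplicon_id = ids[alleles$amplicon_i[rows]],
                            allele_row = rows,
                            modified = alleles$modified[rows],
                            stringsAsFactors = FALSE)
  gname <- config$genotype_ids
  cells <- data.frame(barcode = barcode,
                      doublet = doublet,
                      genotype_id = ifelse(doublet,
                                           paste0(gname[g1], "+", gname[g2]),
                                           gname[g1]),
                      g1 = gname[g1],
                      g2 = ifelse(doublet, gname[g2], NA_character_),
                      stringsAsFactors = FALSE)
  alleles_out <- data.frame(barcode = barcode[alleles$barcode_i],
                            amplicon_id = ids[alleles$amplicon_i],
                            genotype_id = gname[alleles$genotype_i],
                            slot = alleles$slot,
                            allele_seq = alleles$allele_seq,
                            modified = alleles$modified,
                            n_reads = alleles$n_reads,
                            dropped = alleles$dropped,
                            stringsAsFactors = FALSE)
  structure(list(reads = reads,
                 truth = list(cells = cells, alleles = alleles_out,
                              reads = truth_reads),
                 config = config),
            class = "sc_sim")
}

# substitution + spurious 1-bp indel errors, payload only
inject_errors <- function(payload, sub_rate, indel_rate) {
  N <- length(payload)
  if (N == 0L) return(payload)
  bases <- c("A", "C", "G", "T")
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 4, byrow = TRUE,
                dimnames = list(bases, NULL))
  if (sub_rate > 0) {
    L <- nchar(payload)
    ne <- rbinom(N, L, sub_rate)
    one <- which(ne == 1L)
    if (length(one)) {
      pos <- 1L + floor(runif(length(one)) * L[one])
      orig <- substr(payload[one], pos, pos)
      new <- alt[cbind(match(orig, bases), sample.int(3L, length(one),
                                                      replace = TRUE))]
      keep <- !is.na(new) # skip non-ACGT bases
      substr(payload[one[keep]], pos[keep], pos[keep]) <- new[keep]
    }
    multi <- which(ne >= 2L)
    for (i in multi) {
      s <- strsplit(payload[i], "")[[1]]
      pos <- sample.int(length(s), ne[i])
      for (p in pos) {
        if (s[p] %in% bases) s[p] <- sample(setdiff(bases, s[p]), 1L)
      }
      payload[i] <- paste(s, collapse = "")
    }
  }
  if (indel_rate > 0) {
    L <- nchar(payload)
    ni <- rbinom(N, L, indel_rate)
    hit <- which(ni > 0L)
    for (i in hit) {
      for (k in seq_len(ni[i])) {
        Li <- nchar(payload[i])
        p <- sample.int(Li, 1L)
        if (runif(1) < 0.5 && Li > 1L) { # deletion of one base
          payload[i] <- paste0(substr(payload[i], 1L, p - 1L),
                               substr(payload[i], p + 1L, Li))
        } else { # insertion of one random base after p
          payload[i] <- paste0(substr(payload[i], 1L, p),
                               sample(bases, 1L),
                               substr(payload[i], p + 1L, Li))
        }
      }
    }
  }
  payload
}

#' Truth edit matrix from realized read counts
#'
#' Aggregates the simulator's per-allele read counts into the same
#' cells x amplicons percent-modified matrix the pipeline produces, with
#' the same coverage threshold; in the noiseless limit the pipeline matrix
#' equals this truth exactly.
#'
#' @param sim an `sc_sim`.
#' @param min_reads coverage threshold (default 5).
#' @return an [edit_matrix].
#' @export
sim_truth_matrix <- function(sim, min_reads = 5L) {
  stopifnot(inherits(sim, "sc_sim"))
  al <- data.table::as.data.table(sim$truth$alleles)
  agg <- al[, list(n_reads = sum(n_reads),
                   pct_modified = if (sum(n_reads) > 0)
                     100 * sum(n_reads[modified]) / sum(n_reads)
                   else NA_real_),
            by = list(barcode, amplicon_id)]
  agg <- as.data.frame(agg)
  # coverage-only amplicons (no quantification window) are never quantified
  pan <- sim$config$panel
  haswin <- !vapply(pan$amplicons, function(a) is.null(a$window), logical(1))
  agg$pct_modified[!haswin[agg$amplicon_id]] <- NA_real_
  agg <- agg[agg$n_reads > 0L, , drop = FALSE]
  build_edit_matrix(agg, cells = sort(sim$truth$cells$barcode), pan = pan,
                    min_reads = min_reads)
}

#' Truth zygosity calls from realized allele counts
#'
#' Groups realized reads by allele sequence per (cell, CRISPR amplicon),
#' computes the modified fraction and the second-allele frequency, and
#' applies the standard zygosity rule. This is the "what was actually
#' sequenced" truth; see [sim_programmed_zygosity()] for the programmed
#' genotype classes.
#'
#' @param sim an `sc_sim`.
#' @param min_reads coverage threshold (default 5).
#' @inheritParams classify_zygosity
#' @return data frame `barcode`, `amplicon_id`, `n_reads`, `pct_modified`,
#'   `heterozygosity`, `zygosity`.
#' @export
sim_truth_zygosity <- function(sim, min_reads = 5L, lower = 20, upper = 80) {
  stopifnot(inherits(sim, "sc_sim"))
  pan <- sim$config$panel
  haswin <- !vapply(pan$amplicons, function(a) is.null(a$window), logical(1))
  al <- data.table::as.data.table(sim$truth$alleles)
  al <- al[haswin[amplicon_id] & n_reads > 0L]
  bys <- al[, list(count = sum(n_reads), nmod = sum(n_reads[modified])),
            by = list(barcode, amplicon_id, allele_seq)]
  data.table::setorder(bys, barcode, amplicon_id, -count, allele_seq)
  out <- bys[, list(n_reads = sum(count),
                    pct_modified = 100 * sum(nmod) / sum(count),
                    heterozygosity = if (.N >= 2L)
                      100 * count[2] / sum(count) else 0),
             by = list(barcode, amplicon_id)]
  out <- as.data.frame(out[n_reads >= min_reads])
  out$zygosity <- classify_zygosity(out$pct_modified, out$heterozygosity,
                                    lower, upper)
  out
}

#' Programmed zygosity classes of singlet cells
#'
#' @param sim an `sc_sim`.
#' @return data frame `barcode`, `amplicon_id`, `zygosity` for every
#'   singlet barcode and CRISPR amplicon, from the programmed genotypes.
#' @export
sim_programmed_zygosity <- function(sim) {
  stopifnot(inherits(sim, "sc_sim"))
  cls <- sim$config$genotype_class
  cells <- sim$truth$cells
  single <- cells[!cells$doublet, , drop = FALSE]
  out <- do.call(rbind, lapply(names(cls), function(a) {
    data.frame(barcode = single$barcode, amplicon_id = a,
               zygosity = unname(cls[[a]][single$g1]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a simulation to disk
#'
#' Writes the reads as FASTQ (flat quality), the truth tables as TSV, and
#' a JSON echo of the configuration for reproducibility.
#'
#' @param sim an `sc_sim`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq.gz"))
  write.table(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$alleles, file.path(dir, "truth_alleles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$reads, file.path(dir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  echo <- list(panel = cfg$panel$name, n_barcodes = cfg$n_barcodes,
               genotypes = cfg$genotype_ids, proportions = cfg$proportions,
               doublet_rate = cfg$doublet_rate, ado_rate = cfg$ado_rate,
               mean_coverage = cfg$mean_coverage,
               coverage_dispersion = cfg$coverage_dispersion,
               sub_error_rate = cfg$sub_error_rate,
               indel_error_rate = cfg$indel_error_rate, seed = cfg$seed)
  jsonlite::write_json(echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
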