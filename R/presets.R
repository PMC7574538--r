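#' Demonstration amplicon panel with embedded guides
#'
#' Generates a deterministic panel of random amplicon references with a
#' 20-nt guide spacer and NGG PAM embedded at a fixed position in every
#' CRISPR amplicon. The nine bases upstream of the PAM follow a period-4
#' pattern (`ACGTACGTA`), so short deletions placed at the cut site cannot
#' left-shift out of the quantification window -- a deliberately
#' non-repetitive cut-site context.
#'
#' The first six on-target amplicons are named after the murine
#' leukemia-driver loci this assay class is typically aimed at
#' (Trp53, Atm, Chd2, Samhd1, Mga, Birc3).
#'
#' @param n_on,n_off,n_control number of amplicons per category.
#' @param amp_len amplicon length (default 200; panels of this assay class
#'   run about 196-260 bp).
#' @param seed RNG seed for the random reference sequence (restores the
#'   caller's RNG state).
#' @return an `amplicon_panel`.
#' @export
demo_panel <- function(n_on = 6L, n_off = 0L, n_control = 0L,
                       amp_len = 200L, seed = 42L) {
  stopifnot(n_on + n_off + n_control >= 1L, amp_len >= 120L)
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed,
                               envir = globalenv()), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand <- function(k) paste(sample(bases, k, replace = TRUE), collapse = "")
  gene_names <- c("Trp53", "Atm", "Chd2", "Samhd1", "Mga", "Birc3")
  on_ids <- if (n_on <= 6L) gene_names[seq_len(n_on)]
            else c(gene_names, sprintf("on%02d", seq_len(n_on - 6L) + 6L))
  make_crispr <- function(id, category) {
    spacer <- paste0(rand(11L), "ACGTACGTA") # fixed cut-site context
    ref <- paste0(rand(55L), spacer, "TGG", rand(amp_len - 78L))
    amplicon(id, ref, category, guide_spacer = spacer,
             guide_strand = "forward")
  }
  amps <- c(
    lapply(on_ids, make_crispr, category = "on_target"),
    lapply(sprintf("off%02d", seq_len(n_off)), make_crispr,
           category = "off_target"),
    lapply(sprintf("ctrl%02d", seq_len(n_control)), function(id)
      amplicon(id, rand(amp_len), "control"))
  )
  panel(amps, name = "demo_panel")
}

# per-line deletion edits used by the presets: lengths 2/3 at the cut, and
# a distinct 5-bp deletion for compound heterozygotes; none of these can
# left-shift in the demo panel's period-4 cut-site context
preset_edit1 <- function(i) edit_spec("del", offset = -1L, len = 2L + (i - 1L) %% 2L)
preset_edit2 <- function() edit_spec("del", offset = -2L, len = 5L)

#' Admixture-of-single-edited-lines simulation preset
#'
#' Models the pooling of singly-edited cell lines: each line carries edits
#' at exactly one on-target locus, so any barcode with editing at two or
#' more targets betrays a doublet. Lines are homozygous-edited clones by
#' default (`zygosity = c(hom = 1)`); supply weights over
#' `c("het", "hom", "comphet")` to split each line into zygosity
#' subclones. Defaults reflect the platform's typical operating regime:
#' coverage 26x per amplicon per cell, ~7.5% allelic dropout, 8% doublets,
#' 0.1% substitution error.
#'
#' @param pan an `amplicon_panel` (its on-targets define the lines).
#' @param n_barcodes number of barcodes (default 5000).
#' @param proportions per-line mixture proportions (default equal).
#' @param doublet_rate doublet probability (default 0.08).
#' @param zygosity named weights over `het`, `hom`, `comphet`
#'   (default pure hom).
#' @param ado_rate,mean_coverage,coverage_dispersion,sub_error_rate,indel_error_rate,structure,seed
#'   passed to [sim_config()].
#' @return a [sim_config()].
#' @export
admixture_preset <- function(pan, n_barcodes = 5000L, proportions = NULL,
                             doublet_rate = 0.08, zygosity = c(hom = 1),
                             ado_rate = 0.075, mean_coverage = 26,
                             coverage_dispersion = 8,
                             sub_error_rate = 0.001,
                             indel_error_rate = 1e-4,
                             structure = read_structure(), seed = 1L) {
  ot <- on_targets(pan)
  K <- length(ot)
  if (K < 1L) stop("panel has no on-target amplicons")
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  stopifnot(length(proportions) == K)
  zyg <- zygosity / sum(zygosity)
  stopifnot(all(names(zyg) %in% c("het", "hom", "comphet")))
  pop <- list(); prop <- numeric(0)
  for (i in seq_len(K)) {
    e1 <- preset_edit1(i)
    for (z in names(zyg)) {
      if (zyg[[z]] <= 0) next
      pair <- switch(z,
                     het = list("ref", e1),
                     hom = list(e1, e1),
                     comphet = list(e1, preset_edit2()))
      pop[[length(pop) + 1L]] <-
        genotype(paste0(ot[i], "_", z),
                 edits = setNames(list(pair), ot[i]))
      prop <- c(prop, proportions[i] * zyg[[z]])
    }
  }
  sim_config(pan, n_barcodes, pop, prop, doublet_rate = doublet_rate,
             ado_rate = ado_rate, mean_coverage = mean_coverage,
             coverage_dispersion = coverage_dispersion,
             sub_error_rate = sub_error_rate,
             indel_error_rate = indel_error_rate, structure = structure,
             seed = seed)
}

#' Multiplexed-editing simulation preset
#'
#' Models a cell line transduced with a pool of guides: each cell acquires
#' a homozygous edit at each on-target independently with its transduction
#' probability, producing a Binomial multiplicity law over 0..K edited
#' targets. Doublets default to zero here: multi-edited cells are biology
#' in this design, and the pipeline performs no doublet flagging outside
#' admixture mode.
#'
#' @param pan an `amplicon_panel`.
#' @param n_barcodes number of barcodes (default 5000).
#' @param transduction_prob per-target edit probability, scalar or one per
#'   on-target (default 0.3).
#' @param doublet_rate doublet probability (default 0).
#' @inheritParams admixture_preset
#' @return a [sim_config()].
#' @export
multiplexed_preset <- function(pan, n_barcodes = 5000L,
                               transduction_prob = 0.3, doublet_rate = 0,
                               ado_rate = 0.075, mean_coverage = 26,
                               coverage_dispersion = 8,
                               sub_error_rate = 0.001,
                               indel_error_rate = 1e-4,
                               structure = read_structure(), seed = 1L) {
  ot <- on_targets(pan)
  K <- length(ot)
  if (K < 1L) stop("panel has no on-target amplicons")
  if (K > 12L) stop("multiplexed preset enumerates 2^K genotypes; K > 12 ",
                    "is not supported")
  p <- rep(transduction_prob, length.out = K)
  stopifnot(all(p >= 0 & p <= 1))
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  colnames(grid) <- ot
  pop <- list(); prop <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    inc <- grid[r, ]
    prop[r] <- prod(ifelse(inc, p, 1 - p))
    edits <- list()
    for (i in which(inc)) {
      e <- preset_edit1(i)
      edits[[ot[i]]] <- list(e, e)
    }
    pop[[r]] <- genotype(paste0("combo_",
                                paste(as.integer(inc), collapse = "")),
                         edits = edits)
  }
  sim_config(pan, n_barcodes, pop, prop, doublet_rate = doublet_rate,
             ado_rate = ado_rate, mean_coverage = mean_coverage,
             coverage_dispersion = coverage_dispersion,
             sub_error_rate = sub_error_rate,
             indel_error_rate = indel_error_rate, structure = structure,
             seed = seed)
}
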