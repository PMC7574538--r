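test_that("simulation is deterministic given the seed", {
  pan <- toy_panel(2, 0, 1)
  cfg <- admixture_preset(pan, n_barcodes = 15, seed = 19,
                          mean_coverage = 12)
  s1 <- simulate_reads(cfg)
  s2 <- simulate_reads(cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$alleles, s2$truth$alleles)
  expect_identical(s1$truth$cells, s2$truth$cells)
})

test_that("truth read counts are conserved and barcodes traceable", {
  pan <- toy_panel(2, 0, 1)
  cfg <- admixture_preset(pan, n_barcodes = 40, seed = 20)
  sim <- simulate_reads(cfg)
  expect_identical(nrow(sim$reads), sum(sim$truth$alleles$n_reads))
  expect_identical(nrow(sim$reads), nrow(sim$truth$reads))
  expect_true(all(sim$truth$reads$barcode %in% sim$truth$cells$barcode))
  # dropped alleles emit no reads
  expect_true(all(sim$truth$alleles$n_reads[sim$truth$alleles$dropped] == 0L))
})

test_that("a homozygous-edited population reports 100% modification", {
  pan <- toy_panel(1, 0, 0)
  e <- edit_spec("del", offset = -1L, len = 3L)
  cfg <- sim_config(pan, 20, list(genotype("hom",
                                           setNames(list(list(e, e)),
                                                    names(pan$amplicons)))),
                    1, mean_coverage = 20, seed = 21)
  sim <- simulate_reads(cfg)
  expect_true(all(sim$truth$reads$modified))
  q <- quantify_cells(filter_reads(sim$reads)$tagged, pan)
  s <- q$summaries[q$summaries$called, ]
  expect_true(all(s$pct_modified == 100))
})

test_that("heterozygous allele frequencies are binomial around one half", {
  pan <- toy_panel(1, 0, 0)
  e <- edit_spec("del", offset = -1L, len = 3L)
  cfg <- sim_config(pan, 5, list(genotype("het",
                                          setNames(list(list("ref", e)),
                                                   names(pan$amplicons)))),
                    1, mean_coverage = 1000, coverage_dispersion = Inf,
                    seed = 22)
  sim <- simulate_reads(cfg)
  al <- sim$truth$alleles
  for (bc in unique(al$barcode)) {
    sub <- al[al$barcode == bc, ]
    n <- sum(sub$n_reads)
    f <- sub$n_reads[sub$modified] / n
    expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
  }
})

test_that("invalid configurations are rejected", {
  pan <- toy_panel(1, 0, 0)
  g <- genotype("wt")
  expect_error(sim_config(pan, 10, list(g), 0.9), "sum to 1")
  expect_error(sim_config(pan, 10, list(g), 1, doublet_rate = 1.5),
               "rates")
  # programmed edit outside the amplicon
  far <- edit_spec("del", offset = 500L, len = 3L)
  expect_error(
    sim_config(pan, 10,
               list(genotype("bad", setNames(list(list(far, far)),
                                             names(pan$amplicons)))),
    1), "outside amplicon")
})

test_that("admixture preset: single-line mixtures make doublets invisible", {
  pan <- toy_panel(2, 0, 0)
  cfg <- admixture_preset(pan, n_barcodes = 60, proportions = c(1, 0),
                          doublet_rate = 0.3, ado_rate = 0,
                          sub_error_rate = 0, indel_error_rate = 0,
                          mean_coverage = 25, seed = 23)
  sim <- simulate_reads(cfg)
  q <- quantify_cells(filter_reads(sim$reads)$tagged, pan)
  rep <- flag_doublets_admixture(count_edited_targets(q$matrix))
  expect_identical(rep$n_flagged, 0L)
})

test_that("multiplexed preset: degenerate transduction probabilities", {
  pan <- toy_panel(3, 0, 0)
  cfg0 <- multiplexed_preset(pan, n_barcodes = 25, transduction_prob = 0,
                             ado_rate = 0, sub_error_rate = 0,
                             indel_error_rate = 0, mean_coverage = 20,
                             seed = 24)
  sim0 <- simulate_reads(cfg0)
  q0 <- quantify_cells(filter_reads(sim0$reads)$tagged, pan)
  prof0 <- count_edited_targets(q0$matrix)
  expect_true(all(prof0$profile$n_edited == 0L))
  cfg1 <- multiplexed_preset(pan, n_barcodes = 25, transduction_prob = 1,
                             ado_rate = 0, sub_error_rate = 0,
                             indel_error_rate = 0, mean_coverage = 20,
                             seed = 25)
  sim1 <- simulate_reads(cfg1)
  q1 <- quantify_cells(filter_reads(sim1$reads)$tagged, pan)
  prof1 <- count_edited_targets(q1$matrix)
  # fully covered cells carry all three edits
  full <- prof1$profile$n_covered == 3L
  expect_true(all(prof1$profile$n_edited[full] == 3L))
})

test_that("programmed edits outside the window are truth-flagged unmodified", {
  pan <- toy_panel(1, 0, 0)
  amp <- pan$amplicons[[1]]
  off_window <- edit_spec("del", offset = 15L, len = 2L)
  cfg <- sim_config(pan, 5,
                    list(genotype("far", setNames(list(list(off_window,
                                                            off_window)),
                                                  amp$amplicon_id))),
                    1, mean_coverage = 20, seed = 26)
  sim <- simulate_reads(cfg)
  expect_true(all(!sim$truth$reads$modified))
  q <- quantify_cells(filter_reads(sim$reads)$tagged, pan)
  s <- q$summaries[q$summaries$called, ]
  expect_true(all(s$pct_modified == 0))
})

test_that("simulation output round-trips to disk", {
  pan <- toy_panel(1, 0, 1)
  cfg <- admixture_preset(pan, n_barcodes = 8, mean_coverage = 8, seed = 27)
  sim <- simulate_reads(cfg)
  dir <- file.path(tempdir(), "simout")
  write_sim(sim, dir)
  back <- read_fastq(file.path(dir, "reads.fastq.gz"))
  expect_identical(back$seq, sim$reads$seq)
  truth <- read.delim(file.path(dir, "truth_cells.tsv"))
  expect_identical(nrow(truth), 8L)
  cfg_echo <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_identical(cfg_echo$n_barcodes, 8L)
  expect_identical(cfg_echo$seed, 27L)
})

test_that("allelic dropout distorts realized counts but is recorded", {
  pan <- toy_panel(1, 0, 0)
  cfg <- admixture_preset(pan, n_barcodes = 200, zygosity = c(het = 1),
                          ado_rate = 0.5, doublet_rate = 0,
                          sub_error_rate = 0, indel_error_rate = 0,
                          mean_coverage = 10, seed = 28)
  sim <- simulate_reads(cfg)
  al <- sim$truth$alleles
  expect_gt(sum(al$dropped), 0L)
  drop_rate <- mean(al$dropped)
  expect_lt(abs(drop_rate - 0.5), 3 * sqrt(0.25 / nrow(al)))
})
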