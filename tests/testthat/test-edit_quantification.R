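# helper: read with a deletion of `len` bases at 0-based ref position `start`
del_read <- function(ref, start, len) {
  paste0(substr(ref, 1, start), substr(ref, start + len + 1, nchar(ref)))
}

# helper: read with `seq` inserted at 0-based inter-base position `pos`
ins_read <- function(ref, pos, seq) {
  paste0(substr(ref, 1, pos), seq, substr(ref, pos + 1, nchar(ref)))
}

test_that("perfect reads are unmodified; cut-spanning deletions are modified", {
  pan <- toy_panel(1, 0, 0)
  amp <- pan$amplicons[[1]]
  cut <- amp$cut_site
  aln <- align_semiglobal(amp$ref_seq, amp$ref_seq)
  expect_false(classify_read(aln, amp))
  # 3-base deletion spanning the cut site
  aln_del <- align_semiglobal(del_read(amp$ref_seq, cut - 1L, 3L),
                              amp$ref_seq)
  expect_true(classify_read(aln_del, amp))
  # 2-base deletion 10 bases downstream of the window
  aln_far <- align_semiglobal(del_read(amp$ref_seq, amp$window[2] + 10L, 2L),
                              amp$ref_seq)
  expect_false(classify_read(aln_far, amp))
  # control amplicons cannot be classified
  ctrl <- toy_panel(1, 0, 1)$amplicons$ctrl01
  expect_error(classify_read(aln, ctrl), "no quantification window")
})

test_that("deletion window calls agree with interval intersection at every placement", {
  pan <- toy_panel(1, 0, 0, seed = 71)
  amp <- pan$amplicons[[1]]
  ws <- amp$window[1]; we <- amp$window[2]
  L <- nchar(amp$ref_seq)
  for (start in 0:(L - 2L)) {
    read <- del_read(amp$ref_seq, start, 2L)
    aln <- align_semiglobal(read, amp$ref_seq)
    # oracle: left-normalize the placement by string logic, then intersect
    p <- oracle_shift_del(amp$ref_seq, start, 2L)
    expect_identical(classify_read(aln, amp), p < we && p + 2L > ws,
                     label = paste("deletion at", start))
  }
})

test_that("insertions at the window boundary count as inside (closed interval)", {
  pan <- toy_panel(1, 0, 0)
  amp <- pan$amplicons[[1]]
  ws <- amp$window[1]; we <- amp$window[2]
  ref <- amp$ref_seq
  base_at <- function(i) substr(ref, i, i + 1L) # 0-based single base
  non_shifting_ins <- function(pos) {
    # inserted base differs from the reference base left of the anchor,
    # so the insertion cannot left-shift
    setdiff(c("A", "C", "G", "T"),
            substr(ref, pos, pos))[1]
  }
  for (pos in c(ws, we)) {
    aln <- align_semiglobal(ins_read(ref, pos, non_shifting_ins(pos)), ref)
    expect_true(classify_read(aln, amp), label = paste("anchor", pos))
  }
  for (pos in c(ws - 3L, we + 3L)) {
    aln <- align_semiglobal(ins_read(ref, pos, non_shifting_ins(pos)), ref)
    expect_false(classify_read(aln, amp), label = paste("anchor", pos))
  }
})

test_that("window substitutions count only when substitutions_count is on", {
  pan <- toy_panel(1, 0, 0)
  amp <- pan$amplicons[[1]]
  read <- amp$ref_seq
  p1 <- amp$window[1] + 1L # 1-based position inside the window
  substr(read, p1 + 1L, p1 + 1L) <- setdiff(c("A", "C", "G", "T"),
                                            substr(read, p1 + 1L, p1 + 1L))[1]
  aln <- align_semiglobal(read, amp$ref_seq)
  expect_false(classify_read(aln, amp))
  expect_true(classify_read(aln, amp, count_substitutions = TRUE))
})

test_that("cell-amplicon summaries report the top two alleles", {
  # fewer than min_reads: NO_CALL
  s <- summarize_cell_amplicon(rep(FALSE, 4), rep("AAAA", 4))
  expect_false(s$called)
  expect_true(is.na(s$pct_modified))
  # all-reference cell
  s0 <- summarize_cell_amplicon(rep(FALSE, 10), rep("AAAA", 10))
  expect_identical(s0$pct_modified, 0)
  expect_identical(s0$heterozygosity, 0)
  # 6 reads of one deletion allele, 4 reference
  s1 <- summarize_cell_amplicon(c(rep(TRUE, 6), rep(FALSE, 4)),
                                c(rep("AA--", 6), rep("AAAA", 4)))
  expect_identical(s1$pct_modified, 60)
  expect_identical(s1$allele1_seq, "AA--")
  expect_true(s1$allele1_modified)
  expect_identical(s1$allele1_freq, 0.6)
  expect_identical(s1$allele2_seq, "AAAA")
  expect_false(s1$allele2_modified)
  expect_identical(s1$allele2_freq, 0.4)
  expect_identical(s1$heterozygosity, 40)
  # count ties break lexicographically by allele sequence
  s2 <- summarize_cell_amplicon(rep(c(TRUE, FALSE), 5),
                                rep(c("TT", "AA"), 5))
  expect_identical(s2$allele1_seq, "AA")
  expect_identical(s2$allele2_seq, "TT")
})

test_that("grouped pipeline summaries equal the single-group computation", {
  pan <- toy_panel(2, 0, 0)
  cfg <- admixture_preset(pan, n_barcodes = 20, doublet_rate = 0,
                          zygosity = c(het = 0.5, hom = 0.5),
                          ado_rate = 0, mean_coverage = 15,
                          sub_error_rate = 0, indel_error_rate = 0,
                          seed = 9)
  sim <- simulate_reads(cfg)
  tagged <- filter_reads(sim$reads)$tagged
  q <- quantify_cells(tagged, pan)
  asg <- sceditr:::assign_batch(tagged$payload, pan)
  keep <- !is.na(asg$amplicon_id)
  groups <- split(which(keep),
                  paste(tagged$barcode[keep], asg$amplicon_id[keep]))
  for (g in sample(groups, 10)) {
    ref_row <- summarize_cell_amplicon(asg$modified[g], asg$allele[g],
                                       tagged$barcode[g[1]],
                                       asg$amplicon_id[g[1]])
    got <- q$summaries[q$summaries$barcode == ref_row$barcode &
                         q$summaries$amplicon_id == ref_row$amplicon_id, ]
    expect_identical(nrow(got), 1L)
    expect_identical(got$n_reads, ref_row$n_reads)
    expect_equal(got$pct_modified, ref_row$pct_modified)
    expect_identical(got$allele1_seq, ref_row$allele1_seq)
    expect_equal(got$allele1_freq, ref_row$allele1_freq)
    expect_identical(got$allele2_seq, ref_row$allele2_seq)
    expect_equal(got$heterozygosity, ref_row$heterozygosity)
  }
})

test_that("allele frequencies sum to one for two-allele cells", {
  pan <- toy_panel(1, 0, 0)
  cfg <- admixture_preset(pan, n_barcodes = 30, doublet_rate = 0,
                          zygosity = c(het = 1), ado_rate = 0,
                          mean_coverage = 20, sub_error_rate = 0,
                          indel_error_rate = 0, seed = 10)
  sim <- simulate_reads(cfg)
  q <- quantify_cells(filter_reads(sim$reads)$tagged, pan)
  s <- q$summaries[q$summaries$called, ]
  expect_true(all(abs(s$allele1_freq + s$allele2_freq - 1) < 1e-9))
})

test_that("the edit matrix is dense when covered and NA when not", {
  summaries <- data.frame(
    barcode = rep(c("c1", "c2"), each = 3),
    amplicon_id = rep(c("a", "b", "c"), 2),
    n_reads = c(10L, 8L, 6L, 9L, 3L, 7L),
    pct_modified = c(0, 50, 100, 25, 60, 75))
  em <- build_edit_matrix(summaries, min_reads = 5L)
  expect_identical(dim(em$pct), c(2L, 3L))
  expect_identical(sum(is.na(em$pct)), 1L)
  expect_true(is.na(em$pct["c2", "b"]))
  expect_identical(em$coverage["c2", "b"], 3L)
  # duplicate (cell, amplicon) rows are an error
  expect_error(build_edit_matrix(rbind(summaries, summaries[1, ])),
               "duplicate")
})

test_that("matrix export writes TSV and MatrixMarket with index files", {
  summaries <- data.frame(barcode = c("c1", "c1", "c2"),
                          amplicon_id = c("a", "b", "a"),
                          n_reads = c(10L, 10L, 10L),
                          pct_modified = c(0, 50, 100))
  em <- build_edit_matrix(summaries)
  prefix <- file.path(tempdir(), "em_test")
  write_edit_matrix(em, prefix)
  expect_true(file.exists(paste0(prefix, "_pct.tsv")))
  mm <- Matrix::readMM(paste0(prefix, "_pct.mtx"))
  expect_identical(dim(mm), c(2L, 2L))
  expect_identical(readLines(paste0(prefix, "_rows.txt")), c("c1", "c2"))
})

test_that("bulk quantification reproduces programmed editing fractions", {
  pan <- toy_panel(2, 0, 0)
  amp <- pan$amplicons[[1]]
  edited <- del_read(amp$ref_seq, amp$cut_site - 1L, 3L)
  reads <- data.frame(
    read_id = sprintf("b%03d", 1:120),
    seq = c(rep(edited, 85), rep(amp$ref_seq, 15),
            rep(pan$amplicons[[2]]$ref_seq, 20)))
  out <- quantify_bulk(reads, pan)
  expect_identical(out$n_reads, c(100L, 20L))
  expect_equal(out$pct_modified, c(85, 0))
  # empty input: empty report
  expect_identical(nrow(quantify_bulk(reads[0, ], pan)), 0L)
})

test_that("substitution-only sequencing noise never inflates modification", {
  pan <- toy_panel(1, 0, 0)
  # all-reference population under heavy substitution-only noise
  cfg <- sim_config(pan, 25, list(genotype("wt")), 1,
                    mean_coverage = 20, sub_error_rate = 0.01, seed = 12)
  sim <- simulate_reads(cfg)
  q <- quantify_cells(filter_reads(sim$reads)$tagged, pan)
  s <- q$summaries[q$summaries$called, ]
  expect_true(all(s$pct_modified == 0))
})
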