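test_that("barcode extraction inverts the exact read construction", {
  set.seed(1)
  st <- read_structure()
  bc1 <- rand_dna(9); bc2 <- rand_dna(9); payload <- rand_dna(60)
  read <- data.frame(read_id = "r1",
                     seq = paste0(st$constant1, bc1, st$constant2, bc2,
                                  st$constant3, payload))
  out <- extract_and_trim(read, st)
  expect_identical(out$status, "ok")
  expect_identical(out$barcode, paste0(bc1, bc2))
  expect_identical(nchar(out$barcode), 18L)
  expect_identical(out$payload, payload)
})

test_that("45-base payloads are discarded as short_read", {
  set.seed(2)
  st <- read_structure()
  read <- data.frame(read_id = "r1",
                     seq = paste0(st$constant1, rand_dna(9), st$constant2,
                                  rand_dna(9), st$constant3, rand_dna(45)))
  out <- extract_and_trim(read, st)
  expect_identical(out$status, "short_read")
  # one more base and the read is retained (46-bp minimum)
  read$seq <- paste0(read$seq, "A")
  expect_identical(extract_and_trim(read, st)$status, "ok")
})

test_that("17-base barcodes are discarded as short_barcode", {
  set.seed(3)
  st <- read_structure()
  read <- data.frame(read_id = "r1",
                     seq = paste0(st$constant1, rand_dna(9), st$constant2,
                                  rand_dna(8)))
  out <- extract_and_trim(read, st)
  expect_identical(nchar(out$barcode), 17L)
  expect_identical(out$status, "short_barcode")
})

test_that("corrupt constants yield structure_not_found, tolerantly if asked", {
  set.seed(4)
  st <- read_structure()
  c1_bad <- st$constant1
  substr(c1_bad, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                  substr(c1_bad, 3, 3))[1]
  read <- data.frame(read_id = "r1",
                     seq = paste0(c1_bad, rand_dna(9), st$constant2,
                                  rand_dna(9), st$constant3, rand_dna(60)))
  expect_identical(extract_and_trim(read, st)$status, "structure_not_found")
  tol <- read_structure(max_constant_mismatches = 1L)
  expect_identical(extract_and_trim(read, tol)$status, "ok")
})

test_that("filter tallies conserve the input count", {
  reads <- programmed_fate_reads(n_ok = 20, n_short_read = 5,
                                 n_short_barcode = 3)
  fl <- filter_reads(reads)
  expect_identical(fl$stats$input, 28L)
  expect_identical(fl$stats$retained, 20L)
  expect_identical(fl$stats$short_read, 5L)
  expect_identical(fl$stats$short_barcode, 3L)
  expect_identical(fl$stats$input,
                   fl$stats$retained + fl$stats$short_read +
                     fl$stats$short_barcode + fl$stats$structure_not_found)
  # empty input: all counters zero
  fl0 <- filter_reads(reads[0, , drop = FALSE])
  expect_identical(unlist(unclass(fl0$stats)),
                   c(input = 0L, retained = 0L, short_read = 0L,
                     short_barcode = 0L, structure_not_found = 0L))
})

test_that("extraction recovers the true barcode for all error-free reads", {
  pan <- toy_panel(2, 0, 0)
  cfg <- admixture_preset(pan, n_barcodes = 25, doublet_rate = 0,
                          ado_rate = 0, sub_error_rate = 0,
                          indel_error_rate = 0, mean_coverage = 10,
                          seed = 5)
  sim <- simulate_reads(cfg)
  out <- extract_and_trim(sim$reads)
  expect_true(all(out$status == "ok"))
  expect_identical(out$barcode,
                   sim$truth$reads$barcode[match(out$read_id,
                                                 sim$truth$reads$read_id)])
})

test_that("overlapping pairs reconstruct the template exactly", {
  set.seed(6)
  template <- rand_dna(150)
  r1 <- data.frame(read_id = "p1", seq = substr(template, 1, 100))
  r2 <- data.frame(read_id = "p1",
                   seq = revcomp(substr(template, 51, 150)))
  merged <- merge_pairs(r1, r2)
  expect_identical(merged$seq, template)
})

test_that("non-overlapping pairs are force-merged by concatenation", {
  set.seed(7)
  a <- rand_dna(40); b <- rand_dna(40)
  merged <- merge_pairs(data.frame(read_id = "p", seq = a),
                        data.frame(read_id = "p", seq = revcomp(b)))
  expect_identical(merged$seq, paste0(a, b))
})

test_that("the higher-quality base wins at overlap conflicts", {
  set.seed(9)
  template <- rand_dna(60)
  s1 <- template
  s2 <- template
  # conflict at position 40 (1-based), inside the overlap
  newb <- setdiff(c("A", "C", "G", "T"), substr(s1, 40, 40))[1]
  substr(s2, 40, 40) <- newb
  r1 <- data.frame(read_id = "p", seq = substr(s1, 1, 50),
                   qual = strrep("I", 50))
  r2hi <- data.frame(read_id = "p", seq = revcomp(substr(s2, 21, 60)),
                     qual = strrep("J", 40))
  m <- merge_pairs(r1, r2hi, max_mismatch_frac = 0.2)
  expect_identical(substr(m$seq, 40, 40), newb) # r2 quality higher
  r2lo <- data.frame(read_id = "p", seq = revcomp(substr(s2, 21, 60)),
                     qual = strrep("A", 40))
  m2 <- merge_pairs(r1, r2lo, max_mismatch_frac = 0.2)
  expect_identical(substr(m2$seq, 40, 40), substr(s1, 40, 40)) # r1 quality higher
})

test_that("FASTQ round-trips through write and read", {
  set.seed(8)
  reads <- data.frame(read_id = sprintf("r%02d", 1:5),
                      seq = vapply(1:5, function(i) rand_dna(30),
                                   character(1)),
                      qual = strrep("F", 30))
  fq <- tempfile(fileext = ".fastq.gz")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$seq, reads$seq)
  expect_identical(back$qual, reads$qual)
})
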