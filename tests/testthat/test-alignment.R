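test_that("a read identical to the reference aligns perfectly", {
  set.seed(1)
  ref <- rand_dna(40)
  aln <- align_semiglobal(ref, ref)
  expect_identical(aln$score, 2L * 40L)
  expect_identical(nrow(aln$ops), 1L)
  expect_identical(aln$ops$op, "M")
  expect_identical(aln$identity, 1)
})

test_that("a clean 3-base deletion yields one left-shifted D op", {
  # non-repetitive context so the deletion cannot shift
  ref <- "ACGTGCATTGCAGGCTAACG"
  read <- paste0(substr(ref, 1, 7), substr(ref, 11, 20)) # delete [7, 10)
  aln <- align_semiglobal(read, ref)
  d <- aln$ops[aln$ops$op == "D", ]
  expect_identical(nrow(d), 1L)
  expect_identical(d$len, 3L)
  expect_identical(d$ref_pos, oracle_shift_del(ref, 7L, 3L))
  expect_identical(aln$score, 2L * 17L - (5L + 3L * 1L))
})

test_that("deletions in repeats left-normalize to the leftmost placement", {
  ref <- "ACGTAAAAAGCTGATC"
  # deleting any 2 A's from the homopolymer yields the same read
  read <- paste0(substr(ref, 1, 6), substr(ref, 9, 16))
  aln <- align_semiglobal(read, ref)
  d <- aln$ops[aln$ops$op == "D", ]
  expect_identical(nrow(d), 1L)
  # homopolymer starts at 0-based 4; leftmost placement is [4, 6)
  expect_identical(d$ref_pos, 4L)
})

test_that("a single substitution gives one X op and identity (L-1)/L", {
  set.seed(2)
  ref <- rand_dna(30)
  read <- ref
  substr(read, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(ref, 15, 15))[1]
  aln <- align_semiglobal(read, ref)
  expect_identical(sum(aln$ops$op == "X"), 1L)
  expect_identical(sum(aln$ops$op %in% c("I", "D")), 0L)
  expect_equal(aln$identity, 29 / 30)
})

test_that("scores match the brute-force DP oracle on random short pairs", {
  set.seed(3)
  for (i in 1:500) {
    q <- rand_dna(sample(1:12, 1))
    r <- rand_dna(sample(1:12, 1))
    expect_identical(align_semiglobal(q, r)$score,
                     as.integer(oracle_sg_score(q, r)))
  }
})

test_that("scores match Biostrings pairwiseAlignment as an independent check", {
  set.seed(4)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:100) {
    q <- rand_dna(sample(5:25, 1))
    r <- rand_dna(sample(5:25, 1))
    ref_score <- Biostrings::score(Biostrings::pairwiseAlignment(
      q, r, type = "global-local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 1))
    expect_identical(align_semiglobal(q, r)$score, as.integer(ref_score))
  }
})

test_that("alignment is deterministic and reverse-complement symmetric", {
  set.seed(5)
  for (i in 1:50) {
    q <- rand_dna(sample(4:15, 1))
    r <- rand_dna(sample(4:15, 1))
    a1 <- align_semiglobal(q, r)
    a2 <- align_semiglobal(q, r)
    expect_identical(a1$ops, a2$ops)
    expect_identical(a1$score,
                     align_semiglobal(revcomp(q), revcomp(r))$score)
  }
})

test_that("reads are assigned to their amplicon, in either orientation", {
  pan <- toy_panel(3, 0, 0)
  ids <- names(pan$amplicons)
  for (id in ids) {
    ref <- pan$amplicons[[id]]$ref_seq
    expect_identical(assign_amplicon(ref, pan)$amplicon_id, id)
    hit <- assign_amplicon(revcomp(ref), pan)
    expect_identical(hit$amplicon_id, id)
    expect_identical(hit$strand, "-")
  }
})

test_that("score ties across amplicons are reported as ambiguous", {
  set.seed(6)
  shared <- rand_dna(60)
  a1 <- amplicon("c1", paste0(rand_dna(40), shared), "control")
  a2 <- amplicon("c2", paste0(shared, rand_dna(40)), "control")
  pan <- panel(list(a1, a2))
  hit <- assign_amplicon(shared, pan)
  expect_true(is.na(hit$amplicon_id))
  expect_identical(hit$reason, "ambiguous")
})

test_that("degraded reads below min_identity stay unassigned", {
  set.seed(7)
  pan <- toy_panel(2, 0, 0)
  junk <- rand_dna(150)
  hit <- assign_amplicon(junk, pan, min_identity = 0.65)
  expect_true(is.na(hit$amplicon_id))
  expect_identical(hit$reason, "low_identity")
  # 5% substitutions still assign at min_identity 0.8
  ref <- pan$amplicons[[2]]$ref_seq
  read <- ref
  pos <- sample(nchar(ref), round(0.05 * nchar(ref)))
  for (p in pos)
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(ref, p, p))[1]
  hit2 <- assign_amplicon(read, pan, min_identity = 0.8)
  expect_identical(hit2$amplicon_id, names(pan$amplicons)[2])
})

test_that("batch assignment agrees with per-read assignment", {
  set.seed(8)
  pan <- toy_panel(3, 0, 1)
  reads <- character(0)
  for (id in names(pan$amplicons)) {
    ref <- pan$amplicons[[id]]$ref_seq
    mut <- ref
    substr(mut, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ref, 50, 50))[1]
    reads <- c(reads, ref, revcomp(ref), mut)
  }
  reads <- c(reads, rand_dna(150)) # unassignable
  batch <- sceditr:::assign_batch(reads, pan)
  for (i in seq_along(reads)) {
    single <- assign_amplicon(reads[i], pan)
    expect_identical(batch$amplicon_id[i], single$amplicon_id)
    expect_identical(batch$reason[i], single$reason)
  }
})
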