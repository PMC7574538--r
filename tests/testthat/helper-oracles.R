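# Independent reference implementations used as test oracles.

# Brute-force Gotoh DP, score only: global in the read, free at reference
# ends, affine gap cost gap_open + L * gap_extend. Written independently of
# the C++ aligner.
oracle_sg_score <- function(q, r, match = 2, mismatch = 3, gap_open = 5,
                            gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  rb <- strsplit(r, "")[[1]]
  n <- length(qa)
  m <- length(rb)
  NEG <- -1e9
  go <- gap_open + gap_extend
  ge <- gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0
  for (i in seq_len(n) + 1) I[i, 1] <- -(gap_open + (i - 1) * gap_extend)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (qa[i - 1] == rb[j - 1]) match else -mismatch
      M[i, j] <- max(M[i - 1, j - 1], I[i - 1, j - 1], D[i - 1, j - 1]) + s
      I[i, j] <- max(M[i - 1, j] - go, I[i - 1, j] - ge)
      D[i, j] <- max(M[i, j - 1] - go, D[i, j - 1] - ge)
    }
  }
  max(pmax(M[n + 1, ], I[n + 1, ]))
}

# Literal scalar transcription of the zygosity rules.
oracle_zygosity <- function(p, h, lower = 20, upper = 80) {
  if (p < lower) return("WT_WT")
  if (p >= lower && p < upper) return("WT_Mut")
  if (h >= lower) return("Mut_Mut2")
  "Mut_Mut"
}

# Brute-force enumeration of subset intersection counts over a logical
# cells x targets matrix.
oracle_combinations <- function(edited) {
  genes <- colnames(edited)
  K <- length(genes)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), K)))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    subset <- grid[r, ]
    cnt <- sum(apply(edited, 1, function(row) all(row == subset)))
    if (cnt > 0) {
      key <- if (!any(subset)) "(none)" else paste(genes[subset],
                                                   collapse = "+")
      out[[key]] <- cnt
    }
  }
  out
}

# Left-normalized placement of a deletion of length l starting at 0-based
# position p in ref (string logic, independent of the aligner).
oracle_shift_del <- function(ref, p, l) {
  while (p > 0 &&
         substr(ref, p, p) == substr(ref, p + l, p + l)) p <- p - 1
  p
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
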