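# Fixture builders: everything is generated in code at test time.

toy_panel <- function(n_on = 3, n_off = 0, n_control = 1, seed = 11) {
  demo_panel(n_on, n_off, n_control, seed = seed)
}

# A read set with programmed per-read fates for the filter:
# intact reads, reads whose payload is one base too short, and reads
# truncated one base into the second barcode segment.
programmed_fate_reads <- function(n_ok = 850, n_short_read = 100,
                                  n_short_barcode = 50,
                                  structure = read_structure(), seed = 99) {
  set.seed(seed)
  mk <- function(payload_len, bc2_len = 9) {
    paste0(structure$constant1, rand_dna(9), structure$constant2,
           rand_dna(bc2_len),
           if (bc2_len == 9) paste0(structure$constant3,
                                    rand_dna(payload_len)) else "")
  }
  seqs <- c(vapply(seq_len(n_ok), function(i) mk(60), character(1)),
            vapply(seq_len(n_short_read), function(i) mk(45), character(1)),
            vapply(seq_len(n_short_barcode), function(i) mk(0, bc2_len = 8),
                   character(1)))
  fate <- c(rep("ok", n_ok), rep("short_read", n_short_read),
            rep("short_barcode", n_short_barcode))
  o <- sample(length(seqs))
  data.frame(read_id = sprintf("p%05d", seq_along(o)),
             seq = seqs[o], fate = fate[o],
             stringsAsFactors = FALSE)
}

# Long-format Cq table for a 96-cell plate with a programmed multiplicity
# profile (named vector: sgRNA count -> number of cells).
qpcr_fixture <- function(mult = c("1" = 25, "2" = 44, "3" = 15, "4" = 8,
                                  "5" = 4),
                         n_assays = 12, reps = 8, seed = 3) {
  set.seed(seed)
  assays <- sprintf("sg%02d", seq_len(n_assays))
  n_cells <- sum(mult)
  rows <- vector("list", n_cells)
  ci <- 0
  for (k in names(mult)) {
    for (j in seq_len(mult[[k]])) {
      ci <- ci + 1
      present <- sample(assays, as.integer(k))
      cq <- ifelse(rep(assays, each = reps) %in% present,
                   round(runif(n_assays * reps, 10, 20), 2), NA_real_)
      rows[[ci]] <- data.frame(cell = sprintf("cell%03d", ci),
                               assay = rep(assays, each = reps),
                               replicate = rep(seq_len(reps), n_assays),
                               cq = cq, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
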