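# Small in-code fixtures shared across test files.

# A random event table: n_reads reads on one chromosome, contiguous positions.
random_events <- function(n_reads = 3L, n_events = 30L, seed = 1L) {
  set.seed(seed)
  pieces <- lapply(seq_len(n_reads), function(r) {
    start <- sample(0:500, 1L)
    ev <- data.frame(
      read_id = sprintf("r%02d", r), chrom = "chr1", strand = "+",
      ref_pos = start + seq_len(n_events) - 1L,
      ref_base = sample(c("A", "C", "G", "T"), n_events, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ev$samples <- lapply(seq_len(n_events), function(i) rnorm(sample(2:9, 1L), 0, 1))
    ev
  })
  do.call(rbind, pieces)
}

# Labeled windows with a planted mean shift on the center events: an easy,
# quickly learnable two-class problem for training smoke tests.
separable_windows <- function(n = 200L, w = 9L, shift = 3, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- array(rnorm(w * 7L * n, 0, 0.5), dim = c(w, 7L, n))
  ctr <- (w + 1L) %/% 2L
  x[, 4:7, ] <- 0
  for (i in seq_len(n)) {
    x[, 3L + sample(4L, 1L), i] <- 1          # arbitrary one-hot rows
    x[ctr, 1L, i] <- x[ctr, 1L, i] + shift * y[i]
  }
  meta <- data.frame(read_id = sprintf("r%04d", seq_len(n)), chrom = "chr1",
                     strand = "+",
                     ref_pos = rep(seq_len(max(2L, n %/% 4L)), length.out = n),
                     stringsAsFactors = FALSE)
  new_meth_windows(x, meta, as.integer(y), w)
}

tiny_model_config <- function(seed = 7L, dropout = 0) {
  model_config(d_model = 10L, n_heads = 2L, n_layers = 2L, d_ff = 12L,
               window = 5L, n_pe = 3L, dropout = dropout, seed = seed)
}
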