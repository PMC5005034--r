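# Independent oracles and small fixtures, kept free of the package's own
# string-scanning and windowing code paths.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# naive left-to-right substring scan: 0-based cut position at each motif end
naive_cut_positions <- function(sequence, motif) {
  k <- nchar(motif)
  cuts <- integer(0)
  for (i in seq_len(nchar(sequence) - k + 1L)) {
    if (substr(sequence, i, i + k - 1L) == motif) {
      cuts <- c(cuts, i + k - 1L)   # 1-based inclusive end == 0-based cut
    }
  }
  cuts
}

# brute-force per-read window accumulation: each read of fragment f falls in
# the fixed window containing f's start coordinate
naive_fixed_window_scores <- function(count_vector, fragment_map, window_size,
                                      seq_len_total = max(fragment_map$end)) {
  n_win <- ceiling(seq_len_total / window_size)
  scores <- numeric(n_win)
  for (f in seq_len(nrow(fragment_map))) {
    for (r in seq_len(count_vector$count[f])) {
      w <- fragment_map$start[f] %/% window_size + 1L
      scores[w] <- scores[w] + 1
    }
  }
  scores
}

# shared small simulated run, built once per test session
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        sequence_length = 60000L,
        reads_per_sample = 5000L,
        undigested_fraction = 0.1,
        self_ligation_fraction = 0.05,
        enhancer_folds = data.frame(position = c(10000L, 45000L),
                                    condition = c("B", "B"),
                                    fold = c(3, 0.5)),
        seed = 42L
      )
      ref <- sim_reference(cfg)
      cache <<- list(cfg = cfg, ref = ref,
                     barcodes = barcode_table(
                       c("s1", "s2", "s3", "s4"),
                       c("ACGTGG", "TGCACC", "GATCAA", "CTAGTT")))
    }
    cache
  }
})
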