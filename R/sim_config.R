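#' Simulation configuration for synthetic 4C-seq data
#'
#' Bundles and validates the parameters of the generative model used
#' throughout the synthetic-data module: a uniform-random genome digested by a
#' primary (CATG, NlaIII-like) and secondary (GATC, DpnII-like) enzyme, a bait
#' fragment, per-fragment contact probabilities following a power-law distance
#' decay, condition-specific fold changes planted at designated "enhancer"
#' fragments, and a read mixture containing contact, undigested (bait
#' run-through) and self-ligation reads.
#'
#' @param sequence_length Genome length in bases.
#' @param primary_motif Primary enzyme recognition motif (default `"CATG"`).
#' @param secondary_motif Secondary enzyme motif (default `"GATC"`).
#' @param bait_position 0-based coordinate of the viewpoint; the primary
#'   fragment containing it becomes the bait. Default: sequence midpoint.
#' @param decay_exponent Power-law decay exponent `alpha` (> 0) in the
#'   baseline contact weight `(1 + d)^-alpha`, `d` the midpoint distance to
#'   the bait. Default 1.
#' @param enhancer_folds Data frame with columns `position` (0-based
#'   coordinate of the planted fragment), `condition` (label) and `fold`
#'   (> 0 multiplier applied to that fragment's pre-normalisation weight in
#'   that condition). `NULL` for no planted effects.
#' @param undigested_fraction,self_ligation_fraction Proportions in `[0, 1]`
#'   of reads that run through into the bait-adjacent fragment (failed
#'   digestion) or re-capture the bait itself (self-ligation);
#'   their sum must not exceed 1.
#' @param reads_per_sample Number of reads emitted per sample library.
#' @param read_length Read length in bases (default 100, single-end).
#' @param seed Integer seed; every generator operation is a pure function of
#'   (inputs, seed).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sequence_length = 100000L,
                       primary_motif = "CATG",
                       secondary_motif = "GATC",
                       bait_position = sequence_length %/% 2L,
                       decay_exponent = 1,
                       enhancer_folds = NULL,
                       undigested_fraction = 0.05,
                       self_ligation_fraction = 0.05,
                       reads_per_sample = 10000L,
                       read_length = 100L,
                       seed = 1L) {
  check_dna(primary_motif, "primary_motif")
  check_dna(secondary_motif, "secondary_motif")
  if (sequence_length < 10L * read_length) {
    abort("`sequence_length` must be at least 10 * read_length")
  }
  if (bait_position < 0 || bait_position >= sequence_length) {
    abort("`bait_position` must lie in [0, sequence_length)")
  }
  if (!is.numeric(decay_exponent) || decay_exponent <= 0) {
    abort("`decay_exponent` must be > 0")
  }
  if (undigested_fraction < 0 || self_ligation_fraction < 0 ||
      undigested_fraction + self_ligation_fraction > 1) {
    abort("undigested_fraction + self_ligation_fraction must lie in [0, 1]")
  }
  if (!is.null(enhancer_folds)) {
    enhancer_folds <- as_tibble(enhancer_folds)
    stopifnot(all(c("position", "condition", "fold") %in% names(enhancer_folds)))
    if (any(enhancer_folds$fold <= 0)) abort("all planted folds must be > 0")
  }
  structure(
    list(
      sequence_length = as.integer(sequence_length),
      primary_motif = primary_motif,
      secondary_motif = secondary_motif,
      bait_position = as.integer(bait_position),
      decay_exponent = decay_exponent,
      enhancer_folds = enhancer_folds,
      undigested_fraction = undigested_fraction,
      self_ligation_fraction = self_ligation_fraction,
      reads_per_sample = as.integer(reads_per_sample),
      read_length = as.integer(read_length),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$sequence_length, "bp;",
      x$primary_motif, "/", x$secondary_motif,
      "; bait @", x$bait_position,
      "; alpha =", x$decay_exponent,
      "; reads/sample =", x$reads_per_sample,
      "; seed =", x$seed, "\n")
  invisible(x)
}

#' Barcode table constructor
#'
#' Validates a set of inline barcodes: sample names unique, barcodes unique,
#' and no barcode a prefix of another (so demultiplexing by prefix match is
#' unambiguous).
#'
#' @param sample Character vector of sample names.
#' @param barcode Character vector of barcode sequences (A/C/G/T).
#' @return A tibble with columns `sample`, `barcode`.
#' @export
barcode_table <- function(sample, barcode) {
  stopifnot(length(sample) == length(barcode))
  purrr::walk(barcode, check_dna, what = "barcode")
  if (anyDuplicated(sample)) abort("duplicate sample names in barcode table")
  if (anyDuplicated(barcode)) abort("duplicate barcodes in barcode table")
  for (i in seq_along(barcode)) {
    for (j in seq_along(barcode)) {
      if (i != j && startsWith(barcode[[j]], barcode[[i]])) {
        abort(sprintf("barcode '%s' is a prefix of '%s'", barcode[[i]], barcode[[j]]))
      }
    }
  }
  tibble(sample = as.character(sample), barcode = as.character(barcode))
}
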