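#' Demultiplex inline-barcoded reads
#'
#' Assigns each read to the sample whose barcode matches the read prefix
#' within `max_mismatches` (Hamming distance over the barcode length) and
#' strips the barcode. A read is assigned only if exactly one barcode
#' achieves the minimum distance; ties and reads with no barcode within
#' tolerance go to the unassigned pool. Default `max_mismatches = 0` (exact
#' prefix match).
#'
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @param barcodes A [barcode_table()] (`sample`, `barcode`; validated).
#' @param max_mismatches Maximum barcode mismatches tolerated (default 0).
#'
#' @return A list of class `demux_result`:
#'   * `assigned` — tibble `read_id`, `sample`, `sequence` (barcode
#'     stripped);
#'   * `unassigned` — tibble `read_id`, `sequence` (untouched);
#'   * `tally` — per-sample read counts plus the unassigned count.
#'   Conservation holds exactly: `nrow(assigned) + nrow(unassigned) ==
#'   nrow(reads)`.
#' @export
demultiplex <- function(reads, barcodes, max_mismatches = 0L) {
  barcodes <- barcode_table(barcodes$sample, barcodes$barcode)  # revalidate
  n <- nrow(reads)
  if (n == 0L) {
    res <- list(
      assigned = tibble(read_id = character(), sample = character(),
                        sequence = character()),
      unassigned = tibble(read_id = character(), sequence = character()),
      tally = tibble(sample = c(barcodes$sample, "<unassigned>"),
                     n = 0L)
    )
    return(structure(res, class = "demux_result"))
  }
  dist <- matrix(NA_integer_, nrow = n, ncol = nrow(barcodes))
  for (j in seq_len(nrow(barcodes))) {
    bc <- barcodes$barcode[j]
    k <- nchar(bc)
    d <- integer(n)
    for (p in seq_len(k)) {
      d <- d + (substr(reads$sequence, p, p) != substr(bc, p, p))
    }
    dist[, j] <- d
  }
  best <- dist[, 1L]
  for (j in seq_len(ncol(dist))[-1L]) best <- pmin(best, dist[, j])
  n_best <- rowSums(dist == best)
  hit <- best <= max_mismatches & n_best == 1L
  which_bc <- max.col(-dist, ties.method = "first")

  assigned <- tibble(
    read_id = reads$read_id[hit],
    sample = barcodes$sample[which_bc[hit]],
    sequence = substr(reads$sequence[hit],
                      nchar(barcodes$barcode[which_bc[hit]]) + 1L,
                      nchar(reads$sequence[hit]))
  )
  unassigned <- tibble(read_id = reads$read_id[!hit],
                       sequence = reads$sequence[!hit])
  tally <- bind_rows(
    left_join(tibble(sample = barcodes$sample),
              count(assigned, .data$sample), by = "sample"),
    tibble(sample = "<unassigned>", n = nrow(unassigned))
  )
  tally$n[is.na(tally$n)] <- 0L
  structure(list(assigned = assigned, unassigned = unassigned, tally = tally),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("<demux_result>\n")
  print(x$tally)
  invisible(x)
}

#' Trim the bait-end segment from demultiplexed reads
#'
#' Reads produced by inverse PCR from the viewpoint begin with the bait-end
#' segment, which terminates in the primary restriction motif. Reads starting
#' with `bait_end` have it stripped, leaving the captured sequence (nothing
#' of the bait beyond the motif is retained); reads that do not are flagged
#' non-bait and excluded from assignment.
#'
#' @param reads Tibble with columns `read_id`, `sample`, `sequence`
#'   (the `assigned` element of a [demultiplex()] result).
#' @param bait_end Bait-end segment; must end in `primary_motif`.
#' @param primary_motif Primary enzyme motif (default `"CATG"`).
#'
#' @return A list with `trimmed` (tibble `read_id`, `sample`, `sequence` of
#'   captured portions) and `non_bait` (tibble of excluded reads).
#' @export
trim_bait <- function(reads, bait_end, primary_motif = "CATG") {
  if (!endsWith(bait_end, primary_motif)) {
    abort("`bait_end` must terminate in the primary motif")
  }
  is_bait <- startsWith(reads$sequence, bait_end)
  trimmed <- tibble(
    read_id = reads$read_id[is_bait],
    sample = reads$sample[is_bait],
    sequence = substr(reads$sequence[is_bait], nchar(bait_end) + 1L,
                      nchar(reads$sequence[is_bait]))
  )
  list(trimmed = trimmed, non_bait = reads[!is_bait, , drop = FALSE])
}
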