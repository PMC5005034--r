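#' Run the per-sample 4C processing chain on a multiplexed read set
#'
#' Convenience wrapper chaining [demultiplex()], [trim_bait()],
#' [assign_reads()] and [filter_bait_proximal()] for every sample in the
#' barcode table. Exact read conservation holds across the chain: input
#' reads = assigned-and-counted + unassigned (bad barcode) + non-bait +
#' unmapped + ambiguous + filtered (self-ligation + undigested).
#'
#' @param reads Tibble `read_id`, `sequence` (a pooled multiplexed run).
#' @param barcodes A [barcode_table()].
#' @param reference List from [sim_reference()], or any list providing
#'   `sequence`, `fragment_map`, `bait` and `bait_end`.
#' @param max_mismatches Barcode mismatch tolerance (default 0).
#' @param min_match_length Assignment prefix length (default 20).
#' @param both_ends Strand-aware assignment of fragment ends (default FALSE).
#' @param primary_motif Primary enzyme motif the bait-end segment terminates
#'   in (default `"CATG"`).
#'
#' @return A list with:
#'   * `counts` — named list of filtered `fragment_counts`, one per sample;
#'   * `summary` — one row per sample ([glance()] of each count vector plus
#'     `n_unassigned_share` and `n_non_bait`);
#'   * `n_input`, `n_unassigned` — run-level read bookkeeping.
#' @export
process_run <- function(reads, barcodes, reference,
                        max_mismatches = 0L, min_match_length = 20L,
                        both_ends = FALSE, primary_motif = "CATG") {
  dm <- demultiplex(reads, barcodes, max_mismatches = max_mismatches)
  counts <- list()
  summaries <- list()
  for (s in barcodes$sample) {
    sample_reads <- filter(dm$assigned, .data$sample == s)
    tr <- trim_bait(sample_reads, reference$bait_end,
                    primary_motif = primary_motif)
    cv <- assign_reads(tr$trimmed, reference$fragment_map,
                       reference$sequence,
                       min_match_length = min_match_length,
                       both_ends = both_ends, sample_name = s)
    cv <- filter_bait_proximal(cv, reference$bait)
    counts[[s]] <- cv
    summaries[[s]] <- mutate(glance(cv), n_non_bait = nrow(tr$non_bait))
  }
  list(counts = counts,
       summary = purrr::list_rbind(summaries),
       n_input = nrow(reads),
       n_unassigned = nrow(dm$unassigned))
}
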