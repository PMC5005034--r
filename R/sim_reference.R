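#' Generate a seeded random reference sequence with a usable bait
#'
#' Draws a uniform-random DNA sequence of `config$sequence_length` bases and
#' verifies that it supports the simulated 4C experiment: at least 20
#' primary-motif occurrences; a bait fragment (the primary-digest fragment
#' containing `bait_position`) that contains at least one secondary-motif
#' occurrence, ends at a primary cut site, is long enough to carry the
#' bait-end primer segment, and has a downstream neighbour to receive
#' undigested run-through reads. If a draw fails these guarantees the
#' generator retries with a seed derived deterministically from
#' `config$seed`, up to `max_tries` times, so the result is still a pure
#' function of the config.
#'
#' @param config A [sim_config()].
#' @param max_tries Bounded number of seeded retries (default 25).
#'
#' @return A list with elements `sequence` (character string), `fragment_map`
#'   (primary digest, see [digest_sequence()]), `bait`
#'   (a `bait_descriptor`, see [locate_bait()]) and `bait_end` (the bait-end
#'   primer-to-motif segment used as read prefix, see [bait_end_sequence()]).
#' @export
sim_reference <- function(config, max_tries = 25L) {
  stopifnot(inherits(config, "sim_config"))
  for (try in seq_len(max_tries)) {
    seq_i <- withr::with_seed(config$seed + (try - 1L) * 1000003L, {
      paste(sample(c("A", "C", "G", "T"), config$sequence_length,
                   replace = TRUE), collapse = "")
    })
    fm <- digest_sequence(seq_i, config$primary_motif)
    if (nrow(fm) < 21L) next    # >= 20 motif occurrences => >= 21 fragments
    bait <- locate_bait(fm, config$bait_position)
    bi <- bait$bait_fragment_index
    bait_len <- fm$end[bi] - fm$start[bi]
    # bait fragment must end at a cut (not be the terminal fragment),
    # carry the 20 bp primer stand-in upstream of its terminal motif,
    # contain the secondary motif, and have a downstream neighbour
    if (bi == nrow(fm)) next
    if (bait_len < 20L + nchar(config$primary_motif)) next
    # downstream neighbour receives run-through reads; must be assignable
    if (fm$end[bi + 1L] - fm$start[bi + 1L] < 20L) next
    bait_seq <- substr(seq_i, fm$start[bi] + 1L, fm$end[bi])
    if (!grepl(config$secondary_motif, bait_seq, fixed = TRUE)) next
    return(list(
      sequence = seq_i,
      fragment_map = fm,
      bait = bait,
      bait_end = bait_end_sequence(seq_i, fm, bait, config$primary_motif)
    ))
  }
  abort(sprintf(
    "could not generate a reference meeting motif guarantees in %d seeded tries",
    max_tries
  ))
}

#' Bait-end segment used as the invariant read prefix
#'
#' In inverse-PCR 4C geometry each read begins with sequence from the bait
#' fragment running up to (and including) the primary restriction motif at
#' the fragment end. The segment modelled here spans from a fixed
#' common-primer stand-in 20 bases upstream of the motif to the motif's end,
#' i.e. the last `20 + nchar(motif)` bases of the bait fragment.
#'
#' @param sequence Reference sequence string.
#' @param fragment_map Primary-digest fragment map.
#' @param bait A `bait_descriptor`.
#' @param primary_motif Primary motif (the segment must end in it).
#' @return A character string.
#' @export
bait_end_sequence <- function(sequence, fragment_map, bait, primary_motif = "CATG") {
  bi <- bait$bait_fragment_index
  end <- fragment_map$end[bi]
  seg <- substr(sequence, end - 20L - nchar(primary_motif) + 1L, end)
  if (!endsWith(seg, primary_motif)) {
    abort("bait fragment does not end at a primary-motif cut")
  }
  seg
}
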