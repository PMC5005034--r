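#' In-silico restriction digestion of a reference sequence
#'
#' Scans `sequence` left to right for every occurrence of the recognition
#' `motif` (overlapping occurrences included) and cuts at the *end* of each
#' occurrence, mirroring an enzyme such as NlaIII (CATG) that leaves its site
#' at the 3' terminus of the upstream fragment. The fragments are the
#' intervals between consecutive cuts plus the two terminal pieces, so they
#' tile the sequence exactly: concatenating the fragment sequences
#' reconstructs the input.
#'
#' Ambiguity codes (e.g. `N`) in the sequence never match a motif. The same
#' convention is applied to primary (default CATG/NlaIII) and secondary
#' (GATC/DpnII) enzymes; downstream read simulation and assignment rely on
#' this consistency, not on enzymatic fidelity.
#'
#' @param sequence A single DNA string (A/C/G/T/N).
#' @param motif Recognition motif, uppercase A/C/G/T (e.g. `"CATG"`).
#'
#' @return A tibble with one row per restriction fragment and columns
#'   `index` (1-based ordinal), `start` (0-based inclusive) and `end`
#'   (0-based exclusive). Fragments are sorted, non-overlapping, and tile
#'   `[0, nchar(sequence))`.
#'
#' @examples
#' digest_sequence("AAACATGAAA", "CATG")   # cuts at 7: fragments [0,7), [7,10)
#' digest_sequence("CATGCATG", "CATG")     # cuts at 4 and 8
#' @export
digest_sequence <- function(sequence, motif) {
  check_dna(motif, "motif")
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("`sequence` must be a single string")
  }
  if (nchar(sequence) < nchar(motif)) {
    abort("`sequence` is shorter than `motif`")
  }
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence))
  cuts <- BiocGenerics::end(hits)             # 1-based inclusive end == 0-based cut
  bounds <- unique(c(0L, cuts, nchar(sequence)))
  bounds <- sort(bounds)
  tibble(
    index = seq_len(length(bounds) - 1L),
    start = bounds[-length(bounds)],
    end   = bounds[-1L]
  )
}

#' Locate the bait (viewpoint) fragment and its neighbours
#'
#' Finds the unique restriction fragment whose half-open interval
#' `[start, end)` contains `bait_position`, together with the indices of the
#' fragments sharing a boundary with it. In 4C-seq the bait fragment captures
#' self-ligation events and its immediate neighbours receive run-through
#' (undigested) reads; both are removed before quantitation.
#'
#' @param fragment_map Tibble from [digest_sequence()].
#' @param bait_position 0-based coordinate inside the reference.
#'
#' @return A list of class `bait_descriptor` with elements
#'   `bait_fragment_index` and `adjacent_fragment_indices` (integer vector of
#'   length 0-2).
#' @export
locate_bait <- function(fragment_map, bait_position) {
  if (!is.data.frame(fragment_map) || nrow(fragment_map) == 0L) {
    abort("`fragment_map` is empty")
  }
  if (bait_position < 0 || bait_position >= max(fragment_map$end)) {
    abort("`bait_position` outside the digested sequence")
  }
  idx <- which(fragment_map$start <= bait_position & bait_position < fragment_map$end)
  stopifnot(length(idx) == 1L)
  adj <- c(idx - 1L, idx + 1L)
  adj <- adj[adj >= 1L & adj <= nrow(fragment_map)]
  structure(
    list(
      bait_fragment_index = as.integer(fragment_map$index[idx]),
      adjacent_fragment_indices = as.integer(fragment_map$index[adj])
    ),
    class = "bait_descriptor"
  )
}

#' @export
print.bait_descriptor <- function(x, ...) {
  cat("<bait_descriptor> fragment", x$bait_fragment_index,
      "| adjacent:", paste(x$adjacent_fragment_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a fragment map as BED3
#'
#' Serialises a restriction-fragment map as sorted BED3 (0-based half-open)
#' and reads it back; `read_fragment_bed()` round-trips to an identical map.
#'
#' @param fragment_map Tibble from [digest_sequence()].
#' @param path File path.
#' @param chrom Chromosome name written in column 1 (default `"chrS"`).
#' @return `write_fragment_bed()` returns `path` invisibly;
#'   `read_fragment_bed()` returns a fragment-map tibble.
#' @export
write_fragment_bed <- function(fragment_map, path, chrom = "chrS") {
  if (!is.data.frame(fragment_map) || nrow(fragment_map) == 0L) {
    abort("`fragment_map` is empty")
  }
  fm <- arrange(fragment_map, .data$start)
  readr::write_tsv(
    tibble(chrom = chrom, start = fm$start, end = fm$end),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_fragment_bed
#' @export
read_fragment_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  tibble(index = seq_len(nrow(bed)), start = bed$start, end = bed$end)
}
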