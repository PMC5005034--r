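#' Fragment count vector
#'
#' Container for per-fragment read counts of one sample plus the filtering
#' bookkeeping the conservation invariant needs. Built by [assign_reads()]
#' and updated by [filter_bait_proximal()].
#'
#' @param counts Integer vector, one entry per fragment.
#' @param sample_name Sample label.
#' @param n_unmapped,n_ambiguous,n_filtered_undigested,n_filtered_self
#'   Filter tallies.
#' @return A tibble of class `fragment_counts` with columns
#'   `fragment_index`, `count` and the tallies as attributes;
#'   `total_assigned` always equals `sum(count)`.
#' @keywords internal
new_fragment_counts <- function(counts, sample_name,
                                n_unmapped = 0L, n_ambiguous = 0L,
                                n_filtered_undigested = 0L,
                                n_filtered_self = 0L) {
  out <- tibble(fragment_index = seq_along(counts), count = as.integer(counts))
  structure(out,
            class = c("fragment_counts", class(out)),
            sample_name = sample_name,
            n_unmapped = as.integer(n_unmapped),
            n_ambiguous = as.integer(n_ambiguous),
            n_filtered_undigested = as.integer(n_filtered_undigested),
            n_filtered_self = as.integer(n_filtered_self))
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat("<fragment_counts>", attr(x, "sample_name"), "|",
      nrow(x), "fragments, total_assigned =", sum(x$count), "\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of a fragment count vector
#'
#' @param x A `fragment_counts` object.
#' @param ... Unused.
#' @return A one-row tibble: `sample`, `total_assigned`, `n_unmapped`,
#'   `n_ambiguous`, `n_filtered_undigested`, `n_filtered_self`.
#' @export
glance.fragment_counts <- function(x, ...) {
  tibble(
    sample = attr(x, "sample_name"),
    total_assigned = sum(x$count),
    n_unmapped = attr(x, "n_unmapped"),
    n_ambiguous = attr(x, "n_ambiguous"),
    n_filtered_undigested = attr(x, "n_filtered_undigested"),
    n_filtered_self = attr(x, "n_filtered_self")
  )
}

#' Assign trimmed reads uniquely to restriction fragments
#'
#' The internal assigner realises the "uniquely mapping" contract (the
#' aligner-based route filters on MAPQ >= 42; see [assign_sam()]) with an
#' explicit rule: the first `min_match_length` bases of each trimmed read are
#' matched exactly against the fragment-start sequences of the map. A read
#' increments exactly one fragment's count iff its prefix matches a unique
#' fragment start; prefixes shared by several fragments are ambiguous;
#' unmatched reads (including reads shorter than `min_match_length`) are
#' unmapped. With `both_ends = TRUE` the reverse complement of each fragment
#' end is also indexed (strand-aware mode for real data); the default
#' start-only mode mirrors unidirectional capture.
#'
#' @param trimmed Tibble `read_id`, `sample`, `sequence` from [trim_bait()].
#' @param fragment_map Primary-digest fragment map.
#' @param reference Reference sequence string the map was digested from.
#' @param min_match_length Prefix length matched (default 20); must not
#'   exceed the read length in use.
#' @param both_ends Also match reverse-complemented fragment ends.
#' @param sample_name Label for the result; default taken from `trimmed`.
#'
#' @return A `fragment_counts` object.
#' @export
assign_reads <- function(trimmed, fragment_map, reference,
                         min_match_length = 20L, both_ends = FALSE,
                         sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- if (nrow(trimmed) > 0L) trimmed$sample[[1L]] else "<none>"
  }
  nf <- nrow(fragment_map)
  flen <- fragment_map$end - fragment_map$start
  usable <- flen >= min_match_length
  keys <- substr(rep(reference, sum(usable)),
                 fragment_map$start[usable] + 1L,
                 fragment_map$start[usable] + min_match_length)
  key_frag <- fragment_map$index[usable]
  if (both_ends) {
    tails <- substr(rep(reference, sum(usable)),
                    fragment_map$end[usable] - min_match_length + 1L,
                    fragment_map$end[usable])
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(tails)))
    keys <- c(keys, rc)
    key_frag <- c(key_frag, fragment_map$index[usable])
  }
  # a key mapping to >1 distinct fragment is inherently ambiguous
  amb_key <- unique(keys[duplicated(keys)])
  amb_key <- amb_key[vapply(amb_key, function(k) {
    length(unique(key_frag[keys == k])) > 1L
  }, logical(1))]

  counts <- integer(nf)
  n_unmapped <- 0L
  n_ambiguous <- 0L
  if (nrow(trimmed) > 0L) {
    long_enough <- nchar(trimmed$sequence) >= min_match_length
    n_unmapped <- n_unmapped + sum(!long_enough)
    pre <- substr(trimmed$sequence[long_enough], 1L, min_match_length)
    is_amb <- pre %in% amb_key
    n_ambiguous <- sum(is_amb)
    m <- match(pre[!is_amb], keys)
    n_unmapped <- n_unmapped + sum(is.na(m))
    hit_frag <- key_frag[m[!is.na(m)]]
    counts <- tabulate(hit_frag, nbins = nf)
  }
  new_fragment_counts(counts, sample_name,
                      n_unmapped = n_unmapped, n_ambiguous = n_ambiguous)
}

#' Remove bait-proximal reads before quantitation
#'
#' Reads assigned to the bait fragment are self-ligation events and reads
#' assigned to a bait-adjacent fragment arise from failed digestion
#' (run-through); neither is informative for contacts. Their counts are
#' moved into `n_filtered_self` and `n_filtered_undigested` respectively and
#' zeroed; every other count is unchanged. The operation is idempotent.
#'
#' @param counts A `fragment_counts` object.
#' @param bait A `bait_descriptor` from [locate_bait()].
#' @return A filtered `fragment_counts` object.
#' @export
filter_bait_proximal <- function(counts, bait) {
  if (bait$bait_fragment_index > nrow(counts) ||
      any(bait$adjacent_fragment_indices > nrow(counts))) {
    abort("bait descriptor is inconsistent with the fragment map")
  }
  v <- counts$count
  self_n <- v[bait$bait_fragment_index]
  undig_n <- sum(v[bait$adjacent_fragment_indices])
  v[c(bait$bait_fragment_index, bait$adjacent_fragment_indices)] <- 0L
  new_fragment_counts(
    v, attr(counts, "sample_name"),
    n_unmapped = attr(counts, "n_unmapped"),
    n_ambiguous = attr(counts, "n_ambiguous"),
    n_filtered_undigested = attr(counts, "n_filtered_undigested") + undig_n,
    n_filtered_self = attr(counts, "n_filtered_self") + self_n
  )
}

#' Assign aligned reads from SAM via the MAPQ uniqueness filter
#'
#' External-aligner route: reads already mapped to the reference are filtered
#' to uniquely mapping alignments with `MAPQ >= min_mapq` (42 by default, the
#' bowtie2 unique-alignment ceiling) and each surviving read increments the
#' fragment whose interval contains its alignment start.
#'
#' @param sam_path Path to a SAM file.
#' @param fragment_map Primary-digest fragment map.
#' @param min_mapq Minimum mapping quality retained (default 42).
#' @param sample_name Label for the result.
#' @return A `fragment_counts` object; alignments below `min_mapq` or
#'   unmapped are tallied in `n_unmapped`.
#' @export
assign_sam <- function(sam_path, fragment_map, min_mapq = 42L,
                       sample_name = "sam") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("assign_sam() requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("pos", "mapq")))[[1L]]
  pos0 <- rec$pos - 1L                      # SAM is 1-based
  keep <- !is.na(pos0) & !is.na(rec$mapq) & rec$mapq >= min_mapq
  frag <- findInterval(pos0[keep], fragment_map$start)
  counts <- tabulate(frag, nbins = nrow(fragment_map))
  new_fragment_counts(counts, sample_name,
                      n_unmapped = sum(!keep))
}

#' Write / read a per-fragment count table (TSV)
#'
#' @param counts A `fragment_counts` object.
#' @param path Output path; columns `fragment_index`, `count`.
#' @return `write_counts_tsv()` returns `path` invisibly; `read_counts_tsv()`
#'   a `fragment_counts` object (tallies not preserved by the format).
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(tibble(fragment_index = counts$fragment_index,
                          count = counts$count), path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param sample_name Sample label attached to the imported counts.
#' @export
read_counts_tsv <- function(path, sample_name = "imported") {
  x <- readr::read_tsv(path, col_types = "ii", progress = FALSE)
  new_fragment_counts(x$count, sample_name)
}
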