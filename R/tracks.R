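# genomic_track: tibble (start, end, score) + metadata attributes.
# normalisation is one of raw | max-library | per-million | relative | difference.
new_genomic_track <- function(windows, scores, sample_name, scheme,
                              normalisation) {
  out <- tibble(start = windows$start, end = windows$end,
                score = as.numeric(scores))
  structure(out,
            class = c("genomic_track", class(out)),
            sample_name = sample_name,
            scheme = scheme,
            normalisation = normalisation)
}

#' @export
print.genomic_track <- function(x, ...) {
  cat("<genomic_track>", attr(x, "sample_name"),
      "|", attr(x, "scheme"), "windows |", attr(x, "normalisation"),
      "|", nrow(x), "windows, total =", format(sum(x$score)), "\n")
  NextMethod()
}

track_meta <- function(x) {
  list(sample_name = attr(x, "sample_name"),
       scheme = attr(x, "scheme"),
       normalisation = attr(x, "normalisation"))
}

same_windows <- function(a, b) {
  nrow(a) == nrow(b) && all(a$start == b$start) && all(a$end == b$end)
}

#' Fixed-window absolute quantitation
#'
#' Divides the digested region into consecutive fixed-size windows (10 kb by
#' default) and scores each window with the summed read counts of the
#' fragments whose *start* coordinate lies inside it. Windows cover
#' `[0, sequence_length)`; the final window may be shorter. The sum of the
#' window scores equals the count vector's `total_assigned`.
#'
#' @param counts A `fragment_counts` object.
#' @param fragment_map The fragment map the counts were assigned on.
#' @param window_size Window width in bases (default 10000).
#'
#' @return A `genomic_track` (scheme `"fixed"`, normalisation `"raw"`).
#' @export
fixed_window_track <- function(counts, fragment_map, window_size = 10000L) {
  if (!is.data.frame(fragment_map) || nrow(fragment_map) == 0L) {
    abort("`fragment_map` is empty")
  }
  if (window_size <= 0) abort("`window_size` must be > 0")
  seq_len_total <- max(fragment_map$end)
  win_start <- seq(0L, seq_len_total - 1L, by = window_size)
  win_end <- pmin(win_start + window_size, seq_len_total)
  wi <- fragment_map$start %/% window_size + 1L
  scores <- vapply(seq_along(win_start), function(w) {
    sum(counts$count[wi == w])
  }, numeric(1))
  new_genomic_track(tibble(start = win_start, end = win_end), scores,
                    attr(counts, "sample_name"), "fixed", "raw")
}

#' Normalise a set of tracks to the highest-coverage library
#'
#' Scales every track so its total equals the maximum total across the set:
#' each track's scores are multiplied by `max(totals) / own total`, leaving
#' the highest-coverage track unchanged and preserving within-track score
#' ratios exactly. All tracks must share identical windows and have positive
#' totals.
#'
#' @param tracks A list of `genomic_track` objects on identical windows.
#' @return A list of `genomic_track`s (normalisation `"max-library"`).
#' @export
normalize_to_max_library <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 2L)
  for (t in tracks[-1L]) {
    if (!same_windows(tracks[[1L]], t)) abort("tracks have mismatched windows")
  }
  totals <- vapply(tracks, function(t) sum(t$score), numeric(1))
  if (any(totals <= 0)) abort("every track must have a positive total")
  top <- max(totals)
  purrr::map2(tracks, totals, function(t, tot) {
    new_genomic_track(t, t$score * (top / tot),
                      attr(t, "sample_name"), attr(t, "scheme"),
                      "max-library")
  })
}

#' Scale a track to reads per million of sequencing library
#'
#' Expresses window scores as reads per window per million reads of the
#' sample's sequencing library: `score * 1e6 / library_size`.
#'
#' @param track A `genomic_track`.
#' @param library_size Total reads in the sequencing library (pre-filtering);
#'   must be positive.
#' @return A `genomic_track` (normalisation `"per-million"`).
#' @export
per_million <- function(track, library_size) {
  if (!is.numeric(library_size) || library_size <= 0) {
    abort("`library_size` must be > 0")
  }
  new_genomic_track(track, track$score * 1e6 / library_size,
                    attr(track, "sample_name"), attr(track, "scheme"),
                    "per-million")
}

#' Adaptive windows by cumulative cross-sample read count
#'
#' Partitions the fragment map into windows each holding a combined (summed
#' over all samples) read count of at least `target` (50,000 by default):
#' scanning fragments left to right, a window closes at the first fragment
#' where the cumulative combined count reaches `target`; the final window
#' keeps the remainder (possibly below target) and is flagged.
#'
#' @param count_vectors List of `fragment_counts`, one per sample, on the
#'   same fragment map.
#' @param fragment_map The shared fragment map.
#' @param target Combined read-count target per window (default 50000).
#'
#' @return A tibble of class `window_partition` with columns `window`,
#'   `frag_from`, `frag_to` (1-based fragment index range), `start`, `end`
#'   (genomic), `combined_count` and `is_remainder`.
#' @export
adaptive_partition <- function(count_vectors, fragment_map, target = 50000L) {
  stopifnot(length(count_vectors) >= 1L, target > 0)
  combined <- Reduce(`+`, purrr::map(count_vectors, "count"))
  if (sum(combined) == 0L) abort("combined counts are all zero")
  cum <- 0L
  from <- 1L
  rows <- list()
  for (i in seq_along(combined)) {
    cum <- cum + combined[i]
    if (cum >= target) {
      rows[[length(rows) + 1L]] <- c(from, i, cum)
      from <- i + 1L
      cum <- 0L
    }
  }
  remainder <- from <= length(combined)
  if (remainder) {
    rows[[length(rows) + 1L]] <- c(from, length(combined), cum)
  }
  m <- do.call(rbind, rows)
  out <- tibble(
    window = seq_len(nrow(m)),
    frag_from = as.integer(m[, 1L]),
    frag_to = as.integer(m[, 2L]),
    start = fragment_map$start[m[, 1L]],
    end = fragment_map$end[m[, 2L]],
    combined_count = as.integer(m[, 3L]),
    is_remainder = FALSE
  )
  if (remainder) out$is_remainder[nrow(out)] <- TRUE
  structure(out, class = c("window_partition", class(out)))
}

#' Relative quantitation on adaptive windows
#'
#' Scores each adaptive window with this sample's read count in the window
#' divided by a depth denominator, correcting for differing sequencing
#' depths. With the default `depth_basis = "assigned"` the denominator is the
#' sample's total assigned count, so the scores of one sample sum to 1; with
#' `"library"` the denominator is the supplied raw library size.
#'
#' @param counts A `fragment_counts` object.
#' @param partition A `window_partition` built from the same sample set.
#' @param depth_basis `"assigned"` (default) or `"library"`.
#' @param library_size Required when `depth_basis = "library"`.
#' @return A `genomic_track` (scheme `"adaptive"`, normalisation
#'   `"relative"`).
#' @export
relative_quantitate <- function(counts, partition,
                                depth_basis = c("assigned", "library"),
                                library_size = NULL) {
  depth_basis <- match.arg(depth_basis)
  denom <- if (depth_basis == "assigned") {
    sum(counts$count)
  } else {
    if (is.null(library_size)) abort("`library_size` required for depth_basis = 'library'")
    library_size
  }
  if (denom <= 0) abort("zero depth denominator")
  scores <- vapply(seq_len(nrow(partition)), function(w) {
    sum(counts$count[partition$frag_from[w]:partition$frag_to[w]])
  }, numeric(1)) / denom
  new_genomic_track(partition, scores, attr(counts, "sample_name"),
                    "adaptive", "relative")
}

#' Differential (subtraction) interaction track
#'
#' Computes the windowwise difference `a - b` of two normalised tracks,
#' showing gained (positive) and lost (negative) contacts between
#' conditions. Both tracks must share identical windows and the same
#' normalisation scheme (`max-library`, `relative` or `per-million`); raw
#' counts are refused because library depth would confound the difference.
#'
#' @param a,b `genomic_track` objects.
#' @return A `genomic_track` (normalisation `"difference"`, sample name
#'   `"<a> - <b>"`).
#' @export
subtract_tracks <- function(a, b) {
  if (!same_windows(a, b)) abort("tracks have mismatched windows")
  na <- attr(a, "normalisation"); nb <- attr(b, "normalisation")
  if (na != nb) abort("tracks have mismatched normalisation schemes")
  if (!na %in% c("max-library", "relative", "per-million")) {
    abort("subtraction requires normalised tracks (max-library, relative or per-million)")
  }
  new_genomic_track(a, a$score - b$score,
                    paste(attr(a, "sample_name"), "-", attr(b, "sample_name")),
                    attr(a, "scheme"), "difference")
}
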