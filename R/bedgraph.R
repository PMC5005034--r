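#' Write / read a genomic track as bedGraph
#'
#' Serialises a track as standard bedGraph (`chrom start end score`, 0-based
#' half-open, sorted) preceded by a track-definition line that names the
#' sample and windowing/normalisation scheme, so `read_bedgraph()`
#' round-trips the track including its metadata. Scores are written with 6
#' significant digits; negative scores (difference tracks) are serialised
#' verbatim.
#'
#' @param track A `genomic_track`.
#' @param path Output path.
#' @param chrom Chromosome name (default `"chrS"`).
#' @return `write_bedgraph()` returns `path` invisibly; `read_bedgraph()` a
#'   `genomic_track`.
#' @export
write_bedgraph <- function(track, path, chrom = "chrS") {
  stopifnot(inherits(track, "genomic_track"))
  ord <- order(track$start)
  header <- sprintf(
    'track type=bedGraph name="%s" description="scheme=%s normalisation=%s"',
    attr(track, "sample_name"), attr(track, "scheme"),
    attr(track, "normalisation"))
  body <- sprintf("%s\t%d\t%d\t%.6g", chrom,
                  track$start[ord], track$end[ord], track$score[ord])
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  header <- lines[[1L]]
  if (!startsWith(header, "track type=bedGraph")) {
    abort("not a bedGraph file with a track-definition line")
  }
  name <- sub('.*name="([^"]*)".*', "\\1", header)
  scheme <- sub('.*scheme=(\\S+).*', "\\1", header)
  normalisation <- sub('.*normalisation=(\\S+)".*', "\\1", header)
  body <- readr::read_tsv(I(lines[-1L]),
                          col_names = c("chrom", "start", "end", "score"),
                          col_types = "ciid", progress = FALSE)
  new_genomic_track(body, body$score, name, scheme, normalisation)
}
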