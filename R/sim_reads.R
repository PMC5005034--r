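#' Simulate a barcoded 4C read library with ground truth
#'
#' Emits `config$reads_per_sample` single-end reads for one sample. Each read
#' is `barcode + bait-end segment + captured sequence`, padded with `A` or
#' truncated to `config$read_length`. The captured sequence is the prefix of
#' the source fragment, drawn per read from a seeded three-way mixture:
#'
#' * `contact` (probability `1 - undigested_fraction -
#'   self_ligation_fraction`): a fragment sampled from the interaction
#'   profile;
#' * `undigested` (`undigested_fraction`): the fragment immediately
#'   downstream of the bait, modelling failed digestion at the bait's end
#'   motif so the read runs through the restriction site;
#' * `self_ligation` (`self_ligation_fraction`): the bait fragment itself.
#'
#' A truth table records each read's source fragment and category, the
#' simulator-side oracle for demultiplexing, assignment and filtering tests.
#'
#' @param reference List from [sim_reference()] (`sequence`, `fragment_map`,
#'   `bait`, `bait_end`).
#' @param profile An `interaction_profile` built on the same fragment map.
#' @param barcode One row of a [barcode_table()] (`sample`, `barcode`), as a
#'   data frame or list.
#' @param config A [sim_config()].
#' @param seed Seed for this library; defaults to `config$seed`.
#'
#' @return A list with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `sample`, `fragment_index`, `category`).
#' @export
sim_reads <- function(reference, profile, barcode, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  fm <- reference$fragment_map
  stopifnot(nrow(profile) == nrow(fm))
  bc <- barcode$barcode
  sample_name <- barcode$sample
  overhead <- nchar(bc) + nchar(reference$bait_end)
  if (config$read_length <= overhead) {
    abort("read_length must exceed barcode + bait-end segment length")
  }
  n <- config$reads_per_sample
  if (n == 0L) {
    empty_truth <- tibble(read_id = character(), sample = character(),
                          fragment_index = integer(), category = character())
    return(list(reads = tibble(read_id = character(), sequence = character()),
                truth = empty_truth))
  }

  bait_i <- reference$bait$bait_fragment_index
  undig_i <- bait_i + 1L   # downstream neighbour; guaranteed by sim_reference
  u <- config$undigested_fraction
  s <- config$self_ligation_fraction

  drawn <- withr::with_seed(seed, {
    category <- sample(c("contact", "undigested", "self_ligation"), n,
                       replace = TRUE, prob = c(1 - u - s, u, s))
    frag <- integer(n)
    is_contact <- category == "contact"
    if (any(is_contact)) {
      frag[is_contact] <- sample(profile$index, sum(is_contact),
                                 replace = TRUE, prob = profile$probability)
    }
    frag[category == "undigested"] <- undig_i
    frag[category == "self_ligation"] <- bait_i
    list(category = category, frag = frag)
  })

  cap_len <- config$read_length - overhead
  cap_start <- fm$start[drawn$frag] + 1L                 # 1-based substr
  cap_end <- pmin(fm$end[drawn$frag], fm$start[drawn$frag] + cap_len)
  captured <- substr(rep(reference$sequence, n), cap_start, cap_end)
  reads <- paste0(bc, reference$bait_end, captured)
  short <- nchar(reads) < config$read_length
  if (any(short)) {
    reads[short] <- paste0(reads[short],
                           strrep("A", config$read_length - nchar(reads[short])))
  }
  read_id <- sprintf("%s_r%07d", sample_name, seq_len(n))
  list(
    reads = tibble(read_id = read_id, sequence = reads),
    truth = tibble(read_id = read_id, sample = sample_name,
                   fragment_index = as.integer(drawn$frag),
                   category = drawn$category)
  )
}

#' Simulate a multiplexed multi-sample 4C run
#'
#' Convenience wrapper: simulates one library per barcode-table row (seeds
#' offset per sample so libraries are independent but reproducible),
#' interleaves nothing, and concatenates reads and truth tables.
#'
#' @param reference List from [sim_reference()].
#' @param profile An `interaction_profile`.
#' @param barcodes A [barcode_table()].
#' @param config A [sim_config()].
#' @return A list with pooled `reads` and `truth` tibbles.
#' @export
sim_run <- function(reference, profile, barcodes, config) {
  libs <- purrr::map(seq_len(nrow(barcodes)), function(i) {
    sim_reads(reference, profile, barcodes[i, ], config,
              seed = config$seed + i * 10007L)
  })
  list(
    reads = purrr::list_rbind(purrr::map(libs, "reads")),
    truth = purrr::list_rbind(purrr::map(libs, "truth"))
  )
}

#' Simulate a qPCR Ct table from true quantities
#'
#' Generates cycle-threshold values under the standard-curve model
#' `Ct = intercept + slope * log10(quantity) + Normal(0, noise_sd)`,
#' seeded, as a fixture for the qPCR quantitation functions.
#'
#' @param quantities Data frame with columns `target` (label) and `quantity`
#'   (> 0), or a bare numeric vector of quantities.
#' @param slope Ct change per log10 quantity (typically about -3.32 at 100%
#'   amplification efficiency).
#' @param intercept Ct at quantity 1.
#' @param noise_sd Gaussian Ct noise standard deviation (0 for exact values).
#' @param seed Integer seed.
#' @return A tibble with columns `target`, `quantity`, `ct`.
#' @export
sim_qpcr_table <- function(quantities, slope = -3.32, intercept = 30,
                           noise_sd = 0, seed = 1L) {
  if (!is.data.frame(quantities)) {
    quantities <- tibble(target = sprintf("t%02d", seq_along(quantities)),
                         quantity = as.numeric(quantities))
  }
  if (any(quantities$quantity <= 0)) abort("all quantities must be > 0")
  ct <- withr::with_seed(seed, {
    intercept + slope * log10(quantities$quantity) +
      rnorm(nrow(quantities), 0, noise_sd)
  })
  tibble(target = quantities$target, quantity = quantities$quantity, ct = ct)
}

#' Read / write FASTQ for simulated libraries
#'
#' Thin wrappers around Biostrings FASTQ I/O. Reads are written 4-line,
#' Phred+33, with constant quality `I`; `read_fastq()` returns the tidy
#' `read_id`/`sequence` tibble the pipeline consumes.
#'
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @param path FASTQ path.
#' @return `write_fastq()` returns `path` invisibly; `read_fastq()` a tibble.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Write a reference sequence as wrapped FASTA
#'
#' @param sequence DNA string.
#' @param path Output path.
#' @param name Record name (default `"chrS"`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequence, path, name = "chrS") {
  x <- Biostrings::DNAStringSet(setNames(sequence, name))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
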