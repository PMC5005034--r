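test_that("demultiplex strips exact barcodes and preserves every read", {
  bcs <- barcode_table("S1", "ACGTGG")
  reads <- tibble::tibble(read_id = "r1", sequence = "ACGTGGTTTTAA")
  dm <- demultiplex(reads, bcs)
  expect_equal(dm$assigned$sample, "S1")
  expect_equal(dm$assigned$sequence, "TTTTAA")

  # empty read set: conservation 0 = 0
  dm0 <- demultiplex(reads[0, ], bcs)
  expect_equal(nrow(dm0$assigned) + nrow(dm0$unassigned), 0L)

  # non-matching read goes to the unassigned pool untouched
  reads2 <- tibble::tibble(read_id = c("r1", "r2"),
                           sequence = c("ACGTGGTTTT", "GGGGGGTTTT"))
  dm2 <- demultiplex(reads2, bcs)
  expect_equal(nrow(dm2$assigned), 1L)
  expect_equal(dm2$unassigned$sequence, "GGGGGGTTTT")
  expect_equal(sum(dm2$tally$n), 2L)
})

test_that("mismatch tolerance assigns unique near-matches and drops ties", {
  bcs <- barcode_table(c("A", "B"), c("AAAAAA", "TTTTTT"))
  reads <- tibble::tibble(
    read_id = c("exact", "one_mm", "two_mm", "tie"),
    sequence = c("AAAAAACC", "AAAAACCC", "AAAACCCC", "AAATTTCC")
  )
  dm0 <- demultiplex(reads, bcs, max_mismatches = 0L)
  expect_equal(dm0$assigned$read_id, "exact")

  dm1 <- demultiplex(reads, bcs, max_mismatches = 1L)
  expect_setequal(dm1$assigned$read_id, c("exact", "one_mm"))

  # at 3 mismatches "tie" is equidistant from both barcodes -> unassigned
  dm3 <- demultiplex(reads, bcs, max_mismatches = 3L)
  expect_true("tie" %in% dm3$unassigned$read_id)
  expect_true("two_mm" %in% dm3$assigned$read_id)
})

test_that("demultiplexed counts match the simulator truth exactly", {
  fx <- default_fixture()
  p <- sim_profile(fx$ref$fragment_map, fx$cfg, "A")
  cfg <- sim_config(sequence_length = fx$cfg$sequence_length,
                    reads_per_sample = 2500L, seed = 17L)
  run <- sim_run(fx$ref, p, fx$barcodes, cfg)
  dm <- demultiplex(run$reads, fx$barcodes)
  truth_n <- dplyr::count(run$truth, sample)
  got_n <- dplyr::count(dm$assigned, sample)
  expect_equal(got_n, truth_n)
  expect_equal(nrow(dm$unassigned), 0L)
})

test_that("trim_bait keeps only bait-prefixed reads and strips to the capture", {
  bait_end <- paste0(strrep("G", 20), "CATG")
  reads <- tibble::tibble(
    read_id = c("bait", "nonbait"),
    sample = "s",
    sequence = c(paste0(bait_end, "TTTT"), "GGGGAAAA")
  )
  tr <- trim_bait(reads, bait_end)
  expect_equal(tr$trimmed$sequence, "TTTT")
  expect_equal(tr$non_bait$read_id, "nonbait")
  expect_error(trim_bait(reads, "GGGG"), "primary motif")
})

test_that("simulated contact reads trim to a prefix of their source fragment", {
  fx <- default_fixture()
  p <- sim_profile(fx$ref$fragment_map, fx$cfg, "A")
  cfg <- sim_config(sequence_length = fx$cfg$sequence_length,
                    reads_per_sample = 1000L, undigested_fraction = 0,
                    self_ligation_fraction = 0, seed = 23L)
  lib <- sim_reads(fx$ref, p, fx$barcodes[1, ], cfg)
  dm <- demultiplex(lib$reads, fx$barcodes)
  tr <- trim_bait(dm$assigned, fx$ref$bait_end)
  expect_equal(nrow(tr$non_bait), 0L)
  joined <- dplyr::left_join(tr$trimmed, lib$truth, by = "read_id")
  fm <- fx$ref$fragment_map
  frag_seq <- substring(fx$ref$sequence,
                        fm$start[joined$fragment_index] + 1L,
                        fm$end[joined$fragment_index])
  # captured portion (before any A-padding) is a prefix of the fragment
  cap <- substr(joined$sequence, 1L,
                pmin(nchar(joined$sequence), nchar(frag_seq)))
  expect_true(all(startsWith(frag_seq, cap)))
})

test_that("assignment is unique-match-or-nothing", {
  # two fragments with identical 8-bp starts -> ambiguous
  s <- paste0("AAAATTTTCATG", "GGGGCCCCATG", "GGGGCCCCGTA")
  fm <- digest_sequence(s, "CATG")
  expect_equal(nrow(fm), 3L)
  trimmed <- tibble::tibble(
    read_id = c("uniq", "amb", "none"),
    sample = "s",
    sequence = c("AAAATTTT", "GGGGCCCC", "TTTTTTTT")
  )
  cv <- assign_reads(trimmed, fm, s, min_match_length = 8L)
  expect_equal(cv$count, c(1L, 0L, 0L))
  expect_equal(attr(cv, "n_ambiguous"), 1L)
  expect_equal(attr(cv, "n_unmapped"), 1L)

  # reads shorter than min_match_length are unmapped
  cv2 <- assign_reads(tibble::tibble(read_id = "short", sample = "s",
                                     sequence = "AAAA"),
                      fm, s, min_match_length = 8L)
  expect_equal(sum(cv2$count), 0L)
  expect_equal(attr(cv2, "n_unmapped"), 1L)
})

test_that("both-ends mode also matches reverse-complemented fragment ends", {
  s <- paste0("AAAATTTTCCCCCATG", "GGGGCCCCTTAAGTAC")
  fm <- digest_sequence(s, "CATG")
  rc_end <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, nchar(s) - 7L, nchar(s)))))
  trimmed <- tibble::tibble(read_id = "rc", sample = "s", sequence = rc_end)
  cv_fwd <- assign_reads(trimmed, fm, s, min_match_length = 8L)
  expect_equal(sum(cv_fwd$count), 0L)
  cv_both <- assign_reads(trimmed, fm, s, min_match_length = 8L,
                          both_ends = TRUE)
  expect_equal(cv_both$count[2L], 1L)
})

test_that("pipeline counts equal simulator truth exactly on noise-free input", {
  fx <- default_fixture()
  p <- sim_profile(fx$ref$fragment_map, fx$cfg, "A")
  cfg <- sim_config(sequence_length = fx$cfg$sequence_length,
                    reads_per_sample = 20000L, undigested_fraction = 0,
                    self_ligation_fraction = 0, seed = 29L)
  lib <- sim_reads(fx$ref, p, fx$barcodes[1, ], cfg)
  dm <- demultiplex(lib$reads, fx$barcodes)
  tr <- trim_bait(dm$assigned, fx$ref$bait_end)
  cv <- assign_reads(tr$trimmed, fx$ref$fragment_map, fx$ref$sequence)
  truth <- tabulate(lib$truth$fragment_index, nbins = nrow(fx$ref$fragment_map))
  expect_identical(cv$count, as.integer(truth))
  expect_equal(attr(cv, "n_unmapped"), 0L)
  expect_equal(attr(cv, "n_ambiguous"), 0L)
})

test_that("bait-proximal filtering is exact, idempotent and bounded", {
  fx <- default_fixture()
  p <- sim_profile(fx$ref$fragment_map, fx$cfg, "A")
  cfg <- sim_config(sequence_length = fx$cfg$sequence_length,
                    reads_per_sample = 20000L, undigested_fraction = 0.2,
                    self_ligation_fraction = 0.05, seed = 31L)
  lib <- sim_reads(fx$ref, p, fx$barcodes[1, ], cfg)
  dm <- demultiplex(lib$reads, fx$barcodes)
  tr <- trim_bait(dm$assigned, fx$ref$bait_end)
  cv <- assign_reads(tr$trimmed, fx$ref$fragment_map, fx$ref$sequence)
  fv <- filter_bait_proximal(cv, fx$ref$bait)

  truth_cat <- table(lib$truth$category)
  expect_equal(attr(fv, "n_filtered_self"),
               unname(truth_cat[["self_ligation"]]))
  expect_equal(attr(fv, "n_filtered_undigested"),
               unname(truth_cat[["undigested"]]))
  bait_idx <- c(fx$ref$bait$bait_fragment_index,
                fx$ref$bait$adjacent_fragment_indices)
  expect_true(all(fv$count[bait_idx] == 0L))

  # idempotence
  fv2 <- filter_bait_proximal(fv, fx$ref$bait)
  expect_identical(fv2$count, fv$count)
  expect_identical(glance(fv2), glance(fv))

  # vector with nothing at bait/adjacent is unchanged
  clean <- fv
  fv3 <- filter_bait_proximal(clean, fx$ref$bait)
  expect_identical(fv3$count, clean$count)

  bad_bait <- structure(list(bait_fragment_index = nrow(cv) + 5L,
                             adjacent_fragment_indices = integer()),
                        class = "bait_descriptor")
  expect_error(filter_bait_proximal(cv, bad_bait), "inconsistent")
})

test_that("read conservation holds exactly across the whole module", {
  fx <- default_fixture()
  p <- sim_profile(fx$ref$fragment_map, fx$cfg, "B")
  cfg <- sim_config(sequence_length = fx$cfg$sequence_length,
                    reads_per_sample = 5000L, undigested_fraction = 0.15,
                    self_ligation_fraction = 0.05,
                    enhancer_folds = fx$cfg$enhancer_folds, seed = 37L)
  run <- sim_run(fx$ref, p, fx$barcodes, cfg)
  pr <- process_run(run$reads, fx$barcodes, fx$ref)
  accounted <- sum(pr$summary$total_assigned + pr$summary$n_unmapped +
                     pr$summary$n_ambiguous + pr$summary$n_non_bait +
                     pr$summary$n_filtered_undigested +
                     pr$summary$n_filtered_self) + pr$n_unassigned
  expect_identical(accounted, pr$n_input)
})

test_that("counts TSV round-trips the count vector", {
  fx <- default_fixture()
  cv <- viewpointr:::new_fragment_counts(
    sample.int(50L, nrow(fx$ref$fragment_map), replace = TRUE), "s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cv, path)
  back <- read_counts_tsv(path, sample_name = "s1")
  expect_equal(back$count, cv$count)
})
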