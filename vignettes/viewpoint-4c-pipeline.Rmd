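---
title: "Viewpoint 4C-seq quantitation: model, pipeline and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viewpoint 4C-seq quantitation: model, pipeline and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viewpointr)
library(dplyr)
```

## The experiment this package models

Circularised chromosome conformation capture with sequencing (4C-seq) asks,
for one genomic "bait" (viewpoint) restriction fragment — typically spanning
a gene promoter — which other fragments of the genome it touches in
three-dimensional nuclear space. Chromatin is cross-linked, digested with a
primary restriction enzyme (NlaIII, recognition site CATG), ligated so that
fragments in spatial contact become joined circles, digested again with a
secondary enzyme (DpnII, GATC) to trim the circles, and re-ligated. Inverse
PCR outward from the bait then amplifies whatever sequence was captured next
to it, and single-end sequencing reads through an inline sample barcode, the
bait's terminal sequence up to its CATG site, and finally the captured
fragment.

Three read classes carry no contact information and must be removed before
quantitation:

* **undigested** reads, which continue from the bait across an uncut CATG
  into the physically adjacent fragment (failed digestion, not a contact);
* **self-ligation** reads, where the bait circularised onto itself;
* reads that do not begin with the bait sequence at all (artefacts,
  mispriming).

After filtering, per-fragment counts are turned into genome-track summaries,
normalised across libraries, and subtracted between biological conditions to
reveal gained and lost contacts — for instance an enhancer cluster that
starts touching a promoter after a stimulus.

## Pipeline contracts

The processing chain is `demultiplex() |> trim_bait() |> assign_reads() |>
filter_bait_proximal()` (bundled as `process_run()`), with two hard
contracts that the test-suite verifies on every simulated library:

1. **Conservation.** Every input read ends in exactly one bin: assigned to a
   fragment, unassigned (bad barcode), non-bait, unmapped, ambiguous, or
   filtered (undigested / self-ligation). The bins sum to the input count
   exactly, never approximately.
2. **Uniqueness.** A read contributes to a fragment only if its first
   `min_match_length` bases (default 20) match the start of exactly one
   fragment. In aligner-based workflows the same contract is realised by
   keeping alignments with MAPQ ≥ 42 — the unique-alignment ceiling of
   bowtie2 — and `assign_sam()` applies that literal filter to SAM input.
   The internal assigner and the MAPQ route are two implementations of one
   rule: a read either maps to one place or it is discarded.

Demultiplexing assigns a read to the unique barcode at minimal Hamming
distance within `max_mismatches` (default 0); ties are unassigned rather
than guessed. Barcode tables are validated up front: no duplicate, and no
barcode a prefix of another, so prefix matching is well defined.

## Quantitation

Three track types cover the quantitation styles used for viewpoint data:

* **Fixed windows** (`fixed_window_track()`): the region is divided into
  `window_size` bins (default 10 kb) and each fragment's count is attributed
  to the window containing the fragment's *start* coordinate. Attribution by
  start is a convention; what matters is that the brute-force per-read
  oracle in the tests uses the same one. Scores conserve the assigned total
  exactly.
* **Adaptive windows** (`adaptive_partition()` + `relative_quantitate()`):
  scanning fragments left to right, a window closes at the first fragment
  where the combined cross-sample count reaches `target` (default 50,000).
  "Contains a total of `target` reads" is ambiguous between ≥ and ≈; the
  greedy-≥ rule is used because it is deterministic and order-independent
  of sample labels. The trailing remainder window (possibly under target)
  is kept and flagged `is_remainder`. Each sample's window counts are then
  divided by its total assigned count (or by a supplied raw library size
  with `depth_basis = "library"`), so scores are depth-corrected
  proportions summing to 1.
* **Normalised differences** (`normalize_to_max_library()` +
  `subtract_tracks()`): libraries are scaled *up* to the highest-coverage
  library — multiplying each track by `max(total)/total` — so the reference
  track keeps its raw values and within-track ratios are preserved exactly.
  Differences are plain windowwise subtractions of equally-normalised
  tracks; no pseudo-counts and no log transform, so a difference of zero
  means literally equal normalised coverage. Subtracting raw tracks is
  refused because library depth would confound the sign.

Tracks serialise to bedGraph with a track-definition line carrying the
sample name and scheme; scores are written with 6 significant digits
(round-trips are exact to ~5 × 10⁻⁶ relative), and negative difference
scores are written verbatim.

## The synthetic-data generator

Real 4C libraries for this design are not redistributable, so the package
ships a seeded generator that produces data with exactly the structure the
pipeline assumes, plus a truth table that records each read's source
fragment and category. All pipeline guarantees are tested against that
truth.

The generative model, per condition:

* **Genome**: uniform-random A/C/G/T of `sequence_length` bases (default
  100 kb — large enough for ~400 NlaIII fragments and stable windowed
  tracks, small enough that a full two-condition, 200,000-read-per-sample
  recovery experiment runs in seconds). A draw is accepted only if it
  supports the experiment: ≥ 20 CATG sites, a bait fragment that ends at a
  CATG cut, is ≥ 24 bp, contains a GATC site, and has a downstream
  neighbour ≥ 20 bp to receive run-through reads; otherwise the generator
  retries with deterministically derived seeds (bounded), so output is
  still a pure function of the seed.
* **Contacts**: fragment *i* gets baseline weight
  `(1 + |mid(i) − mid(bait)|)^(−α)` with decay exponent α = 1 by default.
  No generative contact model is dictated by the assay itself; a power law
  is the field's standard first-order description of intra-chromosomal
  contact decay and produces the near-bait enrichment real tracks show,
  which keeps recovery tests non-trivial. Planted effects multiply a
  designated fragment's weight by a fold (> 1 gained contact, < 1
  "looped-out") before renormalisation, so one planted fold perturbs other
  fragments only through the partition sum.
* **Zero-weight fragments**: the bait itself (self-ligation is modelled as
  its own read category), the bait-adjacent fragments (reads there are
  indistinguishable from undigested run-through and are removed by the
  filter anyway), and fragments shorter than `min_informative_length`
  (default 20 bp), which cannot carry an identifiable capture — the
  simulation analogue of the "blind" fragments excluded in 4C practice.
  Without this, part of the simulated signal would be unrecoverable by
  construction and truth-equality tests would be meaningless.
* **Reads**: `barcode + bait-end segment + captured-fragment prefix`,
  padded with `A` / truncated to 100 bp (single-end). The bait-end segment
  is the bait fragment's last 24 bases (a fixed 20-base primer stand-in
  plus the CATG), mirroring inverse-PCR geometry. A seeded fraction of
  reads is undigested (captures the downstream bait neighbour; default
  0.05) or self-ligated (captures the bait; default 0.05) — mid-range for
  the artefact levels reported for 4C libraries, and large enough that a
  broken filter cannot pass unnoticed. Padding never influences
  assignment, which reads only the first 20 captured bases.
* **qPCR fixtures**: `sim_qpcr_table()` draws Ct values from
  `intercept + slope·log10(quantity) + N(0, noise_sd)` — the standard-curve
  model the quantitation inverts.

What the generator deliberately does **not** emulate: sequencing errors,
PCR duplicates, chimeric multi-junction reads, trans-chromosomal contacts,
mappability variation, and GC or fragment-length bias. Passing tests
therefore demonstrate the pipeline's arithmetic and bookkeeping are exact
under the model's assumptions, not that the pipeline is robust to every
artefact of real libraries; the MAPQ-based SAM route and the mismatch
tolerance exist for that messier setting.

## Recovery experiments

The end-to-end check plants a fold change *F* ∈ {2, 3, 5} at one
"enhancer" fragment and 0.5 at a second ("looped-out") fragment in
condition B, simulates 200,000 reads per sample, runs the full pipeline on
both conditions, and asks whether the max-library-normalised window-score
ratio at each planted fragment recovers the fold (mean over 20 seeded
replicates within ±25%) and whether the difference track has the correct
sign at both windows (in ≥ 95% of replicates).

A measurement subtlety: with ~256 bp average NlaIII fragments, a 10-kb
window holds ~40 fragments, so a fold at one fragment is diluted ~40-fold
at that window size and no windowed ratio could recover it. Recovery is
therefore measured on a 500-bp window grid, and the planted fragments are
chosen with `resolvable_fragments()`: fragments at least as long as the
window that are the sole fragment starting in their grid cell, within
30 kb of the bait so their expected counts are well away from Poisson
noise. This emulates what the corresponding real analyses do implicitly —
fold quotes come from enhancer peaks that dominate their window. At these
settings the recovered means are unbiased to within ~2% and the ±25% band
is several standard errors wide.

## qPCR quantitation

`fit_standard_curve()` fits `Ct = intercept + slope·log10(quantity)` by
least squares (a valid dilution series has slope ≈ −3.32, i.e.
−1/log10(2)); `quantify_ct()` inverts it. On top of that sit the three
ratio quantities used around chromatin experiments:

* `percent_input(ip, no_ab, input, input_fraction)` =
  `100·(ip − no_ab)/(input/input_fraction)`. The input fraction is an
  explicit required argument — there is no hidden dilution assumption —
  and negative background-subtracted signals are floored at 0 with a
  warning rather than propagated into means.
* `interaction_frequency(library, control)`: 3C junction signal divided by
  a positive-control template signal from within the assay's linear range;
  `linear_range_points()` operationalises "linear range" as titration
  points whose Ct is interior to the titration and whose local slope is
  within 15% (configurable) of the fitted slope.
* `rt_fold_change(target, reference, calibrator)`: expression normalised
  to a reference transcript and a calibrator sample. The reference gene is
  the caller's choice precisely because the canonical one (GAPDH) can
  itself respond to a stimulus, in which case a stable alternative such as
  β2-microglobulin belongs in the denominator.

All three are dimensionless and scale-invariant where dimensional analysis
requires it, which the tests assert directly.

## A worked example

Two conditions, one 3-fold gained enhancer planted on a window-resolvable
fragment near the bait:

```{r example}
cfg0 <- sim_config(sequence_length = 100000L, seed = 7L)
ref <- sim_reference(cfg0)
fm <- ref$fragment_map

elig <- setdiff(resolvable_fragments(fm, 500L),
                c(ref$bait$bait_fragment_index,
                  ref$bait$adjacent_fragment_indices))
d <- abs((fm$start[elig] + fm$end[elig]) / 2 - cfg0$bait_position)
enh <- elig[order(d)][1]

cfg <- sim_config(
  sequence_length = 100000L, reads_per_sample = 50000L,
  undigested_fraction = 0.1, self_ligation_fraction = 0.05,
  enhancer_folds = data.frame(position = fm$start[enh],
                              condition = "infected", fold = 3),
  seed = 7L
)
barcodes <- barcode_table(c("naive", "infected"), c("ACGTGG", "TGCACC"))
naive_lib <- sim_reads(ref, sim_profile(fm, cfg, "naive"),
                       barcodes[1, ], cfg, seed = 71L)
inf_lib <- sim_reads(ref, sim_profile(fm, cfg, "infected"),
                     barcodes[2, ], cfg, seed = 72L)
reads <- dplyr::bind_rows(naive_lib$reads, inf_lib$reads)

pr <- process_run(reads, barcodes, ref)
pr$summary

tracks <- lapply(pr$counts, fixed_window_track, fragment_map = fm,
                 window_size = 500L)
norm <- normalize_to_max_library(tracks)
diff <- subtract_tracks(norm$infected, norm$naive)
dplyr::slice_max(tibble::as_tibble(diff), score, n = 3)
```

The largest positive difference lands exactly in the planted enhancer's
window, the normalised window-score ratio there recovers the planted
3-fold gain, and `autoplot(diff)` renders the gained/lost track.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout (BED convention); fragment
  indices are 1-based. Cut positions are motif *ends*, applied uniformly
  to both enzymes; overlapping motif occurrences each cut; `N` never
  matches a motif.
* A position on a fragment boundary belongs to the downstream fragment
  (forced by half-open intervals).
* Empty inputs return empty, well-typed results (`demultiplex()` of zero
  reads, `sim_reads()` with zero reads); empty fragment maps, zero-total
  tracks, non-positive library sizes and zero denominators are errors, not
  NaNs.
* Ties in barcode distance are unassigned; ambiguous assignment prefixes
  count in `n_ambiguous`, never in two fragments.
* Probability sums are enforced to 1 within 1e-9; relative track sums hold
  to 1e-12; max-library totals to 1e-9 relative.

## Limitations

The internal assigner is exact-prefix based and is intended for the
simulated, error-free regime and for unit-testing the pipeline's
bookkeeping; real libraries should be aligned externally and enter through
`assign_sam()`. Only single-chromosome (cis) quantitation is implemented;
trans contacts, statistical significance calls for differential
interactions, and browser-grade visualisation are out of scope.
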