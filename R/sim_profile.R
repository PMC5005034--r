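#' Build a ground-truth contact profile for one condition
#'
#' Assigns each restriction fragment a contact probability with the bait.
#' The baseline weight of fragment i is `(1 + |mid(i) - mid(bait)|)^-alpha`
#' (power-law distance decay, `alpha = config$decay_exponent`). Each
#' `(position, condition, fold)` row of `config$enhancer_folds` whose
#' condition matches `condition_label` multiplies the weight of the fragment
#' containing `position` by `fold` before renormalisation, so a single
#' planted fold perturbs other fragments only through the partition sum. The
#' bait fragment's weight is forced to 0 (self-ligation is modelled
#' separately as a read category) and the weights are normalised to sum to 1.
#'
#' Non-informative fragments also receive zero weight: the bait-adjacent
#' fragments, whose reads are indistinguishable from undigested run-through
#' and are removed by the bait-proximal filter, and fragments shorter than
#' `min_informative_length`, which cannot carry an identifiable capture --
#' the simulation analogue of the "blind" fragments excluded in 4C practice.
#'
#' @param fragment_map Primary-digest fragment map of the generated
#'   reference.
#' @param config A [sim_config()].
#' @param condition_label Condition whose fold entries apply; a label with no
#'   entries yields the pure decay profile.
#' @param min_informative_length Fragments shorter than this receive zero
#'   contact weight (default 20, matching the assigner's default
#'   `min_match_length`).
#'
#' @return A tibble of class `interaction_profile` with columns `index`,
#'   `start`, `end`, `probability` and attributes `condition` and
#'   `bait_fragment_index`.
#' @export
sim_profile <- function(fragment_map, config, condition_label,
                        min_informative_length = 20L) {
  stopifnot(inherits(config, "sim_config"))
  bait <- locate_bait(fragment_map, config$bait_position)
  mid <- (fragment_map$start + fragment_map$end) / 2
  d <- abs(mid - mid[bait$bait_fragment_index])
  w <- (1 + d)^(-config$decay_exponent)
  ef <- config$enhancer_folds
  if (!is.null(ef)) {
    ef <- filter(ef, .data$condition == condition_label)
    for (k in seq_len(nrow(ef))) {
      hit <- which(fragment_map$start <= ef$position[k] &
                     ef$position[k] < fragment_map$end)
      if (length(hit) != 1L) {
        abort(sprintf("enhancer_folds position %d is not inside any fragment",
                      ef$position[k]))
      }
      w[hit] <- w[hit] * ef$fold[k]
    }
  }
  w[bait$bait_fragment_index] <- 0
  w[bait$adjacent_fragment_indices] <- 0
  w[fragment_map$end - fragment_map$start < min_informative_length] <- 0
  out <- tibble(
    index = fragment_map$index,
    start = fragment_map$start,
    end = fragment_map$end,
    probability = w / sum(w)
  )
  structure(out,
            class = c("interaction_profile", class(out)),
            condition = condition_label,
            bait_fragment_index = bait$bait_fragment_index)
}

#' Fragments resolvable at a given fixed-window size
#'
#' Returns the indices of fragments that are at least `window_size` long and
#' are the only fragment whose start falls in their fixed-window grid cell,
#' so a read-count change at such a fragment is visible undiluted in its
#' window score. Planted enhancer fold changes are sited on these fragments
#' in recovery experiments, emulating an enhancer peak that dominates its
#' window.
#'
#' @param fragment_map A fragment map from [digest_sequence()].
#' @param window_size Fixed-window width in bases (default 1000).
#' @return Integer vector of fragment indices.
#' @export
resolvable_fragments <- function(fragment_map, window_size = 1000L) {
  len <- fragment_map$end - fragment_map$start
  cell <- fragment_map$start %/% window_size
  sole <- !(cell %in% cell[duplicated(cell)])
  fragment_map$index[len >= window_size & sole]
}
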