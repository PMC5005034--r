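#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct = intercept + slope * log10(quantity)` to a
#' titration of known standards (the "standard curve method"). A valid
#' dilution series gives a negative slope near -3.32 (100% amplification
#' efficiency doubles product each cycle: slope = -1/log10(2)).
#'
#' @param standards Data frame with columns `quantity` (> 0) and `ct`; at
#'   least 3 points with distinct quantities.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `n` and the fitted `lm` object; supports
#'   [tidy()], [glance()] and `autoplot()`.
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("quantity", "ct") %in% names(standards)))
  if (nrow(standards) < 3L) abort("need at least 3 standards")
  if (any(standards$quantity <= 0)) abort("quantities must be > 0")
  if (length(unique(standards$quantity)) < 2L) {
    abort("standards collapse to a single quantity; cannot fit a slope")
  }
  fit <- lm(ct ~ log10(quantity), data = standards)
  res <- standards$ct - stats::fitted(fit)
  r2 <- 1 - sum(res^2) / sum((standards$ct - mean(standards$ct))^2)
  structure(
    list(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r_squared = r2,
         n = nrow(standards),
         fit = fit,
         standards = as_tibble(standards)),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> Ct = %.4f %+.4f * log10(q)   (r^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n = x$n)
}

#' Invert a standard curve: Ct to quantity
#'
#' `quantity = 10^((ct - intercept) / slope)`; the inverse of the fitted
#' line, vectorised over `ct`.
#'
#' @param curve A `standard_curve`.
#' @param ct Cycle-threshold value(s).
#' @return Numeric quantities in the standards' units.
#' @export
quantify_ct <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) abort("standard curve has zero slope")
  10^((ct - curve$intercept) / curve$slope)
}

#' ChIP enrichment as percent of input
#'
#' Computes `100 * (ip - no_antibody) / (input / input_fraction)`: the
#' immunoprecipitated signal, after subtraction of the no-antibody control,
#' expressed as a percentage of the total input chromatin (the measured
#' input signal scaled up by the fraction of chromatin it represents).
#' Negative background-subtracted signals are floored at 0 with a warning.
#'
#' @param ip_quantity IP signal (standard-curve quantified).
#' @param no_antibody_quantity No-antibody control signal.
#' @param input_quantity Input sample signal (> 0).
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#'   Required explicitly; there is no hidden dilution assumption.
#' @return Percentage(s); vectorised.
#' @export
percent_input <- function(ip_quantity, no_antibody_quantity,
                          input_quantity, input_fraction) {
  if (any(input_quantity <= 0)) abort("`input_quantity` must be > 0")
  if (any(input_fraction <= 0 | input_fraction > 1)) {
    abort("`input_fraction` must lie in (0, 1]")
  }
  x <- 100 * (ip_quantity - no_antibody_quantity) /
    (input_quantity / input_fraction)
  if (any(x < 0)) {
    warn("negative background-subtracted signal floored at 0")
    x <- pmax(x, 0)
  }
  x
}

#' 3C interaction frequency against a positive control
#'
#' Divides the chromatin-library signal for a ligation junction by the
#' signal of a positive-control template from within the linear range of the
#' assay, giving a dimensionless relative interaction frequency.
#'
#' @param library_quantity Chromatin (3C) library signal(s).
#' @param positive_control_quantity Positive-control signal (> 0).
#' @return `library_quantity / positive_control_quantity`.
#' @export
interaction_frequency <- function(library_quantity, positive_control_quantity) {
  if (any(positive_control_quantity <= 0)) {
    abort("`positive_control_quantity` must be > 0")
  }
  library_quantity / positive_control_quantity
}

#' Reference-gene-normalised RT-qPCR fold change
#'
#' `(target / reference) / calibrator_ratio`: the target signal normalised
#' to a reference transcript (e.g. GAPDH, or beta-2-microglobulin when
#' GAPDH itself responds to the stimulus), expressed relative to a
#' calibrator sample's normalised ratio (1 when expressing a sample relative
#' to itself).
#'
#' @param target_quantity Target transcript signal.
#' @param reference_quantity Reference transcript signal (> 0).
#' @param calibrator_ratio Normalised ratio of the calibrator sample (> 0,
#'   default 1).
#' @return Fold change(s); vectorised.
#' @export
rt_fold_change <- function(target_quantity, reference_quantity,
                           calibrator_ratio = 1) {
  if (any(reference_quantity <= 0)) abort("`reference_quantity` must be > 0")
  if (any(calibrator_ratio <= 0)) abort("`calibrator_ratio` must be > 0")
  (target_quantity / reference_quantity) / calibrator_ratio
}

#' Flag titration points inside the assay's linear range
#'
#' Operationalises "within the linear range": a titration point qualifies if
#' its Ct lies strictly between the minimum and maximum Ct of the titration
#' and the local slope of the adjacent segments (in Ct per log10 quantity)
#' deviates from the fitted overall slope by less than `slope_tol`
#' (relative, default 0.15).
#'
#' @param titration Data frame with columns `quantity`, `ct`.
#' @param slope_tol Relative local-slope tolerance (default 0.15).
#' @return The titration tibble, sorted by quantity, with an added logical
#'   column `in_linear_range`.
#' @export
linear_range_points <- function(titration, slope_tol = 0.15) {
  curve <- fit_standard_curve(titration)
  x <- arrange(as_tibble(titration), .data$quantity)
  lq <- log10(x$quantity)
  seg <- diff(x$ct) / diff(lq)                   # local slope per segment
  ok_seg <- abs(seg - curve$slope) < slope_tol * abs(curve$slope)
  n <- nrow(x)
  # a point is linear if every adjacent segment is, and its Ct is interior
  adj_ok <- c(ok_seg[1L], ok_seg[-1L] & ok_seg[-length(ok_seg)], ok_seg[n - 1L])
  interior <- x$ct > min(x$ct) & x$ct < max(x$ct)
  mutate(x, in_linear_range = adj_ok & interior)
}
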