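# Robustness-oriented DisEn variants. Each is a small, well-defined deviation
# from the core pipeline; all reduce to dispersion_entropy() on clean input
# (altmet_disen excepted, by design).

#' Skip-sample dispersion entropy (SkipDisEn)
#'
#' Removes samples marked missing and concatenates the survivors into a
#' continuous series, preserving their original order, then runs the standard
#' pipeline on the retained samples (location and scale included). On a
#' segment with no missing samples this is identical to
#' [dispersion_entropy()].
#'
#' @inheritParams dispersion_entropy
#' @return A `disen_result`; `n_skipped` counts the removed samples.
#' @export
skip_disen <- function(seg, params = disen_params()) {
  seg <- as_signal_segment(seg)
  kept <- seg$values[!seg$missing]
  disen_core(kept, params, "mean_sd",
             n_total = length(seg$values), n_skipped = sum(seg$missing))
}

#' Linearly interpolated dispersion entropy (LinInterDisEn)
#'
#' Replaces each missing sample by two-point linear interpolation between the
#' nearest available neighbours,
#' `y(x) = (y0 * (x1 - x) + y1 * (x - x0)) / (x1 - x0)`,
#' so the analysed series keeps its original length N. Gaps touching either
#' end of the segment have only one neighbour and are filled by nearest-value
#' extension. The completed series then runs through the standard pipeline.
#'
#' @inheritParams dispersion_entropy
#' @return A `disen_result` with `n_effective = N`; `n_skipped` counts the
#'   interpolated (formerly missing) samples.
#' @export
lininter_disen <- function(seg, params = disen_params()) {
  seg <- as_signal_segment(seg)
  filled <- fill_gaps_linear(seg)
  res <- disen_core(filled, params, "mean_sd",
                    n_total = length(filled), n_skipped = 0L)
  res$n_skipped <- sum(seg$missing)
  res
}

# Interior gaps: exact two-point linear interpolation between nearest
# neighbours; boundary gaps: constant extension (rule = 2).
fill_gaps_linear <- function(seg) {
  miss <- seg$missing
  if (!any(miss)) return(seg$values)
  if (sum(!miss) < 2L)
    disen_stop("linear interpolation needs at least 2 available samples",
               "disen_too_short")
  idx <- seq_along(seg$values)
  stats::approx(x = idx[!miss], y = seg$values[!miss], xout = idx,
                method = "linear", rule = 2)$y
}

#' Robust-statistics dispersion entropy (AltMetDisEn)
#'
#' Identical to [skip_disen()] except that the mapping statistics are the
#' median and the scaled median absolute deviation (1.4826 * MAD) instead of
#' mean and standard deviation. Both estimators resist outliers, so the class
#' allocation is not dragged by an inflated amplitude range. Note that even on
#' clean data the result differs (slightly) from the original algorithm,
#' because median/scaled-MAD and mean/SD are different estimates on any finite
#' sample; that baseline deviation is itself a quantity of interest, see
#' [altmet_baseline_deviation()].
#'
#' If the scaled MAD collapses to zero on non-constant data (a
#' majority-constant window), the degenerate-input convention applies: value
#' 0 with `degenerate = TRUE`.
#'
#' @inheritParams dispersion_entropy
#' @return A `disen_result`.
#' @export
altmet_disen <- function(seg, params = disen_params()) {
  seg <- as_signal_segment(seg)
  kept <- seg$values[!seg$missing]
  disen_core(kept, params, "median_scaled_mad",
             n_total = length(seg$values), n_skipped = sum(seg$missing))
}

#' Dynamic skip-sample dispersion entropy (DynSkipDisEn)
#'
#' Automatically discards outlier samples before the entropy computation:
#' (1) the mean and standard deviation of the raw input segment are computed
#' with all samples included (outliers inflate the SD, which is why a strict
#' cutoff is needed); (2) every sample deviating from that mean by more than
#' `cutoff` standard deviations is discarded, as is every sample already
#' marked missing; (3) the surviving samples are concatenated skip-style and
#' the standard pipeline runs with location and scale recomputed on the
#' survivors.
#'
#' With a very large cutoff and no missing samples this reduces exactly to
#' [dispersion_entropy()].
#'
#' @inheritParams dispersion_entropy
#' @return A `disen_result`; `n_skipped` counts missing plus filtered samples.
#' @export
dynskip_disen <- function(seg, params = disen_params()) {
  seg <- as_signal_segment(seg)
  avail <- seg$values[!seg$missing]
  if (length(avail) < 2L)
    disen_stop("too few available samples for the cutoff filter", "disen_too_short")
  mu <- mean(avail)
  sigma <- stats::sd(avail)
  keep <- abs(avail - mu) <= params$cutoff * sigma
  disen_core(avail[keep], params, "mean_sd",
             n_total = length(seg$values),
             n_skipped = sum(seg$missing) + sum(!keep))
}

#' Look up a variant function by name
#'
#' @param variant One of `"original"`, `"skip"`, `"lininter"`, `"altmet"`,
#'   `"dynskip"`.
#' @return The corresponding function `(seg, params) -> disen_result`.
#' @export
disen_variant <- function(variant) {
  switch(match.arg(variant, c("original", "skip", "lininter", "altmet", "dynskip")),
         original = dispersion_entropy,
         skip = skip_disen,
         lininter = lininter_disen,
         altmet = altmet_disen,
         dynskip = dynskip_disen)
}
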