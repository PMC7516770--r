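# Contamination simulator: produce disruptedM (missing-sample) and disruptedO
# (outlier-sample) copies of a clean series on a grouped-segment grid
# controlled by a percentage factor P and a grouping factor G.

# Run `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

round_half_up <- function(x) floor(x + 0.5)

#' Segment a series into consecutive groups of G samples
#'
#' @param n Series length.
#' @param G Grouping factor (samples per segment, >= 1). When `n` is not a
#'   multiple of `G` a shorter remainder segment is kept (and selectable).
#' @return A data.frame with 1-based inclusive `start` and `end` columns, one
#'   row per segment, in order.
#' @examples
#' segment_series(7, 3)
#' @export
segment_series <- function(n, G) {
  n <- as.integer(n); G <- as.integer(G)
  if (G < 1L || n < G)
    disen_stop("need n >= G >= 1", "disen_invalid_input")
  start <- seq.int(1L, n, by = G)
  data.frame(start = start, end = pmin(start + G - 1L, n))
}

#' Draw the disrupted segments
#'
#' Selects `round(P/100 * n_segments)` distinct segment indices uniformly
#' without replacement (half-up rounding). Reproducible given `seed`.
#'
#' @param n_segments Number of segments available.
#' @param P Percentage of segments to disrupt, in (0, 100].
#' @param seed Integer seed.
#' @return Sorted integer vector of selected segment indices (possibly empty,
#'   with a warning, when the rounded count is 0).
#' @export
select_segments <- function(n_segments, P, seed) {
  if (P <= 0 || P > 100) disen_stop("P must be in (0, 100]", "disen_invalid_input")
  k <- round_half_up(P / 100 * n_segments)
  if (k == 0L) {
    warning("selection percentage rounds to zero segments")
    return(integer(0))
  }
  sort(with_seed(seed, sample.int(n_segments, k, replace = FALSE)))
}

#' Mark the selected segments as missing
#'
#' @param clean A clean [signal_segment()].
#' @param segments Segment table from [segment_series()].
#' @param selection Indices into `segments` (from [select_segments()]).
#' @return A `disrupted_series`: a `signal_segment` whose `missing` mask is
#'   `TRUE` exactly on the selected segments' samples (values untouched), with
#'   a `disruption` attribute recording the recipe.
#' @export
apply_missing <- function(clean, segments, selection) {
  clean <- as_signal_segment(clean)
  mask <- logical(length(clean$values))
  for (i in selection) mask[segments$start[i]:segments$end[i]] <- TRUE
  out <- clean
  out$missing <- mask
  out$values[mask] <- NA_real_
  attr(out, "disruption") <- list(mode = "missing", selection = selection)
  class(out) <- c("disrupted_series", class(clean))
  out
}

#' Inject outlier segments
#'
#' Each selected segment receives one amplitude draw
#' `v ~ Normal(outlier_mean_abs, outlier_sd)` and one sign; every sample in
#' the segment is set to `sign * v` (grouped outliers share sign and value).
#' Signs are balanced: half the selected segments positive, half negative,
#' randomly assigned; with an odd count the extra segment gets a fair-coin
#' sign. `outlier_mean_abs` defaults to 4 times the maximum absolute amplitude
#' of the clean series, placing outliers well outside the physiological range
#' while emulating a bounded recording instrument.
#'
#' @inheritParams apply_missing
#' @param seed Integer seed for the amplitude and sign draws.
#' @param outlier_mean_abs Mean absolute outlier amplitude; default
#'   `4 * max(abs(values))` of the clean series.
#' @param outlier_sd Standard deviation of the outlier amplitude draw
#'   (default 0.5).
#' @return A `disrupted_series` with no missing samples.
#' @export
apply_outliers <- function(clean, segments, selection, seed,
                           outlier_mean_abs = NULL, outlier_sd = 0.5) {
  clean <- as_signal_segment(clean)
  if (any(clean$missing))
    disen_stop("outlier injection expects a complete clean series", "disen_invalid_input")
  if (is.null(outlier_mean_abs))
    outlier_mean_abs <- 4 * max(abs(clean$values))
  if (outlier_mean_abs <= max(abs(clean$values)))
    disen_stop("outlier_mean_abs must exceed the clean series' max |amplitude|",
               "disen_invalid_input")
  k <- length(selection)
  out <- clean
  if (k > 0L) {
    draws <- with_seed(seed, {
      amp <- stats::rnorm(k, mean = outlier_mean_abs, sd = outlier_sd)
      half <- k %/% 2L
      signs <- c(rep(1, half), rep(-1, half))
      if (k %% 2L == 1L) signs <- c(signs, sample(c(-1, 1), 1L))
      list(amp = amp, signs = sample(signs))
    })
    for (j in seq_len(k)) {
      i <- selection[j]
      out$values[segments$start[i]:segments$end[i]] <- draws$signs[j] * draws$amp[j]
    }
  }
  attr(out, "disruption") <- list(mode = "outlier", selection = selection,
                                  outlier_mean_abs = outlier_mean_abs,
                                  outlier_sd = outlier_sd)
  class(out) <- c("disrupted_series", class(clean))
  out
}

#' One disrupted copy of a clean series
#'
#' Convenience wrapper combining [segment_series()], [select_segments()] and
#' [apply_missing()] / [apply_outliers()].
#'
#' @param clean Clean [signal_segment()] (no missing samples).
#' @param mode `"missing"` or `"outlier"`.
#' @param P Percentage of segments disrupted (the paper's grid uses
#'   10, 20, 30, 40, 50).
#' @param G Grouping factor in samples (grid: 1..5).
#' @param seed Integer seed.
#' @param ... Passed to [apply_outliers()] (`outlier_mean_abs`, `outlier_sd`).
#' @return A `disrupted_series`.
#' @export
disrupt_series <- function(clean, mode = c("missing", "outlier"), P, G, seed, ...) {
  mode <- match.arg(mode)
  clean <- as_signal_segment(clean)
  segs <- segment_series(length(clean$values), G)
  sel <- select_segments(nrow(segs), P, seed)
  out <- if (mode == "missing") apply_missing(clean, segs, sel)
         else apply_outliers(clean, segs, sel, seed = seed + 1L, ...)
  attr(out, "disruption") <- c(attr(out, "disruption"),
                               list(P = P, G = G, seed = seed))
  out
}

#' Generate the full disruption battery for one series
#'
#' Replicates the contamination recipe over every (P, G) combination
#' `replicates` times; the default grid (P in 10..50 by 10, G in 1..5, 10
#' replicates) yields 5 x 5 x 10 = 250 disrupted copies. Per-copy seeds are
#' derived deterministically from `base_seed` and the grid position, so two
#' runs with the same `base_seed` are identical.
#'
#' @inheritParams disrupt_series
#' @param P_list Percentages of segments to disrupt.
#' @param G_list Grouping factors.
#' @param replicates Disrupted copies per (P, G) cell.
#' @param base_seed Integer master seed.
#' @return A list of `disrupted_series`; each element's `disruption` attribute
#'   records `P`, `G`, `replicate` and the derived seed.
#' @export
generate_disruption_battery <- function(clean, mode = c("missing", "outlier"),
                                        P_list = c(10, 20, 30, 40, 50),
                                        G_list = 1:5, replicates = 10L,
                                        base_seed = 1L, ...) {
  mode <- match.arg(mode)
  if (length(P_list) == 0L || length(G_list) == 0L || replicates < 1L)
    disen_stop("empty disruption grid", "disen_invalid_input")
  out <- vector("list", length(P_list) * length(G_list) * replicates)
  k <- 0L
  for (pi in seq_along(P_list)) for (gi in seq_along(G_list)) for (r in seq_len(replicates)) {
    k <- k + 1L
    seed <- derive_seed(base_seed, pi, gi, r)
    d <- disrupt_series(clean, mode, P = P_list[pi], G = G_list[gi], seed = seed, ...)
    attr(d, "disruption")$replicate <- r
    out[[k]] <- d
  }
  out
}

# Deterministic per-copy seed; keeps results below 2^31 - 1.
derive_seed <- function(base_seed, pi, gi, r) {
  as.integer((as.numeric(base_seed) * 2654435761 + pi * 1000003 +
                gi * 10007 + r * 101) %% 2147483647)
}
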