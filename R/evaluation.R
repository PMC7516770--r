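# Windowed ground-truth evaluation: non-overlapping windows on the original
# index grid, per-window absolute percentage deviation from the clean-window
# DisEn, and pooled (variant, P, G) summaries.

#' Non-overlapping window grid
#'
#' Splits `1..n` into `floor(n / window_length)` consecutive windows of equal
#' length; a trailing partial window is discarded.
#'
#' @param n Series length.
#' @param window_length Samples per window (default 360, a deliberately small
#'   window stressing short-segment performance).
#' @return A data.frame with `window`, `start`, `end` columns (1-based
#'   inclusive).
#' @export
window_series <- function(n, window_length = 360L) {
  n <- as.integer(n); window_length <- as.integer(window_length)
  if (window_length < 1L) disen_stop("window_length must be >= 1", "disen_invalid_input")
  k <- n %/% window_length
  if (k < 1L)
    disen_stop(sprintf("series of length %d shorter than one %d-sample window",
                       n, window_length), "disen_too_short")
  start <- (seq_len(k) - 1L) * window_length + 1L
  data.frame(window = seq_len(k), start = start, end = start + window_length - 1L)
}

window_values <- function(seg, grid, i) {
  signal_segment(seg$values[grid$start[i]:grid$end[i]],
                 seg$missing[grid$start[i]:grid$end[i]])
}

#' Ground-truth DisEn per window
#'
#' Applies the original algorithm independently to each clean window.
#'
#' @param clean Clean [signal_segment()] (no missing samples).
#' @param grid Window grid from [window_series()].
#' @param params [disen_params()].
#' @return Numeric vector of DisEn values (nats), one per window.
#' @export
ground_truth <- function(clean, grid, params = disen_params()) {
  clean <- as_signal_segment(clean)
  vapply(seq_len(nrow(grid)), function(i)
    dispersion_entropy(window_values(clean, grid, i), params)$value,
    numeric(1))
}

#' Evaluate one variant against per-window ground truth
#'
#' For every window of the grid, runs `variant` on the disrupted window (the
#' same index range of the disrupted series) and computes the absolute
#' percentage deviation `|observed - truth| / truth * 100` from the clean
#' window's original-DisEn ground truth. Windows where the variant cannot run
#' (too few retained samples) are kept with status `"failed"`; windows with
#' zero ground truth are kept with status `"undefined_truth"`. Both are
#' excluded from summaries but counted.
#'
#' @param clean Clean [signal_segment()].
#' @param disrupted The disrupted copy (same length, same index grid).
#' @param variant Variant name, see [disen_variant()].
#' @param grid Window grid from [window_series()].
#' @param params [disen_params()].
#' @param truth Optional precomputed [ground_truth()] vector (avoids
#'   recomputing it for every disrupted copy).
#' @return A data.frame with one row per window: `window`, `variant`, `truth`,
#'   `observed`, `abs_pct_deviation`, `status` (`"ok"`, `"failed"`,
#'   `"undefined_truth"`).
#' @export
evaluate_variant <- function(clean, disrupted, variant, grid,
                             params = disen_params(), truth = NULL) {
  clean <- as_signal_segment(clean)
  fn <- disen_variant(variant)
  if (is.null(truth)) truth <- ground_truth(clean, grid, params)
  k <- nrow(grid)
  observed <- rep(NA_real_, k)
  status <- rep("ok", k)
  for (i in seq_len(k)) {
    res <- tryCatch(fn(window_values(disrupted, grid, i), params),
                    disen_too_short = function(e) NULL)
    if (is.null(res)) status[i] <- "failed" else observed[i] <- res$value
  }
  dev <- ifelse(status == "ok" & truth > 0,
                abs(observed - truth) / truth * 100, NA_real_)
  status[status == "ok" & truth <= 0] <- "undefined_truth"
  data.frame(window = grid$window, variant = variant, truth = truth,
             observed = observed, abs_pct_deviation = dev, status = status,
             stringsAsFactors = FALSE)
}

#' Baseline deviation of the robust-statistics variant on clean data
#'
#' AltMetDisEn differs from the original algorithm even on clean series,
#' because median/scaled-MAD and mean/SD are different finite-sample
#' estimates. This measures that intrinsic deviation: per window,
#' `|altmet - original| / original * 100`, pooled over all windows of all
#' supplied series.
#'
#' @param series A [signal_segment()] or list of them (clean, no missing
#'   samples).
#' @param window_length Samples per window.
#' @param params [disen_params()].
#' @return A list with `mean`, `sd` (both %), and `n` windows used.
#' @export
altmet_baseline_deviation <- function(series, window_length = 360L,
                                      params = disen_params()) {
  if (inherits(series, "signal_segment") || is.numeric(series))
    series <- list(series)
  devs <- unlist(lapply(series, function(s) {
    s <- as_signal_segment(s)
    grid <- window_series(length(s$values), window_length)
    truth <- ground_truth(s, grid, params)
    rec <- evaluate_variant(s, s, "altmet", grid, params, truth = truth)
    rec$abs_pct_deviation[rec$status == "ok"]
  }))
  list(mean = mean(devs), sd = stats::sd(devs), n = length(devs))
}

#' Summarise an experimental cell
#'
#' Pools every valid per-window deviation of one (variant, P, G) cell —
#' across windows, replicates and series — into a single mean absolute
#' percentage deviation with its standard deviation. `sd_mode = "by_series"`
#' instead reports the SD across per-series mean deviations (the alternative
#' reading of the averaging hierarchy); the mean is unaffected when series
#' contribute equal window counts.
#'
#' @param records A data.frame of [evaluate_variant()] rows (rbind of one
#'   cell), optionally with a `series` column for `sd_mode = "by_series"`.
#' @param sd_mode `"pooled"` (default) or `"by_series"`.
#' @return A list with `mean`, `sd`, `n_ok`, `n_failed`, `n_undefined`.
#' @export
summarize_setup <- function(records, sd_mode = c("pooled", "by_series")) {
  sd_mode <- match.arg(sd_mode)
  if (nrow(records) == 0L) disen_stop("empty cell", "disen_invalid_input")
  ok <- records$status == "ok"
  devs <- records$abs_pct_deviation[ok]
  if (length(devs) == 0L) disen_stop("no valid windows in cell", "disen_invalid_input")
  s <- if (sd_mode == "pooled") {
    if (length(devs) > 1L) stats::sd(devs) else 0
  } else {
    if (is.null(records$series))
      disen_stop("by_series SD needs a 'series' column", "disen_invalid_input")
    per <- tapply(records$abs_pct_deviation[ok], records$series[ok], mean)
    if (length(per) > 1L) stats::sd(per) else 0
  }
  list(mean = mean(devs), sd = s,
       n_ok = sum(ok),
       n_failed = sum(records$status == "failed"),
       n_undefined = sum(records$status == "undefined_truth"))
}

#' Evaluate variants over a full disruption battery
#'
#' Convenience driver: generates (or accepts) a disruption battery for one
#' clean series, evaluates each requested variant on every disrupted copy,
#' and returns the per-window records plus the per-(variant, P, G) summary
#' table — the tidy data behind the study's performance figures.
#'
#' @param clean Clean [signal_segment()].
#' @param mode `"missing"` or `"outlier"`.
#' @param variants Character vector of variant names.
#' @param P_list,G_list,replicates,base_seed Battery grid, see
#'   [generate_disruption_battery()].
#' @param window_length,params Evaluation settings.
#' @param series_id Identifier copied into the output tables.
#' @return A list with `records` (per-window data.frame incl. `P`, `G`,
#'   `replicate`) and `summary` (one row per variant x P x G with pooled mean
#'   and SD of the absolute percentage deviation).
#' @export
evaluate_battery <- function(clean, mode, variants,
                             P_list = c(10, 20, 30, 40, 50), G_list = 1:5,
                             replicates = 10L, base_seed = 1L,
                             window_length = 360L, params = disen_params(),
                             series_id = "series") {
  clean <- as_signal_segment(clean)
  grid <- window_series(length(clean$values), window_length)
  truth <- ground_truth(clean, grid, params)
  battery <- generate_disruption_battery(clean, mode, P_list, G_list,
                                         replicates, base_seed)
  recs <- vector("list", length(battery) * length(variants))
  k <- 0L
  for (d in battery) {
    info <- attr(d, "disruption")
    for (v in variants) {
      k <- k + 1L
      r <- evaluate_variant(clean, d, v, grid, params, truth = truth)
      r$P <- info$P; r$G <- info$G; r$replicate <- info$replicate
      r$series <- series_id
      recs[[k]] <- r
    }
  }
  records <- do.call(rbind, recs)
  cells <- unique(records[, c("variant", "P", "G")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$variant == cells$variant[i] & records$P == cells$P[i] &
      records$G == cells$G[i]
    s <- summarize_setup(records[sel, ])
    data.frame(series = series_id, variant = cells$variant[i],
               P = cells$P[i], G = cells$G[i],
               mean_abs_pct_deviation = s$mean, sd_abs_pct_deviation = s$sd,
               n_ok = s$n_ok, n_failed = s$n_failed,
               n_undefined = s$n_undefined, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(records = records, summary = summ)
}
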