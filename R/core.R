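# Core dispersion-entropy pipeline: location/scale estimation, log-sigmoid
# mapping, class allocation, pattern extraction, Shannon entropy.

disen_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "disen_error", "error", "condition")))
}

#' Construct a signal segment
#'
#' A `signal_segment` bundles a finite univariate amplitude series with an
#' aligned missing-sample mask. Missing samples may be supplied either through
#' `missing_mask` or as `NA`/`NaN` entries in `values`; both conventions are
#' merged into one mask.
#'
#' @param values Numeric vector of amplitudes (one sample per element).
#' @param missing_mask Optional logical vector, `TRUE` where a sample is
#'   missing. Defaults to `is.na(values)`.
#' @param id Optional character identifier carried through evaluation tables.
#' @return An object of class `signal_segment` with elements `values`,
#'   `missing` and `id`. Non-missing values are guaranteed finite.
#' @examples
#' seg <- signal_segment(c(1, 2, NA, 3))
#' seg$missing
#' @export
signal_segment <- function(values, missing_mask = NULL, id = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1L) disen_stop("a signal segment needs at least one sample", "disen_invalid_input")
  if (is.null(missing_mask)) {
    missing_mask <- is.na(values)
  } else {
    if (length(missing_mask) != n)
      disen_stop("missing_mask must be the same length as values", "disen_invalid_input")
    missing_mask <- as.logical(missing_mask) | is.na(values)
  }
  if (any(!is.finite(values[!missing_mask])))
    disen_stop("non-missing samples must be finite", "disen_invalid_input")
  values[missing_mask] <- NA_real_
  structure(list(values = values, missing = missing_mask, id = id),
            class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment> N = %d, missing = %d%s\n",
              length(x$values), sum(x$missing),
              if (is.null(x$id)) "" else paste0(", id = ", x$id)))
  invisible(x)
}

#' @export
length.signal_segment <- function(x) length(x$values)

as_signal_segment <- function(x) {
  if (inherits(x, "signal_segment")) x else signal_segment(x)
}

#' Dispersion entropy parameters
#'
#' The algorithm configuration. Defaults are the fixed parameter set used
#' throughout the evaluation harness: embedding dimension `m = 2` samples,
#' `c = 6` classes, time delay `d = 1` sample, log-sigmoid mapping, and a
#' cutoff of 0.7 standard deviations (the cutoff is consumed only by
#' [dynskip_disen()]).
#'
#' @param m Embedding dimension (integer, >= 1): length of each dispersion
#'   pattern.
#' @param c Number of classes (integer, >= 2).
#' @param d Time delay (integer, >= 1): index stride between pattern elements.
#' @param mapping Mapping function name; only `"logsig"` is implemented.
#' @param cutoff Positive multiple of the segment standard deviation beyond
#'   which [dynskip_disen()] discards samples.
#' @return An object of class `disen_params`.
#' @export
disen_params <- function(m = 2L, c = 6L, d = 1L, mapping = "logsig", cutoff = 0.7) {
  m <- as.integer(m); c <- as.integer(c); d <- as.integer(d)
  if (is.na(m) || m < 1L) disen_stop("m must be an integer >= 1", "disen_invalid_input")
  if (is.na(c) || c < 2L) disen_stop("c must be an integer >= 2", "disen_invalid_input")
  if (is.na(d) || d < 1L) disen_stop("d must be an integer >= 1", "disen_invalid_input")
  mapping <- match.arg(mapping, "logsig")
  if (!is.numeric(cutoff) || cutoff <= 0) disen_stop("cutoff must be > 0", "disen_invalid_input")
  structure(list(m = m, c = c, d = d, mapping = mapping, cutoff = cutoff),
            class = "disen_params")
}

#' Location and scale of a series
#'
#' Computes the statistics used to standardise the signal before the
#' log-sigmoid mapping. `"mean_sd"` is the classical pair (arithmetic mean,
#' sample standard deviation with the n-1 denominator). `"median_scaled_mad"`
#' is the robust pair used by the AltMetDisEn variant: the median, and the
#' median absolute deviation from the median scaled by 1.4826 so that it is a
#' consistent estimator of the standard deviation under normality.
#'
#' @param values Numeric vector, at least 2 finite values.
#' @param method `"mean_sd"` or `"median_scaled_mad"`.
#' @return A list of class `location_scale` with elements `location`, `scale`
#'   (>= 0) and `method`.
#' @examples
#' compute_location_scale(1:5, "mean_sd")               # (3, sqrt(2.5))
#' compute_location_scale(c(1, 2, 3, 4, 100), "median_scaled_mad")
#' @export
compute_location_scale <- function(values, method = c("mean_sd", "median_scaled_mad")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 2L)
    disen_stop("location/scale needs at least 2 values", "disen_invalid_input")
  if (any(!is.finite(values)))
    disen_stop("location/scale needs finite values", "disen_invalid_input")
  if (method == "mean_sd") {
    loc <- mean(values); sc <- stats::sd(values)
  } else {
    loc <- stats::median(values); sc <- stats::mad(values)  # constant 1.4826
  }
  structure(list(location = loc, scale = sc, method = method),
            class = "location_scale")
}

#' Log-sigmoid mapping
#'
#' Squashes the standardised signal into (0, 1):
#' `y_j = 1 / (1 + exp(-(x_j - location) / scale))`. Monotone in `x_j`; the
#' location maps to 0.5.
#'
#' @param values Numeric vector of amplitudes.
#' @param ls A [compute_location_scale()] result with strictly positive scale.
#' @return Numeric vector strictly inside (0, 1).
#' @export
map_logsig <- function(values, ls) {
  if (ls$scale <= 0)
    disen_stop("degenerate (zero-scale) input: mapping undefined", "disen_degenerate_scale")
  1 / (1 + exp(-(values - ls$location) / ls$scale))
}

#' Allocate mapped samples to classes
#'
#' Each mapped sample y in (0, 1) receives the integer class
#' `round(c * y + 0.5)` with ties rounded half away from zero, clipped to
#' `[1, c]`. Class boundaries therefore sit at y = k/c, and the allocation is
#' monotone in y.
#'
#' @param mapped Numeric vector in (0, 1).
#' @param n_classes Number of classes c (integer >= 2).
#' @return Integer vector of classes in `[1, n_classes]`.
#' @export
assign_classes <- function(mapped, n_classes) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) disen_stop("need at least 2 classes", "disen_invalid_input")
  if (any(mapped <= 0 | mapped >= 1))
    disen_stop("mapped values must lie strictly in (0, 1)", "disen_invalid_input")
  # round-half-away-from-zero; the argument is always positive here
  u <- floor(n_classes * mapped + 0.5 + 0.5)
  as.integer(pmin(pmax(u, 1), n_classes))
}

#' Extract the dispersion-pattern distribution
#'
#' Forms every delay-embedded vector `(u_i, u_{i+d}, ..., u_{i+(m-1)d})` for
#' i = 1 .. N - (m-1)d and tallies the occurrences of each pattern.
#'
#' @param classes Integer vector of class labels.
#' @param m Embedding dimension.
#' @param d Time delay.
#' @return An object of class `dispersion_distribution`: a list with
#'   `counts` (named integer vector; names are comma-separated class tuples)
#'   and `n_vectors` (= N - (m-1)d). Counts sum to `n_vectors`.
#' @examples
#' extract_patterns(c(1, 2, 3, 2, 1), m = 2, d = 1)
#' @export
extract_patterns <- function(classes, m, d) {
  classes <- as.integer(classes)
  n <- length(classes)
  m <- as.integer(m); d <- as.integer(d)
  n_vec <- n - (m - 1L) * d
  if (n_vec < 1L)
    disen_stop(sprintf("series of length %d too short for m = %d, d = %d", n, m, d),
               "disen_too_short")
  emb <- vapply(seq_len(m) - 1L, function(k) classes[seq_len(n_vec) + k * d],
                integer(n_vec))
  if (n_vec == 1L) emb <- matrix(emb, nrow = 1L)
  keys <- apply(emb, 1L, paste, collapse = ",")
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, n_vectors = n_vec, m = m),
            class = "dispersion_distribution")
}

#' Relative pattern frequencies
#'
#' @param dist A [extract_patterns()] result.
#' @return Named numeric vector of relative frequencies summing to 1.
#' @export
pattern_frequencies <- function(dist) {
  dist$counts / dist$n_vectors
}

#' Shannon entropy of a dispersion distribution
#'
#' `-sum(p_k log p_k)` in nats over patterns with positive frequency. Zero for
#' a single pattern; the maximum `m * log(c)` is attained when all `c^m`
#' patterns are equiprobable.
#'
#' @param dist A [extract_patterns()] result.
#' @return Entropy in nats (non-negative scalar).
#' @export
shannon_entropy <- function(dist) {
  if (is.null(dist$n_vectors) || dist$n_vectors < 1L || length(dist$counts) == 0L)
    disen_stop("empty dispersion distribution", "disen_invalid_input")
  p <- dist$counts / dist$n_vectors
  p <- p[p > 0]
  -sum(p * log(p))
}

# Shared tail of every variant: map -> classify -> embed -> entropy.
# `values` are the retained, finite samples in original order.
disen_core <- function(values, params, ls_method, n_total, n_skipped) {
  min_n <- (params$m - 1L) * params$d + 1L
  if (length(values) < max(min_n, 2L))
    disen_stop(sprintf(
      "need at least %d samples for m = %d, d = %d (got %d)",
      max(min_n, 2L), params$m, params$d, length(values)), "disen_too_short")
  ls <- compute_location_scale(values, ls_method)
  if (ls$scale <= 0) {
    # constant (or majority-constant under MAD) input: a single class, hence a
    # single pattern and entropy 0 in the analytic limit
    return(disen_result(0, params, n_effective = length(values),
                        n_skipped = n_skipped, degenerate = TRUE))
  }
  y <- map_logsig(values, ls)
  u <- assign_classes(y, params$c)
  dist <- extract_patterns(u, params$m, params$d)
  disen_result(shannon_entropy(dist), params, n_effective = length(values),
               n_skipped = n_skipped, degenerate = FALSE)
}

disen_result <- function(value, params, n_effective, n_skipped, degenerate) {
  structure(list(value = value,
                 normalized = value / (params$m * log(params$c)),
                 n_effective = n_effective,
                 n_skipped = n_skipped,
                 degenerate = degenerate,
                 params = params),
            class = "disen_result")
}

#' @export
print.disen_result <- function(x, ...) {
  cat(sprintf("DisEn = %.5f nats (normalized %.4f), n = %d, skipped = %d%s\n",
              x$value, x$normalized, x$n_effective, x$n_skipped,
              if (x$degenerate) " [degenerate input]" else ""))
  invisible(x)
}

#' Dispersion entropy of a complete series
#'
#' The original algorithm: standardise with mean and sample standard
#' deviation, map through the log-sigmoid, allocate `c` classes, extract the
#' `(m, d)` dispersion-pattern distribution and take its Shannon entropy.
#' The original algorithm has no notion of missing data: any sample marked
#' missing raises an error (use [skip_disen()], [lininter_disen()] or
#' [altmet_disen()] for gapped data). A constant series has exactly one
#' pattern; it returns value 0 with `degenerate = TRUE` rather than dividing
#' by a zero scale.
#'
#' @param seg A [signal_segment()] (or plain numeric vector) with no missing
#'   samples.
#' @param params A [disen_params()] configuration.
#' @return A `disen_result`: `value` (nats, in `[0, m*log(c)]`), `normalized`
#'   (`value / (m*log(c))`), `n_effective`, `n_skipped`, `degenerate`.
#' @examples
#' set.seed(1)
#' dispersion_entropy(rnorm(360))
#' @export
dispersion_entropy <- function(seg, params = disen_params()) {
  seg <- as_signal_segment(seg)
  if (any(seg$missing))
    disen_stop("the original algorithm cannot analyse series with missing samples",
               "disen_missing_samples")
  disen_core(seg$values, params, "mean_sd",
             n_total = length(seg$values), n_skipped = 0L)
}
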