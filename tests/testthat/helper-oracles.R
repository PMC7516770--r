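# Independent oracles used across the suite.

# Brute-force dispersion-pattern tally: materialise every embedded vector
# with an explicit loop and count keys in a plain environment.
oracle_patterns <- function(u, m, d) {
  n_vec <- length(u) - (m - 1) * d
  tally <- new.env()
  for (i in seq_len(n_vec)) {
    key <- paste(u[i + (0:(m - 1)) * d], collapse = ",")
    prev <- if (exists(key, tally, inherits = FALSE)) get(key, tally) else 0L
    assign(key, prev + 1L, tally)
  }
  keys <- sort(ls(tally))
  counts <- vapply(keys, function(k) get(k, tally), integer(1))
  names(counts) <- keys
  counts
}

# Eulerian circuit over the complete digraph (with loops) on k vertices,
# via Hierholzer's algorithm. The returned vertex walk has length k^2 + 1 and
# its consecutive pairs cover every ordered pair of classes exactly once, so
# the (m = 2, d = 1) pattern distribution of this class series is uniform.
debruijn_classes <- function(k) {
  adj <- lapply(seq_len(k), function(i) seq_len(k))
  stack <- 1L
  circuit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    if (length(adj[[v]])) {
      w <- adj[[v]][1]
      adj[[v]] <- adj[[v]][-1]
      stack <- c(stack, w)
    } else {
      circuit <- c(circuit, v)
      stack <- stack[-length(stack)]
    }
  }
  rev(circuit)
}

# Closed-form expected dispersion entropy of iid Gaussian input under the
# log-sigmoid pipeline: class-occupancy probabilities are Phi at the
# logit(k/c) boundaries; iid samples make the m-tuple entropy m * H1.
gauss_logsig_disen <- function(c = 6, m = 2) {
  bounds <- stats::qlogis(seq_len(c - 1) / c)
  p <- diff(stats::pnorm(c(-Inf, bounds, Inf)))
  -m * sum(p * log(p))
}

# Random series on a dyadic grid (multiples of 2^-8), so that scaling by a
# power of two and shifting by an integer are exact in floating point.
dyadic_series <- function(n) sample.int(512L, n, replace = TRUE) / 256
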