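# Nonparametric comparison layer for deviation distributions: a
# Kolmogorov-Smirnov normality screen followed by pairwise Mann-Whitney U
# tests between variants tested under the same experimental setup.

#' Kolmogorov-Smirnov normality screen
#'
#' Standardises the deviations (subtract mean, divide by sample SD) and
#' compares them to the standard normal with a two-sided one-sample KS test.
#' Note the usual caveat: with estimated location and scale the plain KS
#' p-value is conservative anti-normal (a Lilliefors-type situation); the
#' screen is used only to justify the switch to rank-based tests.
#'
#' @param deviations Numeric vector, n >= 5, non-degenerate.
#' @return A list with `statistic` and `p_value`.
#' @export
ks_normality_screen <- function(deviations) {
  deviations <- deviations[is.finite(deviations)]
  if (length(deviations) < 5L)
    disen_stop("normality screen needs at least 5 values", "disen_invalid_input")
  s <- stats::sd(deviations)
  if (s == 0)
    disen_stop("degenerate (constant) distribution", "disen_degenerate_scale")
  z <- (deviations - mean(deviations)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Pairwise Mann-Whitney U tests within one experimental setup
#'
#' Applies a two-sided Mann-Whitney U (Wilcoxon rank-sum) test to every
#' unordered pair of deviation distributions produced by different variants
#' under the same setup. No multiplicity correction is applied; instead a
#' strict raw significance threshold (default 1e-3) flags each pair.
#'
#' @param cells Named list mapping variant name to its numeric deviation
#'   vector.
#' @param threshold Raw p-value significance threshold.
#' @return A data.frame with one row per pair: `variant_a`, `variant_b`,
#'   `u_statistic`, `p_value`, `significant`.
#' @export
pairwise_mannwhitney <- function(cells, threshold = 1e-3) {
  keep <- vapply(cells, function(x) length(x[is.finite(x)]) > 0L, logical(1))
  if (any(!keep)) {
    warning(sprintf("skipping empty cell(s): %s",
                    paste(names(cells)[!keep], collapse = ", ")))
    cells <- cells[keep]
  }
  vs <- names(cells)
  if (length(vs) < 2L)
    disen_stop("need at least 2 non-empty variants to compare", "disen_invalid_input")
  pairs <- utils::combn(vs, 2L)
  out <- apply(pairs, 2L, function(p) {
    wt <- suppressWarnings(stats::wilcox.test(cells[[p[1]]], cells[[p[2]]],
                                              alternative = "two.sided"))
    data.frame(variant_a = p[1], variant_b = p[2],
               u_statistic = unname(wt$statistic), p_value = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_value < threshold
  rownames(out) <- NULL
  out
}

#' Pairwise tests across a whole summary grid
#'
#' Groups per-window deviation records by experimental setup (and any other
#' grouping columns present, e.g. dataset or disruption mode) and runs
#' [pairwise_mannwhitney()] within each cell. On the full study grid of 3
#' variants x 25 (P, G) setups x 3 datasets x 2 disruption modes this yields
#' 450 comparisons.
#'
#' @param records Data.frame with columns `variant`, `abs_pct_deviation`,
#'   `status`, plus the grouping columns.
#' @param by Character vector of grouping column names (default `c("P", "G")`
#'   plus `"series"` and `"mode"` when present).
#' @param threshold Raw p-value threshold.
#' @return Data.frame: grouping columns + pair columns.
#' @export
compare_variants <- function(records, by = NULL, threshold = 1e-3) {
  if (is.null(by))
    by <- intersect(c("mode", "series", "P", "G"), names(records))
  ok <- records[records$status == "ok", , drop = FALSE]
  key <- interaction(ok[by], drop = TRUE)
  out <- lapply(split(ok, key), function(cell) {
    cells <- split(cell$abs_pct_deviation, cell$variant)
    if (length(cells) < 2L) return(NULL)
    res <- pairwise_mannwhitney(cells, threshold)
    cbind(cell[rep(1L, nrow(res)), by, drop = FALSE], res)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
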