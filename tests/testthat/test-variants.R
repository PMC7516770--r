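test_that("skip variant reduces to the original on complete series and to
           manual concatenation on gapped ones", {
  set.seed(21)
  x <- rnorm(360)
  expect_identical(skip_disen(x)$value, dispersion_entropy(x)$value)

  seg <- signal_segment(c(1, 2, NA, 3, 2, 1))
  expect_identical(skip_disen(seg)$value,
                   dispersion_entropy(c(1, 2, 3, 2, 1))$value)
  expect_identical(skip_disen(seg)$n_skipped, 1L)

  # order preservation against a hand-built oracle on random masks
  for (rep in 1:20) {
    v <- rnorm(120)
    mask <- runif(120) < 0.3
    if (sum(!mask) < 3) next
    got <- skip_disen(signal_segment(ifelse(mask, NA, v)))
    want <- dispersion_entropy(v[!mask])
    expect_identical(got$value, want$value)
    expect_identical(got$n_skipped, sum(mask))
  }

  all_gone <- signal_segment(rep(NA_real_, 10), rep(TRUE, 10))
  expect_error(skip_disen(all_gone), class = "disen_too_short")
})

test_that("linear interpolation fills gaps by the two-point formula and
           nearest-value extension at the boundaries", {
  expect_identical(lininter_disen(signal_segment(c(0, 1, NA, 3, 4)))$value,
                   dispersion_entropy(0:4)$value)
  seg <- signal_segment(c(NA, 5, 6, 7))
  expect_identical(disentropy:::fill_gaps_linear(seg), c(5, 5, 6, 7))
  expect_identical(disentropy:::fill_gaps_linear(
    signal_segment(c(1, 2, NA, NA, 8, NA))), c(1, 2, 4, 6, 8, 8))

  x <- rnorm(100)
  expect_identical(lininter_disen(x)$value, dispersion_entropy(x)$value)
  expect_error(lininter_disen(signal_segment(c(NA, 1, NA))),
               class = "disen_too_short")
})

test_that("linear interpolation recovers piecewise-linear series exactly", {
  # integer-valued triangle wave: interpolation of interior gaps is exact
  tri <- as.numeric(c(0:10, 9:0))  # period 21, linear pieces 1..11 and 11..21
  x <- rep(tri, 20)                # length 420
  mask <- rep(FALSE, 420)
  for (p0 in 21 * (0:19)) {
    mask[p0 + 3:5] <- TRUE     # inside the ascending piece
    mask[p0 + 14:16] <- TRUE   # inside the descending piece
  }
  seg <- signal_segment(ifelse(mask, NA, x))
  expect_identical(disentropy:::fill_gaps_linear(seg), x)
  expect_identical(lininter_disen(seg)$value, dispersion_entropy(x)$value)
})

test_that("robust-statistics variant shrugs off a single huge outlier and
           tracks the original on symmetric data", {
  withers <- compute_location_scale(c(1:359, 1e6), "median_scaled_mad")
  clean <- compute_location_scale(1:360, "median_scaled_mad")
  expect_equal(withers$location, clean$location, tolerance = 0.01)
  expect_equal(withers$scale, clean$scale, tolerance = 0.01)

  set.seed(31)
  x <- rnorm(360)
  a <- altmet_disen(x)$value
  o <- dispersion_entropy(x)$value
  expect_lt(abs(a - o) / o, 0.10)  # consistent estimators on symmetric data

  # skips missing samples the same way skip_disen does
  v <- rnorm(200); mask <- runif(200) < 0.2
  seg <- signal_segment(ifelse(mask, NA, v))
  expect_identical(altmet_disen(seg)$value, altmet_disen(v[!mask])$value)
})

test_that("scaled MAD of large Gaussian samples converges to the true SD", {
  set.seed(77)
  x <- rnorm(1e5, sd = 3)
  expect_equal(stats::mad(x), 3, tolerance = 0.02)
})

test_that("majority-constant series triggers the degenerate-MAD convention", {
  x <- c(rep(5, 80), rnorm(20))
  res <- altmet_disen(x)
  expect_true(res$degenerate)
  expect_equal(res$value, 0)
})

test_that("dynamic skip removes exactly the out-of-range samples", {
  set.seed(41)
  x <- rnorm(360)
  huge <- disen_params(cutoff = 1e6)
  expect_identical(dynskip_disen(x, huge)$value, dispersion_entropy(x)$value)

  # low-frequency sinusoid with one injected outlier at 4x max amplitude:
  # a cutoff of 2 SDs removes the outlier and nothing else
  ri <- sin(2 * pi * 0.01 * (1:360))
  spiked <- ri
  spiked[100] <- 4 * max(abs(ri))
  p2 <- disen_params(cutoff = 2)
  mu <- mean(spiked); sdev <- sd(spiked)
  expect_identical(which(abs(spiked - mu) > 2 * sdev), 100L)
  masked <- signal_segment(replace(spiked, 100, NA))
  expect_identical(dynskip_disen(spiked, p2)$value, skip_disen(masked, p2)$value)
  expect_identical(dynskip_disen(spiked, p2)$n_skipped, 1L)

  # constant segment: zero SD means zero deviations, everything retained
  const <- dynskip_disen(rep(2, 50))
  expect_true(const$degenerate)
  expect_identical(const$n_skipped, 0L)
  expect_equal(const$value, 0)
})

test_that("dynamic skip honours the missing mask before filtering", {
  set.seed(51)
  v <- rnorm(300)
  mask <- runif(300) < 0.1
  seg <- signal_segment(ifelse(mask, NA, v))
  expect_identical(dynskip_disen(seg, disen_params(cutoff = 1e6))$value,
                   skip_disen(seg)$value)
})
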