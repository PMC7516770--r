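test_that("location/scale estimators match their closed forms", {
  ls <- compute_location_scale(1:5, "mean_sd")
  expect_equal(ls$location, 3)
  expect_equal(ls$scale, sqrt(2.5))  # sample SD, n - 1 denominator

  ls <- compute_location_scale(c(1, 2, 3, 4, 100), "median_scaled_mad")
  expect_equal(ls$location, 3)
  expect_equal(ls$scale, 1.4826)  # MAD of {2,1,0,1,97} is 1

  ls <- compute_location_scale(c(7, 7, 7, 7), "mean_sd")
  expect_equal(ls$location, 7)
  expect_equal(ls$scale, 0)

  expect_error(compute_location_scale(1), class = "disen_invalid_input")
})

test_that("log-sigmoid mapping hits its fixed points and stays in (0,1)", {
  ls <- compute_location_scale(c(0, 2), "mean_sd")  # location 1, scale sqrt(2)
  expect_equal(map_logsig(ls$location, ls), 0.5)
  expect_equal(map_logsig(ls$location + ls$scale, ls), 1 / (1 + exp(-1)))
  y <- map_logsig(seq(-50, 50, length.out = 101), ls)
  expect_true(all(y > 0 & y < 1))
  expect_true(all(diff(y) > 0))  # monotone
  ls$scale <- 0
  expect_error(map_logsig(1, ls), class = "disen_degenerate_scale")
})

test_that("class allocation rounds half away from zero and is monotone", {
  expect_identical(assign_classes(0.01, 6), 1L)
  expect_identical(assign_classes(0.5, 6), 4L)   # round(3.5) -> 4, half away
  expect_identical(assign_classes(0.99, 6), 6L)
  y <- sort(runif(200, 1e-6, 1 - 1e-6))
  u <- assign_classes(y, 6)
  expect_true(all(diff(u) >= 0))
  expect_true(all(u >= 1 & u <= 6))
  expect_error(assign_classes(c(0.5, 1.2), 6), class = "disen_invalid_input")
})

test_that("pattern extraction matches direct enumeration on the spec'd cases", {
  d1 <- extract_patterns(c(1, 2, 3, 2, 1), m = 2, d = 1)
  expect_identical(d1$n_vectors, 4L)
  expect_identical(d1$counts[sort(names(d1$counts))],
                   c("1,2" = 1L, "2,1" = 1L, "2,3" = 1L, "3,2" = 1L))

  d2 <- extract_patterns(c(5, 5, 5, 5), m = 2, d = 1)
  expect_identical(d2$counts, c("5,5" = 3L))

  d3 <- extract_patterns(1:4, m = 2, d = 2)
  expect_identical(d3$counts[sort(names(d3$counts))], c("1,3" = 1L, "2,4" = 1L))

  expect_error(extract_patterns(1:2, m = 3, d = 1), class = "disen_too_short")
})

test_that("pattern extraction agrees exactly with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(5:60, 1)
    cc <- sample(2:4, 1)
    m <- sample(1:3, 1)
    d <- sample(1:2, 1)
    if (n < (m - 1) * d + 1) next
    u <- sample.int(cc, n, replace = TRUE)
    got <- extract_patterns(u, m, d)
    want <- oracle_patterns(u, m, d)
    expect_identical(got$counts[sort(names(got$counts))], want)
    expect_identical(got$n_vectors, n - (m - 1L) * d)
  }
})

test_that("relative frequencies sum to one within 1e-12", {
  set.seed(7)
  for (rep in 1:20) {
    u <- sample.int(6, sample(10:300, 1), replace = TRUE)
    p <- pattern_frequencies(extract_patterns(u, 2, 1))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("Shannon entropy hits its analytic values", {
  single <- extract_patterns(rep(3L, 10), 2, 1)
  expect_equal(shannon_entropy(single), 0)

  four <- list(counts = c(a = 5L, b = 5L, c = 5L, d = 5L), n_vectors = 20L)
  expect_equal(shannon_entropy(four), log(4))

  uniform36 <- list(counts = stats::setNames(rep(1L, 36), 1:36), n_vectors = 36L)
  expect_equal(shannon_entropy(uniform36), log(36))

  expect_error(shannon_entropy(list(counts = integer(0), n_vectors = 0L)),
               class = "disen_invalid_input")
})

test_that("dispersion entropy: degenerate, missing, range and Gaussian oracle", {
  res <- dispersion_entropy(rep(3, 100))
  expect_equal(res$value, 0)
  expect_true(res$degenerate)
  expect_identical(res$n_effective, 100L)

  seg <- signal_segment(c(1, 2, NA, 4))
  expect_error(dispersion_entropy(seg), class = "disen_missing_samples")

  set.seed(11)
  for (rep in 1:10) {
    r <- dispersion_entropy(rnorm(sample(50:500, 1)))
    expect_gte(r$value, 0)
    expect_lte(r$value, 2 * log(6))
    expect_equal(r$normalized, r$value / (2 * log(6)))
  }

  # iid Gaussian at large N converges to the closed-form class-occupancy
  # entropy of the logistic-mapped standard normal
  set.seed(101)
  big <- dispersion_entropy(rnorm(1e5))
  expect_equal(big$value, gauss_logsig_disen(6, 2), tolerance = 0.005)
})

test_that("dispersion entropy is invariant under positive affine maps", {
  set.seed(5)
  for (rep in 1:10) {
    x <- dyadic_series(300)
    a <- 2^sample(-2:4, 1)
    b <- sample(-5:5, 1)
    expect_identical(dispersion_entropy(a * x + b)$value,
                     dispersion_entropy(x)$value)
  }
  # generic (non-dyadic) coefficients agree to numerical precision
  x <- rnorm(500)
  expect_equal(dispersion_entropy(pi * x + exp(1))$value,
               dispersion_entropy(x)$value, tolerance = 1e-10)
})

test_that("signal segments validate their inputs", {
  expect_error(signal_segment(numeric(0)), class = "disen_invalid_input")
  expect_error(signal_segment(c(1, Inf, 2)), class = "disen_invalid_input")
  expect_error(signal_segment(1:3, c(TRUE, FALSE)), class = "disen_invalid_input")
  seg <- signal_segment(c(1, Inf, 2), c(FALSE, TRUE, FALSE))  # masked Inf is fine
  expect_identical(seg$missing, c(FALSE, TRUE, FALSE))
  expect_identical(length(seg), 3L)
})

test_that("parameter validation rejects out-of-range configurations", {
  expect_error(disen_params(m = 0), class = "disen_invalid_input")
  expect_error(disen_params(c = 1), class = "disen_invalid_input")
  expect_error(disen_params(d = 0), class = "disen_invalid_input")
  expect_error(disen_params(cutoff = -1), class = "disen_invalid_input")
  p <- disen_params()
  expect_identical(c(p$m, p$c, p$d), c(2L, 6L, 1L))
  expect_equal(p$cutoff, 0.7)
  expect_identical(p$mapping, "logsig")
})
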