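uniform_psd <- function(B = 70) psdn(1:B, rep(1 / B, B), normalize = FALSE)

point_mass_psd <- function(at = 10, B = 70) {
  v <- rep(0, B); v[at] <- 1
  psdn(1:B, v, normalize = FALSE)
}

test_that("psdn constructor enforces its invariants", {
  expect_error(psdn(1:5, c(1, 1, -1, 1, 1)), "non-negative")
  expect_error(psdn(c(1, 2, 4, 8), rep(1, 4)), "uniform")
  expect_error(psdn(1:3, rep(0, 3)), "degenerate")
  p <- psdn(1:10, runif(10))
  expect_equal(sum(p$values), 1, tolerance = 1e-12)
})

test_that("compute_psdn concentrates a pure tone and normalizes", {
  fs <- 200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  p <- compute_psdn(sin(2 * pi * 10 * t), fs)
  expect_equal(sum(p$values), 1, tolerance = 1e-9)
  expect_gte(sum(p$values[abs(p$freqs - 10) <= 1]), 0.95)
  expect_true(all(p$freqs >= 1 & p$freqs <= 70))
  expect_error(compute_psdn(rep(0, 1000), fs), "all-zero")
  expect_error(compute_psdn(rnorm(100), fs), "2 s")
})

test_that("white-noise PSDn is flat (Monte-Carlo calibrated flatness test)", {
  fs <- 200
  flatness <- function(seed) {
    reps <- withr::with_seed(seed, vapply(1:30, function(i)
      compute_psdn(rnorm(fs * 5), fs)$values, numeric(70)))
    avg <- rowMeans(reps)
    sum((avg - mean(avg))^2) / mean(avg)^2
  }
  obs <- flatness(11)
  null <- vapply(101:160, flatness, 0)  # same procedure, independent seeds
  p <- (1 + sum(null >= obs)) / (length(null) + 1)
  expect_gt(p, 0.01)
  avg <- rowMeans(withr::with_seed(11, vapply(1:30, function(i)
    compute_psdn(rnorm(fs * 5), fs)$values, numeric(70))))
  expect_lt(max(avg) / min(avg), 1.5)
})

test_that("relative power sums bands to one and contains tones", {
  p <- uniform_psd()
  expect_equal(relative_power(p, 1, 70), 1.0)
  expect_lt(abs(relative_power(p, 1, 4) - 3 / 69), 1 / 70 + 1e-9)
  bands <- eeg_bands()
  total <- sum(vapply(bands, function(b) relative_power(p, b[1], b[2]), 0))
  expect_equal(total, 1, tolerance = 1e-9)
  fs <- 200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  ptone <- compute_psdn(sin(2 * pi * 10 * t), fs)
  expect_gte(relative_power(ptone, 8, 13), 0.95)
  expect_error(relative_power(p, 0.2, 5), "outside")
  expect_error(relative_power(p, 13, 8), "f1 < f2")
})

test_that("band relative powers always tile the grid", {
  bands <- eeg_bands()
  for (seed in 1:5) {
    p <- psdn(1:70, withr::with_seed(seed, runif(70)))
    total <- sum(vapply(bands, function(b) relative_power(p, b[1], b[2]), 0))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("median frequency follows the cumulative-mass rule", {
  fs <- 200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  expect_lte(abs(median_frequency(compute_psdn(sin(2 * pi * 10 * t), fs)) - 10), 1)
  expect_lte(abs(median_frequency(uniform_psd()) - 35.5), 1)
  # two equal tones: cumulative reaches 0.5 at the first tone under >=
  v <- rep(0, 70); v[6] <- 0.5; v[20] <- 0.5
  expect_equal(median_frequency(psdn(1:70, v, normalize = FALSE)), 6)
})

test_that("median frequency is monotone under upward mass shifts", {
  base <- withr::with_seed(2, runif(70))
  p0 <- psdn(1:70, base)
  for (k in c(5, 20, 40)) {
    shifted <- c(rep(0, k), base[1:(70 - k)])  # move all mass up k bins
    p1 <- psdn(1:70, shifted + 1e-12)
    expect_gte(median_frequency(p1), median_frequency(p0))
  }
})

test_that("individual alpha frequency tracks the alpha band only", {
  fs <- 200
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  expect_lte(abs(individual_alpha_frequency(compute_psdn(sin(2 * pi * 10 * t), fs)) - 10), 1)
  x <- sin(2 * pi * 9 * t) + 3 * sin(2 * pi * 40 * t)
  expect_lte(abs(individual_alpha_frequency(compute_psdn(x, fs)) - 9), 1)
  expect_error(individual_alpha_frequency(point_mass_psd(40)), "no spectral mass")
})

test_that("spectral entropy hits its closed-form anchors", {
  expect_equal(spectral_entropy(uniform_psd()), 1.0, tolerance = 1e-12)
  expect_equal(spectral_entropy(point_mass_psd()), 0.0)
  v <- rep(0, 70); v[c(3, 9)] <- 0.5
  expect_equal(spectral_entropy(psdn(1:70, v, normalize = FALSE)),
               log(2) / log(70), tolerance = 1e-12)
})

test_that("spectral entropy is permutation invariant and bounded", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, runif(70))
    se1 <- spectral_entropy(psdn(1:70, v))
    se2 <- spectral_entropy(psdn(1:70, withr::with_seed(seed + 10, sample(v))))
    expect_equal(se1, se2, tolerance = 1e-12)
    expect_gte(se1, 0); expect_lte(se1, 1)
  }
})
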