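# Multi-tau lag scheme, g2 estimation, and the timestamp front end.

test_that("default lag scheme reproduces the time-tagger spacing", {
  lags <- multi_tau_lags(multi_tau_scheme())
  b1 <- lags[lags$block == 1, ]
  expect_equal(nrow(b1), 16L)
  expect_equal(diff(b1$lag_time), rep(6.145e-9, 15))
  expect_equal(unique(lags$bin_width[lags$block == 2]), 3 * 6.145e-9)
  expect_equal(unique(lags$bin_width[lags$block == 3]), 9 * 6.145e-9)
  expect_true(all(diff(lags$lag_time) > 0))
  # within every block, consecutive lags differ by the block's bin width
  for (b in unique(lags$block)) {
    blk <- lags[lags$block == b, ]
    expect_equal(diff(blk$lag_time), rep(blk$bin_width[1], nrow(blk) - 1))
  }
})

test_that("degenerate one-lag-per-block scheme doubles dyadically", {
  lags <- multi_tau_lags(multi_tau_scheme(base_bin = 1e-6, lags_per_block = 1,
                                          widening_factor = 2, n_blocks = 6))
  expect_equal(lags$lag_time, 1e-6 * c(1, 2, 4, 8, 16, 32))
})

test_that("constant count streams have g2 identically 1", {
  s <- photon_count_series(rep(5, 5000), 1e-6)
  cv <- autocorrelate(s, multi_tau_scheme(base_bin = 1e-6, n_blocks = 3))
  expect_equal(cv$g2, rep(1, nrow(cv)))
})

test_that("independent Poisson counts decorrelate to g2 = 1 within 3 SE", {
  set.seed(11)
  n <- 1e6; mu <- 2
  s <- photon_count_series(rpois(n, mu), 1e-6)
  sch <- multi_tau_scheme(base_bin = 1e-6, n_blocks = 4)
  cv <- autocorrelate(s, sch)
  # shot-noise-only stream: per-lag SE of the estimator ~ sd(I)^2/mean(I)^2/sqrt(n_b)
  n_eff <- n / 3^(cv$block - 1)
  se <- (1 / mu) / sqrt(n_eff)  # var/mean^2 = 1/mu for Poisson
  expect_true(all(abs(cv$g2 - 1) < 3 * se))
})

test_that("multi-tau estimator equals the direct-sum brute force exactly", {
  set.seed(21)
  sch <- multi_tau_scheme(base_bin = 1e-6, n_blocks = 3)
  for (counts in list(rpois(4000, 3),
                      rbinom(6000, 1, 0.05),
                      rep(c(0, 0, 7), 2000))) {
    s <- photon_count_series(counts, 1e-6)
    cv <- autocorrelate(s, sch)
    expect_equal(cv$g2, brute_force_multitau(counts, sch), tolerance = 1e-14)
  }
})

test_that("plain (asymmetric) normalization reduces to the squared mean", {
  set.seed(22)
  counts <- rpois(3000, 4)
  s <- photon_count_series(counts, 1e-6)
  sch <- multi_tau_scheme(base_bin = 1e-6, n_blocks = 1)
  cv <- autocorrelate(s, sch, symmetric = FALSE)
  k <- 5
  n <- length(counts)
  expect_equal(cv$g2[k],
               mean(counts[1:(n - k)] * counts[(k + 1):n]) / mean(counts)^2)
})

test_that("the estimator is shift invariant", {
  set.seed(31)
  counts <- rpois(5000, 3)
  sch <- multi_tau_scheme(base_bin = 1e-6, n_blocks = 2)
  cv1 <- autocorrelate(photon_count_series(counts, 1e-6), sch)
  # prepend a constant prefix, then discard it again: unchanged estimate,
  # regardless of the recorded start time
  with_prefix <- c(rep(3L, 999), counts)
  trimmed <- with_prefix[-seq_len(999)]
  cv2 <- autocorrelate(photon_count_series(trimmed, 1e-6, start_time = 99),
                       sch)
  expect_equal(cv1$g2, cv2$g2)
})

test_that("degenerate and too-short inputs raise informative errors", {
  sch <- multi_tau_scheme(base_bin = 1e-6, n_blocks = 3)
  expect_error(autocorrelate(photon_count_series(rep(0, 5000), 1e-6), sch),
               "all-zero")
  expect_error(autocorrelate(photon_count_series(rpois(50, 2), 1e-6), sch),
               "too short")
  expect_error(autocorrelate(photon_count_series(rpois(5000, 2), 2e-6), sch),
               "base_bin")
  expect_error(photon_count_series(c(1, -1, 2), 1e-6), "non-negative")
})

test_that("timestamp histogramming places events in the right bins", {
  s <- timestamps_to_counts(numeric(0), 1e-6, 1e-5)
  expect_equal(s$counts, rep(0L, 10))
  s2 <- timestamps_to_counts(c(0, 2.5e-6), 1e-6, 5e-6)
  expect_equal(s2$counts, c(1, 0, 1, 0, 0))
  expect_error(timestamps_to_counts(c(2e-6, 1e-6), 1e-6, 1e-5), "sorted")
})

test_that("uniform random timestamps hit the expected mean count", {
  set.seed(41)
  n <- 1e5; dur <- 1
  ts <- sort(runif(n, 0, dur))
  s <- timestamps_to_counts(ts, 1e-4, dur)
  expect_equal(sum(s$counts), n)
  expect_equal(mean(s$counts), n * 1e-4, tolerance = 0.01)
})

test_that("timestamp files round-trip through text and raw tick formats", {
  ts <- sort(runif(500, 0, 1e-3))
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(ts, digits = 17, scientific = TRUE), txt)
  expect_equal(read_timestamps(txt), ts, tolerance = 1e-12)

  tick <- 6.145e-9
  ticks <- sort(sample(0:1e6, 300))
  bin <- withr::local_tempfile(fileext = ".bin")
  con <- file(bin, "wb")
  for (v in ticks) {
    writeBin(as.integer(v %% 2^31), con, size = 4, endian = "little")
    writeBin(0L, con, size = 4, endian = "little")
  }
  close(con)
  expect_equal(read_timestamps(bin, tick = tick), ticks * tick)
})
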