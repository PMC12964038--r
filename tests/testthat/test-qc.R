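test_that("framewise displacement follows the translation+rotation formula", {
  m <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))
  # constant offset, no increments
  m1 <- matrix(rep(c(1, 2, 3, 0.01, 0.02, 0.03), each = 10), 10, 6)
  expect_equal(framewise_displacement(m1), rep(0, 10))
  # single 0.1 mm translation step
  m2 <- matrix(0, 10, 6); m2[5:10, 2] <- 0.1
  expect_equal(framewise_displacement(m2), c(rep(0, 4), 0.1, rep(0, 5)))
  # single 0.002 rad rotation step on a 50 mm sphere = 0.1 mm
  m3 <- matrix(0, 10, 6); m3[5:10, 5] <- 0.002
  expect_equal(framewise_displacement(m3, head_radius = 50),
               c(rep(0, 4), 0.1, rep(0, 5)))
  expect_error(framewise_displacement(matrix(0, 10, 5)), "6 motion columns")
})

test_that("exclusion rules are strict inequalities on both criteria", {
  r1 <- qc_exclude(rep(0.31, 100))
  expect_true(r1$excluded)
  expect_equal(r1$reason, "mean")
  # 21% of frames large but mean small
  fd2 <- c(rep(0.4, 21), rep(0.02, 79))
  r2 <- qc_exclude(fd2)
  expect_true(r2$excluded)
  expect_equal(r2$reason, "proportion")
  # exactly on both thresholds: retained
  fd3 <- c(rep(0.45, 20), rep(0.2625, 80))   # mean 0.30, prop 0.20
  expect_equal(mean(fd3), 0.30)
  expect_equal(mean(fd3 > 0.30), 0.20)
  expect_false(qc_exclude(fd3)$excluded)
})

test_that("exclusion matches a brute-force restatement of the rules", {
  set.seed(10)
  for (i in 1:50) {
    fd <- stats::runif(sample(50:300, 1), 0, 0.6)
    r <- qc_exclude(fd)
    brute <- (sum(fd) / length(fd) > 0.30) ||
      (sum(fd > 0.30) / length(fd) > 0.20)
    expect_identical(r$excluded, brute)
    expect_equal(r$prop_large, mean(fd > 0.30))
  }
})

test_that("the PPG band-pass removes DC and RF, keeps the cardiac band", {
  fs <- 500
  tt <- seq_len(60 * fs) / fs
  expect_lt(max(abs(bandpass_ppg(rep(2, length(tt)), fs))), 0.02)
  amp_at <- function(x, f0) {
    n <- length(x)
    2 * abs(sum(x * exp(-2i * pi * f0 * seq_len(n) / fs))) / n
  }
  y10 <- bandpass_ppg(sin(2 * pi * 10 * tt), fs)
  expect_lt(amp_at(y10, 10), 10^(-20 / 20))         # >= 20 dB down
  y1 <- bandpass_ppg(sin(2 * pi * 1 * tt), fs)
  expect_equal(amp_at(y1, 1), 1, tolerance = 0.05)  # in-band flat
  expect_error(bandpass_ppg(rnorm(100), fs = 5), "too low")
})

test_that("beat detection ignores the dicrotic notch and counts beats", {
  x <- simulate_ppg(60, duration = 600, fs = 500, hr_jitter_sd = 0,
                    seed = 1)
  beats <- detect_beats(bandpass_ppg(x, 500), 500)
  expect_equal(length(beats), 600, tolerance = 2)
  # beat count is unchanged as the dicrotic bump grows
  counts <- vapply(c(0.1, 0.35, 0.5), function(dic) {
    xd <- simulate_ppg(70, duration = 120, fs = 500, dicrotic = dic,
                       seed = 3)
    length(detect_beats(bandpass_ppg(xd, 500), 500))
  }, numeric(1))
  # no double counting as the bump grows (allow one edge beat either way)
  expect_lte(abs(counts[2] - counts[1]), 1)
  expect_lte(abs(counts[3] - counts[1]), 1)
})

test_that("mean heart rate comes from the mean inter-beat interval", {
  expect_equal(as.numeric(mean_hr(0:600)), 60)
  # alternating 0.8/1.2 s intervals still average to 60 bpm
  ibis <- rep(c(0.8, 1.2), 50)
  expect_equal(as.numeric(mean_hr(cumsum(c(0, ibis)))), 60)
  # invariant under a uniform time shift
  b <- cumsum(c(0, rep(0.75, 80)))
  expect_equal(as.numeric(mean_hr(b)), as.numeric(mean_hr(b + 123.4)))
  expect_error(mean_hr(c(1)), "at least 2")
})

test_that("the full PPG pipeline recovers generator heart rates", {
  for (hr in c(50, 65.06, 95)) {
    x <- simulate_ppg(hr, duration = 600, fs = 500, seed = round(hr * 10))
    est <- ppg_to_hr(x, 500)$mean_hr
    expect_lt(abs(est - hr), 0.5)
  }
})
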