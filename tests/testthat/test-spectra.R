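test_that("white noise fits as an empty MAR model", {
  set.seed(1)
  T_len <- 4000
  y <- matrix(rnorm(T_len * 2), ncol = 2)
  m <- fit_mar(y, order = 8, tr = 1)
  for (k in seq_len(8)) {
    expect_true(all(abs(m$coeffs[[k]]) < 3 / sqrt(T_len)))
  }
  expect_equal(m$innovation_cov, stats::cov(y), tolerance = 0.05)
  expect_true(m$stationary)
})

test_that("a known AR(1) process is recovered", {
  set.seed(2)
  y <- as.matrix(arima.sim(list(ar = 0.5), 10000))
  m <- fit_mar(y, order = 3, tr = 1)
  expect_equal(m$coeffs[[1]][1, 1], 0.5, tolerance = 0.05)
})

test_that("independent channels stay uncoupled in the fit", {
  set.seed(3)
  y <- cbind(as.numeric(arima.sim(list(ar = 0.4), 6000)),
             as.numeric(arima.sim(list(ar = 0.6), 6000)))
  m <- fit_mar(y, order = 4, tr = 1)
  for (k in 1:4) {
    expect_lt(max(abs(m$coeffs[[k]][row(m$coeffs[[k]]) !=
                                      col(m$coeffs[[k]])])), 0.05)
  }
  expect_lt(abs(m$innovation_cov[1, 2]) /
              sqrt(prod(diag(m$innovation_cov))), 0.05)
})

test_that("MAR spectrum matches analytic forms", {
  # white noise: flat at delta * Sigma
  delta <- 0.961
  mar_white <- structure(
    list(order = 1, coeffs = list(matrix(0, 2, 2)),
         innovation_cov = diag(2), sample_interval = delta,
         stationary = TRUE, labels = c("a", "b")),
    class = "mar_model")
  cs <- mar_to_csd(mar_white, default_freq_grid())
  for (k in seq_along(cs$freqs)) {
    expect_equal(matrix(cs$values[k, , ], 2), delta * diag(2) + 0i,
                 tolerance = 1e-12)
  }
  # AR(1): S(f) = delta / |1 - a e^{-i 2 pi f delta}|^2
  mar1 <- structure(
    list(order = 1, coeffs = list(matrix(0.5, 1, 1)),
         innovation_cov = matrix(1, 1, 1), sample_interval = 1,
         stationary = TRUE, labels = "a"),
    class = "mar_model")
  f <- c(0.05, 0.2, 0.4)
  S <- mar_to_csd(mar1, f)$values[, 1, 1]
  expect_equal(Re(S), 1 / Mod(1 - 0.5 * exp(-2i * pi * f))^2,
               tolerance = 1e-10)
  expect_equal(Im(S), c(0, 0, 0), tolerance = 1e-12)
})

test_that("integrated MAR spectrum returns the process variance (Parseval)", {
  set.seed(4)
  y <- as.matrix(arima.sim(list(ar = c(0.4, 0.2)), 8192))
  m <- fit_mar(y, order = 8, tr = 1)
  fg <- seq(0.0005, 0.4995, length.out = 500)
  S <- Re(mar_to_csd(m, fg)$values[, 1, 1])
  v_spec <- 2 * sum(S) * (fg[2] - fg[1])
  expect_equal(v_spec, stats::var(as.numeric(y)), tolerance = 0.02)
})

test_that("Welch estimate localizes a sinusoid and matches the MAR view", {
  tt <- seq_len(4096)
  y <- cbind(sin(2 * pi * 0.1 * tt) + rnorm(4096, 0, 0.3))
  w <- welch_csd(y, tr = 1, window = 256)
  f_peak <- w$freqs[which.max(Re(w$values[, 1, 1]))]
  expect_lt(abs(f_peak - 0.1), 1 / 256)

  set.seed(5)
  y2 <- as.matrix(arima.sim(list(ar = c(0.4, 0.2)), 8192))
  w2 <- welch_csd(y2, tr = 1, window = 256)
  band <- w2$freqs >= 0.01 & w2$freqs <= 0.25
  m2 <- mar_to_csd(fit_mar(y2, order = 8, tr = 1), w2$freqs[band])
  rel <- abs(Re(w2$values[band, 1, 1]) - Re(m2$values[, 1, 1])) /
    Re(m2$values[, 1, 1])
  expect_lt(stats::median(rel), 0.15)
})

test_that("white-noise channels show no spurious coherence", {
  set.seed(6)
  y <- matrix(rnorm(4096 * 2), ncol = 2)
  w <- welch_csd(y, tr = 1, window = 128)
  coh <- Mod(w$values[, 1, 2])^2 /
    (Re(w$values[, 1, 1]) * Re(w$values[, 2, 2]))
  expect_true(all(coh < 0.2))
})

test_that("estimated spectra honor the Hermitian invariants", {
  set.seed(7)
  for (rep_i in 1:4) {
    conn <- make_connectivity(3, 0.2, seed = rep_i + 30)
    x <- simulate_neural(conn, duration = 600, dt = 0.1, fluct_sd = 1,
                         seed = rep_i)
    m <- fit_mar(x, order = 8, tr = 0.1)
    cs <- mar_to_csd(m, default_freq_grid(16, 0.02, 2))
    expect_true(is_hermitian_csd(cs))
    w <- welch_csd(x, tr = 0.1, window = 60)
    expect_true(is_hermitian_csd(w))
  }
})

test_that("degenerate regressions are rejected with a clear message", {
  y <- cbind(rnorm(100), rnorm(100))
  y <- cbind(y, y[, 1])                      # duplicated channel
  expect_error(fit_mar(y, order = 2, tr = 1), "rank-deficient")
  expect_error(welch_csd(y[, 1:2], tr = 1, window = 90), "2 segments")
  mar1 <- fit_mar(y[, 1:2], order = 2, tr = 1)
  expect_error(mar_to_csd(mar1, c(0.1, 0.6)), "freqs")
})
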