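test_that("identity-hemodynamics spectra equal the OU closed form", {
  f <- default_freq_grid()
  for (seed in 1:4) {
    n <- sample(2:4, 1)
    conn <- make_connectivity(n, 0.2, seed = seed + 50)
    A <- effective_matrix(conn)
    cs <- generative_csd(conn, f, hemo = NULL)
    worst <- 0
    for (k in seq_along(f)) {
      Tm <- solve(2i * pi * f[k] * diag(n) - A)
      worst <- max(worst, max(Mod(matrix(cs$values[k, , ], n) -
                                    Tm %*% Conj(t(Tm)))))
    }
    expect_lt(worst, 1e-8)
  }
})

test_that("single-node spectrum matches the scalar closed form", {
  conn <- dcm_connectivity(matrix(0, 1, 1))
  f <- default_freq_grid()
  cs <- generative_csd(conn, f, hemo = NULL)
  expect_equal(Re(cs$values[, 1, 1]), 1 / ((2 * pi * f)^2 + 0.25),
               tolerance = 1e-10)
})

test_that("self log-scaling of zero pins the diagonal at -0.5 Hz", {
  pr <- spdcm_priors(3)
  mod <- canheart:::theta_to_model(pr$mean, pr)
  expect_equal(diag(effective_matrix(mod$conn)), rep(-0.5, 3),
               ignore_attr = TRUE)
})

test_that("generated spectra are Hermitian with non-negative diagonals", {
  f <- default_freq_grid()
  set.seed(8)
  for (rep_i in 1:5) {
    repeat {
      conn <- make_connectivity(3, 0.25, seed = sample.int(1e6, 1))
      conn$theta_self <- rnorm(3, 0, 0.2)
      if (is_stable(effective_matrix(conn))) break
    }
    cs <- generative_csd(conn, f, hemo = hemo_params(3),
                         noise = noise_params(ge0 = 0.5))
    expect_true(is_hermitian_csd(cs))
  }
})

test_that("the hemodynamic kernel is a low-pass filter", {
  K <- hemodynamic_kernel(hemo_params(2, transit = c(0, 0.2)),
                          c(0.01, 0.25))
  expect_true(all(Mod(K[2, ]) < Mod(K[1, ])))
})

test_that("the linearized kernel reproduces the nonlinear response for
          small inputs", {
  set.seed(5)
  dt <- 0.05
  n <- 8000
  x <- as.numeric(stats::filter(rnorm(n, 0, 0.003), 0.9,
                                method = "recursive"))
  xs <- matrix(x, ncol = 1)
  attr(xs, "dt") <- dt
  y_nl <- simulate_bold(xs, tr = dt, obs_snr = Inf)
  # linear prediction through the frequency-domain kernel
  fr <- (seq_len(n) - 1) / (n * dt)
  Kf <- hemodynamic_kernel(hemo_params(1), c(1e-9, fr[2:(n / 2)]))
  Kfull <- complex(real = rep(0, n))
  Kfull[1] <- Kf[1]
  Kfull[2:(n / 2)] <- Kf[-1, 1]
  Kfull[(n / 2 + 2):n] <- Conj(Kf[(n / 2):2, 1])
  Kfull[n / 2 + 1] <- Re(Kf[n / 2, 1])
  y_lin <- Re(stats::fft(stats::fft(xs[, 1]) * Kfull, inverse = TRUE)) / n
  i0 <- 500:n
  rel <- sqrt(mean((y_nl[i0] - y_lin[i0])^2)) / stats::sd(y_nl[i0])
  expect_lt(rel, 0.05)
})

test_that("explained variance behaves at its fixed points", {
  f <- default_freq_grid(8)
  set.seed(9)
  vals <- array(complex(real = 0), c(8, 2, 2))
  for (k in 1:8) {
    M <- matrix(rnorm(4) + 1i * rnorm(4), 2)
    S <- M %*% Conj(t(M))
    vals[k, , ] <- S
  }
  obs <- cross_spectrum(f, vals)
  expect_equal(explained_variance(obs, obs), 1)
  null_pred <- obs
  null_pred$values[] <- 0 + 0i
  expect_equal(explained_variance(obs, null_pred), 0)
  bad <- obs
  bad$freqs <- f + 0.001
  expect_error(explained_variance(obs, bad), "mismatch")
})
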