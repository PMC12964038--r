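test_that("inverting the prior-predictive spectrum returns the prior", {
  f <- default_freq_grid()
  pr <- spdcm_priors(3, f)
  obs <- canheart:::predict_features(pr$mean, pr, f)$csd
  fit <- spdcm_invert(obs, pr)
  expect_true(all(abs(fit$Ep - pr$mean) < 0.05))
  expect_gt(fit$explained_variance, 0.99)
  expect_true(all(diff(fit$trace) >= 0))
})

test_that("a noiseless model spectrum is inverted back to its parameters", {
  f <- default_freq_grid()
  pr <- spdcm_priors(3, f)
  set.seed(4)
  th <- matrix(0, 3, 3)
  off <- which(!diag(3))
  th[off] <- sample(c(-0.3, 0.3), 6, TRUE)
  theta_true <- pr$mean
  theta_true[1:6] <- th[off]
  obs <- canheart:::predict_features(theta_true, pr, f)$csd
  fit <- spdcm_invert(obs, pr, max_iter = 256)
  expect_true(all(abs(fit$Ep[1:6] - th[off]) < 0.05))
  expect_gt(fit$explained_variance, 0.99)
  # free-energy trace is monotone over accepted steps
  expect_true(all(diff(fit$trace) >= 0))
  # posterior covariance is symmetric positive-semidefinite
  expect_equal(fit$Cp, t(fit$Cp))
  expect_gte(min(eigen(fit$Cp, only.values = TRUE)$values), -1e-10)
})

test_that("couplings of simulated subjects are recovered from their BOLD", {
  res <- lapply(c(2, 3), function(seed) {
    s <- sim_subject(seed)
    if (is.null(s)) return(NULL)
    fit <- spdcm(s$bold, tr = 0.961)
    expect_true(all(diff(fit$trace) >= 0))
    A_hat <- effective_matrix(as_connectivity(fit))
    cbind(s$true_offdiag, A_hat[which(!diag(3))])
  })
  res <- do.call(rbind, Filter(Negate(is.null), res))
  expect_gt(stats::cor(res[, 1], res[, 2]), 0.6)
})

test_that("more data means a tighter posterior", {
  s_long <- sim_subject(12, n_vol = 2000)
  s_short <- sim_subject(12, n_vol = 200)
  f_long <- spdcm(s_long$bold, tr = 0.961, max_iter = 48)
  f_short <- spdcm(s_short$bold, tr = 0.961, max_iter = 48)
  idx <- 1:6    # coupling block
  expect_lt(sum(diag(f_long$Cp)[idx]), sum(diag(f_short$Cp)[idx]))
})

test_that("the explained-variance screen applies the 10% rule inclusively", {
  mk <- function(ev, conv = TRUE) {
    list(explained_variance = ev, converged = conv)
  }
  rep <- screen_subjects(list(a = mk(0.85), b = mk(0.92), c = mk(0.09),
                              d = mk(0.10), e = mk(0.5, conv = FALSE)))
  expect_equal(rep$included, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(rep$reason[3], "explained_variance")
  expect_equal(rep$reason[5], "nonconvergence")
  expect_equal(attr(rep, "n_included"), 3)
  expect_equal(attr(rep, "n_excluded"), 2)
})

test_that("fit accessors expose the posterior consistently", {
  s <- sim_subject(2, n_vol = 300)
  fit <- spdcm(s$bold, tr = 0.961, max_iter = 24)
  expect_s3_class(fitted(fit), "cross_spectrum")
  expect_named(coef(fit))
  expect_equal(unname(coef(fit)[1:6]),
               unname(fit$Ep[1:6]))
  r <- residuals(fit)
  expect_equal(r$values, fit$observed$values - fit$predicted$values)
  conn <- as_connectivity(fit)
  expect_s3_class(conn, "dcm_connectivity")
  expect_true(is_stable(effective_matrix(conn)))
  expect_output(print(fit), "explained variance")
})
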