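test_that("design matrices follow the centering conventions", {
  cov2 <- data.frame(id = c("a", "b"), group = c("AN", "HC"),
                     hr_bpm = c(65.06, 74.10))
  Xg <- build_design(cov2, "group", patient_label = "AN")
  expect_equal(Xg[, "mean"], c(1, 1), ignore_attr = TRUE)
  # balanced groups: centered +1/-1 coding is unchanged
  expect_equal(Xg[, "group"], c(1, -1), ignore_attr = TRUE)
  Xh <- build_design(cov2, "hr")
  expect_equal(Xh[, "hr"], c(-4.52, 4.52), ignore_attr = TRUE)

  # unbalanced groups still center to zero; raw coding kept in metadata
  cov3 <- data.frame(id = sprintf("s%d", 1:66),
                     group = rep(c("AN", "HC"), c(26, 40)),
                     hr_bpm = rnorm(66, 70, 10))
  X3 <- build_design(cov3, c("group", "hr", "group_x_hr"),
                     patient_label = "AN")
  expect_lt(max(abs(colMeans(X3[, -1]))), 1e-10)
  expect_equal(attr(X3, "raw_coding")$group,
               ifelse(cov3$group == "AN", 1, -1))
  # interaction column is the re-centered product of centered main effects
  prod_c <- X3[, "group"] * X3[, "hr"]
  expect_equal(X3[, "group_x_hr"], prod_c - mean(prod_c),
               ignore_attr = TRUE)
})

test_that("missing covariates and rank deficiency are refused", {
  cov_bad <- data.frame(id = c("a", "b", "c"), group = c("AN", "HC", "HC"),
                        hr_bpm = c(65, NA, 70))
  expect_error(build_design(cov_bad, "hr"), "b")
  cov_rank <- data.frame(id = c("a", "b"), group = c("AN", "AN"))
  expect_error(build_design(cov_rank, "group"), "rank deficient")
})

test_that("a single-subject hierarchy returns that subject, shrunk", {
  set.seed(1)
  pn <- param_names_3()
  post <- make_posterior(c(rep(0.2, 6), rep(0, 3)), pn, paste0("R", 1:3),
                         sd = 0.01)
  X <- build_design(data.frame(id = "a", group = "AN"))
  fit <- peb_fit(list(post), X)
  expect_true(all(abs(fit$Ep["mean", 1:6] - post$Ep[1:6]) < 0.06))
  expect_true(all(abs(fit$Ep["mean", 1:6]) <= abs(post$Ep[1:6]) + 1e-6))
})

test_that("planted group effects are detected and ranked first", {
  found <- 0
  for (seed in 1:3) {
    coh <- posterior_cohort(seed, group_effect = 0.2, effect_idx = 1:3)
    X <- build_design(coh$covariates, "group", patient_label = "AN")
    fit <- peb_fit(coh$posteriors, X)
    ranks <- order(-abs(fit$Ep["group", 1:6]))
    expect_true(all(1:3 %in% ranks[1:5]))
    found <- found + all(fit$PP["group", 1:3] > 0.99)
  }
  expect_gte(found, 2)
})

test_that("a pure-noise regressor stays near zero", {
  maxes <- vapply(1:5, function(seed) {
    coh <- posterior_cohort(seed, group_effect = 0)
    cv <- coh$covariates
    set.seed(seed + 500)
    cv$hr_bpm <- rnorm(nrow(cv), 70, 10)   # noise covariate
    X <- build_design(cv, "hr")
    fit <- peb_fit(coh$posteriors, X)
    max(abs(fit$Ep["hr", ]))
  }, numeric(1))
  expect_lt(mean(maxes), 0.05)
})

test_that("posterior probability is calibrated at its fixed points", {
  set.seed(2)
  coh <- posterior_cohort(2, group_effect = 0.25, effect_idx = 1)
  X <- build_design(coh$covariates, "group", patient_label = "AN")
  fit <- peb_fit(coh$posteriors, X)
  expect_gt(posterior_probability(fit, "group", coh$posteriors[[1]]$Ep |>
                                    names() |> head(1)), 0.99)
  # an effect with posterior mean ~0 sits near even odds or below
  null_pp <- fit$PP["group", 4:6]
  expect_true(all(null_pp < 0.95))
})

test_that("relabeling the groups flips signs but not probabilities", {
  coh <- posterior_cohort(3, group_effect = 0.2, effect_idx = 1:2)
  X1 <- build_design(coh$covariates, "group", patient_label = "AN")
  X2 <- build_design(coh$covariates, "group", patient_label = "HC")
  f1 <- peb_fit(coh$posteriors, X1)
  f2 <- peb_fit(coh$posteriors, X2)
  expect_equal(f1$Ep["group", ], -f2$Ep["group", ], tolerance = 1e-6)
  expect_equal(f1$PP["group", ], f2$PP["group", ], tolerance = 1e-4)
})

test_that("uncertain subjects move the group estimate less", {
  pn <- param_names_3()
  labs <- paste0("R", 1:3)
  mk <- function(val, sd) {
    Ep <- stats::setNames(c(val, rep(0, 8)), pn)
    Cp <- diag(sd^2, 9); dimnames(Cp) <- list(pn, pn)
    list(Ep = Ep, Cp = Cp, labels = labs)
  }
  X <- build_design(data.frame(id = c("a", "b"), group = c("AN", "AN")))
  # same discrepant pair, once with b confident, once with b uncertain
  confident <- peb_fit(list(mk(0.3, 0.02), mk(-0.3, 0.02)), X)
  uncertain <- peb_fit(list(mk(0.3, 0.02), mk(-0.3, 0.5)), X)
  # with b uncertain the group mean sits closer to subject a
  expect_gt(uncertain$Ep["mean", 1], confident$Ep["mean", 1])
})

test_that("thresholding blanks everything at or below the cutoff", {
  coh <- posterior_cohort(4, group_effect = 0.25, effect_idx = 1:3)
  X <- build_design(coh$covariates, "group", patient_label = "AN")
  fit <- peb_fit(coh$posteriors, X)
  tm <- threshold_matrix(fit, "group", cutoff = 0.99)
  shown <- !is.na(tm$Ep)
  expect_true(all(tm$PP[shown] > 0.99))
  # entries with PP <= cutoff (e.g. a synthetic 0.98) are blanked
  fit2 <- fit
  fit2$PP[] <- 0.98
  tm2 <- threshold_matrix(fit2, "group", cutoff = 0.99)
  expect_true(all(is.na(tm2$Ep)))
  expect_output(print(tm), "self-connection log-scaling")
})

test_that("the four-analysis suite runs and respects the null", {
  coh <- posterior_cohort(5, group_effect = 0,
                          hr_slope = 0.012, hr_idx = 2)
  suite <- run_analysis_suite(coh$posteriors, coh$covariates,
                              patient_label = "AN")
  expect_named(suite$matrices,
               c("mean_AN", "hr_AN", "mean_HC", "hr_HC",
                 "group_difference", "interaction"))
  # null group difference: few or no survivors among couplings
  gd <- suite$matrices$group_difference$Ep
  offd <- gd[row(gd) != col(gd)]
  expect_lte(sum(!is.na(offd)), 1)
})
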