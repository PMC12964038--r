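# Shared fixture builders. Everything is generated in code; expensive
# objects are cached per test session.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

## a single simulated 3-node subject at the study acquisition parameters
sim_subject <- function(seed, n_vol = 746, tr = 0.961, couplings = NULL,
                        fluct_sd = 0.1, obs_snr = 1) {
  set.seed(seed)
  th <- matrix(0, 3, 3)
  off <- which(!diag(3))
  th[off] <- if (is.null(couplings)) sample(c(-0.3, 0.3), 6, TRUE) else
    couplings
  conn <- dcm_connectivity(th)
  if (!is_stable(effective_matrix(conn))) return(NULL)
  x <- simulate_neural(conn, duration = n_vol * tr, dt = tr / 19,
                       fluct_sd = fluct_sd, seed = seed)
  bold <- simulate_bold(x, tr = tr, obs_snr = obs_snr, seed = seed + 1000)
  list(conn = conn, bold = bold[seq_len(n_vol), , drop = FALSE],
       true_offdiag = th[off])
}

## construct a subject-level posterior around a given connectivity vector,
## with uncertainty on the scale seen in first-level fits
make_posterior <- function(true_vec, param_names, labels, sd = 0.05,
                           self_sd = 0.02) {
  p <- length(param_names)
  is_self <- startsWith(param_names, "self_")
  sds <- ifelse(is_self, self_sd, sd)
  Ep <- stats::setNames(true_vec + stats::rnorm(p, 0, sds), param_names)
  Cp <- diag(sds^2, p)
  dimnames(Cp) <- list(param_names, param_names)
  list(Ep = Ep, Cp = Cp, labels = labels, converged = TRUE,
       explained_variance = 0.9)
}

## parameter names of the 3-node connectivity field, in package order
param_names_3 <- function() {
  labs <- paste0("R", 1:3)
  off <- which(!diag(3), arr.ind = TRUE)
  c(paste0(labs[off[, 2]], "->", labs[off[, 1]]), paste0("self_", labs))
}

## simulated cohort of constructed posteriors: base couplings + group and/or
## HR effects on designated connections + between-subject noise
posterior_cohort <- function(seed, n_per_group = c(26, 40),
                             group_effect = 0, effect_idx = 1:3,
                             hr_slope = 0, hr_idx = integer(0),
                             subject_sd = 0.1) {
  set.seed(seed)
  pn <- param_names_3()
  labs <- paste0("R", 1:3)
  n <- sum(n_per_group)
  gc <- rep(c(1, -1), n_per_group)
  hr <- stats::rnorm(n, rep(c(65.06, 74.1), n_per_group), 10)
  hrc <- hr - mean(hr)
  base <- c(stats::runif(6, -0.15, 0.15), numeric(3))
  posts <- lapply(seq_len(n), function(i) {
    tv <- base
    tv[effect_idx] <- tv[effect_idx] + gc[i] * group_effect
    tv[hr_idx] <- tv[hr_idx] + hrc[i] * hr_slope
    tv[1:6] <- tv[1:6] + stats::rnorm(6, 0, subject_sd)
    tv[7:9] <- tv[7:9] + stats::rnorm(3, 0, 0.02)
    make_posterior(tv, pn, labs)
  })
  covars <- data.frame(id = sprintf("s%03d", seq_len(n)),
                       group = rep(c("AN", "HC"), n_per_group),
                       hr_bpm = hr, stringsAsFactors = FALSE)
  list(posteriors = posts, covariates = covars, base = base, gc = gc,
       hr = hr)
}

## small written-out demo cohort for pipeline tests
demo_cohort_dir <- function() {
  cached("demo_dir", {
    dir <- file.path(tempdir(), "canheart-demo-cohort")
    spec <- cohort_spec(
      n_per_group = c(4, 4), n_regions = 3, n_volumes = 304, n_dummy = 4,
      base_conn = make_connectivity(3, 0.15, seed = 11),
      effect_group = data.frame(target = 2, source = 1, delta = 0.2),
      with_motion = TRUE, seed = 5
    )
    write_cohort(simulate_cohort(spec), dir)
    dir
  })
}
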