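#' Power-law noise spectral parameters
#'
#' Parameters of the diagonal power-law spectra of endogenous neuronal
#' fluctuations (g_v) and BOLD observation noise (g_e):
#' \deqn{g(f) = e^{a} \, g_0 \, (f/f_0)^{-\beta},}
#' with pooled log-amplitude a and spectral exponent beta. The exponent is
#' parameterized through a logistic transform, \eqn{\beta = 2\,
#' \mathrm{logit}^{-1}(\theta_\beta)}, so it stays in [0, 2]; \eqn{\theta_\beta
#' = 0} gives pink (1/f) noise.
#'
#' @param ln_alpha_v,theta_beta_v log-amplitude and exponent parameter of the
#'   neuronal fluctuation spectrum.
#' @param ln_alpha_e,theta_beta_e same for the observation-noise spectrum.
#' @param gv0,ge0 reference amplitudes (variance/Hz) at \code{f0}.
#' @param f0 reference frequency in Hz.
#' @return list of class \code{noise_params}.
#' @export
noise_params <- function(ln_alpha_v = 0, theta_beta_v = 0,
                         ln_alpha_e = 0, theta_beta_e = 0,
                         gv0 = 1, ge0 = 0, f0 = 0.03) {
  structure(list(ln_alpha_v = ln_alpha_v, theta_beta_v = theta_beta_v,
                 ln_alpha_e = ln_alpha_e, theta_beta_e = theta_beta_e,
                 gv0 = gv0, ge0 = ge0, f0 = f0),
            class = "noise_params")
}

beta_from_theta <- function(theta) 2 * stats::plogis(theta)

## diagonal spectra at the grid (vectors over freqs)
eval_noise_spectra <- function(noise, freqs) {
  bv <- beta_from_theta(noise$theta_beta_v)
  be <- beta_from_theta(noise$theta_beta_e)
  list(gv = exp(noise$ln_alpha_v) * noise$gv0 * (freqs / noise$f0)^(-bv),
       ge = exp(noise$ln_alpha_e) * noise$ge0 * (freqs / noise$f0)^(-be))
}

#' Linearized hemodynamic transfer function
#'
#' First-order transfer function from neuronal activity to BOLD, obtained by
#' Jacobian linearization of the Balloon state equations around their fixed
#' point (s, f, v, q) = (0, 1, 1, 1):
#' \deqn{K(f) = C (i 2 \pi f I - J)^{-1} B,}
#' with B the input map into the vasodilatory signal and C the gradient of the
#' BOLD observation equation. One complex-valued function per region.
#'
#' @param hemo a \code{hemo_params} object.
#' @param freqs frequency grid in Hz.
#' @return complex matrix \code{length(freqs) x n_regions}.
#' @export
hemodynamic_kernel <- function(hemo, freqs) {
  stopifnot(inherits(hemo, "hemo_params"))
  n <- length(hemo$transit)
  K <- matrix(complex(real = 0), length(freqs), n)
  iw <- 2i * pi * freqs
  for (j in seq_len(n)) {
    kappa <- hemo$kappa0 * exp(hemo$decay[j])
    tau <- hemo$tau0 * exp(hemo$transit[j])
    E0 <- hemo$E0; alpha <- hemo$alpha
    # Jacobian of (s, f, v, q) dynamics at the fixed point
    J <- matrix(0, 4, 4)
    J[1, 1] <- -kappa; J[1, 2] <- -hemo$gamma
    J[2, 1] <- 1
    J[3, 2] <- 1 / tau; J[3, 3] <- -1 / (alpha * tau)
    J[4, 2] <- (E0 + (1 - E0) * log(1 - E0)) / (E0 * tau)
    J[4, 3] <- -(1 / alpha - 1) / tau
    J[4, 4] <- -1 / tau
    if (any(!is.finite(J))) stop("hemodynamic_kernel: non-finite Jacobian")
    B <- c(1, 0, 0, 0)
    C <- c(0, 0, hemo$V0 * (hemo$k2 - hemo$k3), -hemo$V0 * (hemo$k1 + hemo$k2))
    eg <- eigen(J)
    cq <- C %*% eg$vectors
    qb <- solve(eg$vectors, B)
    for (m in 1:4) {
      K[, j] <- K[, j] + cq[m] * qb[m] / (iw - eg$values[m])
    }
  }
  K
}

#' Model-implied BOLD cross-spectral density
#'
#' Evaluates the generative cross spectrum of the coupled linear stochastic
#' system observed through (linearized) hemodynamics:
#' \deqn{G_y(f) = K(f) T(f) G_v(f) T(f)^\dagger K(f)^\dagger + G_e(f),}
#' with neuronal transfer function \eqn{T(f) = (i 2 \pi f I - A)^{-1}},
#' \eqn{A[i,i] = -0.5 e^{\theta_i}}, diagonal hemodynamic kernels K, and
#' diagonal power-law spectra \eqn{G_v, G_e}.
#'
#' @param conn a \code{dcm_connectivity} (effective matrix must be stable).
#' @param freqs frequency grid in Hz.
#' @param hemo a \code{hemo_params}, or \code{NULL} for identity hemodynamics
#'   (K = 1, the pure Ornstein-Uhlenbeck observation case).
#' @param noise a \code{noise_params}; defaults to unit flat fluctuation
#'   spectra with no observation-noise floor.
#' @return a \code{cross_spectrum}.
#' @export
generative_csd <- function(conn, freqs, hemo = NULL,
                           noise = noise_params(theta_beta_v = -Inf,
                                                theta_beta_e = -Inf)) {
  A <- effective_matrix(conn)
  if (!is_stable(A)) stop("generative_csd: effective matrix is unstable")
  n <- nrow(A)
  K <- if (is.null(hemo)) {
    matrix(1 + 0i, length(freqs), n)
  } else {
    hemodynamic_kernel(hemo, freqs)
  }
  gs <- eval_noise_spectra(noise, freqs)
  vals <- csd_from_parts(A, K, gs$gv, gs$ge, freqs)
  cross_spectrum(freqs, vals, conn$labels)
}

## Core spectral assembly shared by generative_csd and the inversion.
## A: n x n stable matrix; K: n_freq x n complex kernels; gv, ge: per-freq
## scalars of the pooled diagonal spectra.
csd_from_parts <- function(A, K, gv, ge, freqs) {
  n <- nrow(A)
  n_freq <- length(freqs)
  eg <- eigen(A)
  U <- eg$vectors
  Vi <- solve(U)
  iw <- 2i * pi * freqs
  vals <- array(complex(real = 0), c(n_freq, n, n))
  I_n <- diag(n)
  for (fi in seq_len(n_freq)) {
    Tm <- U %*% ((1 / (iw[fi] - eg$values)) * Vi)
    M <- K[fi, ] * Tm                          # diag(K) %*% T, row scaling
    S <- gv[fi] * (M %*% Conj(t(M))) + ge[fi] * I_n
    vals[fi, , ] <- (S + Conj(t(S))) / 2
  }
  vals
}

## Stack a CSD into a real feature vector: for each frequency, Re of the
## diagonal and Re+Im of the upper triangle. Returns vector plus a block
## index (one block per region pair i <= j) used for precision components.
csd_features <- function(csd) {
  n <- dim(csd$values)[2]
  n_freq <- length(csd$freqs)
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  feat <- c()
  block <- c()
  for (b in seq_len(nrow(pairs))) {
    i <- pairs[b, 1]; j <- pairs[b, 2]
    if (i == j) {
      v <- Re(csd$values[, i, i])
    } else {
      v <- c(Re(csd$values[, i, j]), Im(csd$values[, i, j]))
    }
    feat <- c(feat, v)
    block <- c(block, rep(b, length(v)))
  }
  list(vec = feat, block = block, n_blocks = nrow(pairs))
}

## Per-feature whitening weights aligned with csd_features() ordering: the
## sampling standard deviation of a cross-spectral estimate S_ij(f) scales
## with sqrt(S_ii(f) S_jj(f)), so each feature is divided by that scale.
feature_weights <- function(csd) {
  n <- dim(csd$values)[2]
  n_freq <- length(csd$freqs)
  dvals <- sapply(seq_len(n), function(i) pmax(Re(csd$values[, i, i]), 0))
  floor_v <- 1e-10 * max(dvals)
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  w <- c()
  for (b in seq_len(nrow(pairs))) {
    i <- pairs[b, 1]; j <- pairs[b, 2]
    s <- 1 / sqrt(pmax(dvals[, i] * dvals[, j], floor_v^2))
    w <- c(w, if (i == j) s else c(s, s))
  }
  w
}

#' Fraction of cross-spectral variance explained by a prediction
#'
#' One minus the residual sum of squares over the total (mean-centered) sum
#' of squares, computed on the stacked real and imaginary parts of the cross
#' spectra, floored at zero.
#'
#' @param observed,predicted \code{cross_spectrum} objects on the same grid.
#' @return fraction in [0, 1].
#' @export
explained_variance <- function(observed, predicted) {
  if (!isTRUE(all.equal(observed$freqs, predicted$freqs)) ||
      !all(dim(observed$values) == dim(predicted$values))) {
    stop("explained_variance: frequency grid or dimension mismatch")
  }
  y <- csd_features(observed)$vec
  p <- csd_features(predicted)$vec
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - p)^2)
  max(0, 1 - sse / sst)
}

## Companion time-domain explained variance: both spectra are inverse-
## transformed to cross-covariance sequences over a set of lags and compared
## by the same 1 - SSE/SST statistic.
explained_variance_time <- function(observed, predicted, n_lags = 16,
                                    tr = 0.961) {
  stopifnot(isTRUE(all.equal(observed$freqs, predicted$freqs)))
  lags <- seq(0, n_lags - 1) * tr
  ccov <- function(csd) {
    df <- mean(diff(csd$freqs))
    out <- sapply(lags, function(tau) {
      ph <- exp(2i * pi * csd$freqs * tau)
      # two-sided integral: S(-f) = conj(S(f))
      2 * df * colSums(Re(csd$values * ph), dims = 1)
    })
    as.numeric(out)
  }
  y <- ccov(observed)
  p <- ccov(predicted)
  sst <- sum((y - mean(y))^2)
  max(0, 1 - sum((y - p)^2) / sst)
}
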