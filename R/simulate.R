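#' Simulate latent neuronal dynamics
#'
#' Integrates the linear stochastic system dx/dt = A x + v by Euler-Maruyama
#' from x(0) = 0. With white endogenous fluctuations of standard-deviation
#' parameter \code{fluct_sd}, the increment at step dt is
#' \code{fluct_sd * sqrt(dt) * N(0,1)}, i.e. v has two-sided spectral density
#' \code{fluct_sd^2} and, for a single node with rate a < 0, stationary
#' variance \code{fluct_sd^2 / (2|a|)}. An AR(1)-shaped option colours the
#' fluctuations towards low frequencies while preserving their total power.
#'
#' @param conn a \code{dcm_connectivity} object (must be stable).
#' @param duration length of the simulation in seconds.
#' @param dt integration step in seconds (default 0.05, well below the fastest
#'   time constant at nominal couplings).
#' @param fluct_sd fluctuation amplitude (scalar or per-region vector).
#' @param seed integer RNG seed.
#' @param ar_coef optional AR(1) colouring coefficient in [0, 1); 0 = white.
#' @return time-by-regions matrix of latent states, with attribute "dt".
#' @export
simulate_neural <- function(conn, duration, dt = 0.05, fluct_sd = 1,
                            seed = 1, ar_coef = 0) {
  A <- effective_matrix(conn)
  n <- nrow(A)
  if (!is_stable(A)) stop("simulate_neural: coupling matrix is unstable")
  stopifnot(duration > 0, dt > 0, ar_coef >= 0, ar_coef < 1)
  if (dt > 0.2 / max(Mod(eigen(A, only.values = TRUE)$values))) {
    warning("simulate_neural: dt is coarse relative to the fastest eigenmode")
  }
  fluct_sd <- rep_len(fluct_sd, n)
  n_steps <- ceiling(duration / dt)
  set.seed(seed)
  eps <- matrix(stats::rnorm(n_steps * n), n_steps, n)
  if (ar_coef > 0) {
    # colour, then rescale to unit marginal variance so total power is kept
    for (j in seq_len(n)) eps[, j] <- stats::filter(eps[, j], ar_coef,
                                                    method = "recursive")
    eps <- eps * sqrt(1 - ar_coef^2)
  }
  x <- matrix(0, n_steps, n)
  state <- numeric(n)
  step_sd <- fluct_sd * sqrt(dt)
  Adt <- A * dt
  for (t in seq_len(n_steps)) {
    state <- state + drop(Adt %*% state) + step_sd * eps[t, ]
    if (!all(is.finite(state)) || sum(state^2) > 1e12) {
      stop("simulate_neural: state norm diverged at step ", t)
    }
    x[t, ] <- state
  }
  colnames(x) <- conn$labels
  attr(x, "dt") <- dt
  x
}

#' Default hemodynamic (Balloon) parameters
#'
#' Fixed constants of the Balloon observation model and per-region free
#' log-scalings of the transit time and signal-decay rate. The states per
#' region are vasodilatory signal s, normalized inflow f, venous volume v and
#' deoxyhemoglobin content q, with
#' \deqn{\dot s = x - \kappa s - \gamma (f - 1), \quad \dot f = s,}
#' \deqn{\tau \dot v = f - v^{1/\alpha}, \quad
#'       \tau \dot q = f E(f)/E_0 - v^{1/\alpha} q / v,}
#' \eqn{E(f) = 1 - (1-E_0)^{1/f}}, and BOLD observation
#' \eqn{y = V_0 (k_1 (1-q) + k_2 (1 - q/v) + k_3 (1 - v))}.
#' \eqn{\kappa = 0.64 e^{\theta_\kappa}} (1/s) and
#' \eqn{\tau = 2 e^{\theta_\tau}} (s).
#'
#' @param n_regions number of regions.
#' @param transit,decay per-region log-scalings (default 0).
#' @param gamma flow feedback rate (1/s).
#' @param alpha Grubb vessel stiffness exponent.
#' @param E0 resting oxygen extraction fraction.
#' @param V0 resting venous volume fraction.
#' @return list of class \code{hemo_params}.
#' @export
hemo_params <- function(n_regions, transit = 0, decay = 0,
                        gamma = 0.32, alpha = 0.32, E0 = 0.4, V0 = 0.04) {
  transit <- rep_len(transit, n_regions)
  decay <- rep_len(decay, n_regions)
  structure(
    list(transit = transit, decay = decay, gamma = gamma, alpha = alpha,
         E0 = E0, V0 = V0,
         k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2,
         tau0 = 2, kappa0 = 0.64),
    class = "hemo_params"
  )
}

## Balloon RHS, vectorized over regions. Hemodynamic states are integrated in
## log space (columns of `state` = s, ln f, ln v, ln q per region) so flow,
## volume and deoxyhemoglobin stay strictly positive; the model and its
## fixed-point linearization are unchanged. x = neuronal drive (one value per
## region).
balloon_deriv <- function(state, x, kappa, tau, h) {
  s <- state[, 1]
  f <- exp(state[, 2]); v <- exp(state[, 3]); q <- exp(state[, 4])
  Ef <- 1 - (1 - h$E0)^(1 / f)
  vout <- v^(1 / h$alpha)
  cbind(x - kappa * s - h$gamma * (f - 1),
        s / f,
        (f - vout) / (tau * v),
        (f * Ef / h$E0 - vout * q / v) / (tau * q))
}

balloon_bold <- function(v, q, h) {
  h$V0 * (h$k1 * (1 - q) + h$k2 * (1 - q / v) + h$k3 * (1 - v))
}

#' Simulate BOLD observations from latent neuronal activity
#'
#' Integrates the nonlinear Balloon equations per region driven by the latent
#' series, applies the BOLD observation equation, downsamples to the scan
#' repetition time, and adds observation noise with a power-law spectrum.
#' Baseline BOLD is 0 (the fixed point of the hemodynamics at zero input).
#'
#' @param latent time-by-regions latent matrix with attribute "dt" (or pass
#'   \code{dt}).
#' @param tr repetition time in seconds (sampling interval of the output).
#' @param hemo a \code{hemo_params} object (default constructed to match).
#' @param dt integration step; defaults to \code{attr(latent, "dt")}.
#' @param obs_snr in-band (0.01-0.1 Hz) signal-to-noise power ratio of the
#'   added observation noise; \code{Inf} for noise-free output.
#' @param obs_exponent spectral exponent beta of the 1/f^beta observation
#'   noise.
#' @param seed RNG seed for the observation noise.
#' @return time-by-regions BOLD matrix sampled at \code{tr}.
#' @export
simulate_bold <- function(latent, tr, hemo = NULL, dt = attr(latent, "dt"),
                          obs_snr = Inf, obs_exponent = 1, seed = 1) {
  stopifnot(!is.null(dt), tr > 0)
  n <- ncol(latent)
  n_steps <- nrow(latent)
  if (is.null(hemo)) hemo <- hemo_params(n)
  steps_per_tr <- tr / dt
  if (abs(steps_per_tr - round(steps_per_tr)) > 0.01) {
    stop("simulate_bold: tr must be a multiple of dt (within rounding)")
  }
  y_fine <- matrix(0, n_steps, n)
  kappa <- hemo$kappa0 * exp(hemo$decay)
  tau <- hemo$tau0 * exp(hemo$transit)
  # the log-flow equation is stiff when flow dips: sub-step the hemodynamics
  n_sub <- max(1, ceiling(dt / 0.02))
  h_sub <- dt / n_sub
  state <- matrix(0, n, 4)                     # (s, ln f, ln v, ln q)
  for (t in seq_len(n_steps)) {
    for (s_i in seq_len(n_sub)) {
      # midpoint (RK2) step
      k1 <- balloon_deriv(state, latent[t, ], kappa, tau, hemo)
      k2 <- balloon_deriv(state + 0.5 * h_sub * k1, latent[t, ], kappa, tau,
                          hemo)
      state <- state + h_sub * k2
      # sustained deactivation beyond the flow-feedback range (x < -gamma)
      # sends the flow fixed point negative; floor log-flow at -5 (flow
      # ~ 0.7% of baseline) to keep the integration finite there
      state[, 2] <- pmax(state[, 2], -5)
    }
    if (!all(is.finite(state)) || any(abs(state[, 2:4]) > 20)) {
      stop("simulate_bold: non-physical hemodynamic state at step ", t)
    }
    y_fine[t, ] <- balloon_bold(exp(state[, 3]), exp(state[, 4]), hemo)
  }
  idx <- round(seq_len(floor(n_steps / steps_per_tr)) * steps_per_tr)
  y <- y_fine[idx, , drop = FALSE]
  if (is.finite(obs_snr)) {
    set.seed(seed)
    for (j in seq_len(n)) {
      noise <- powerlaw_noise(nrow(y), obs_exponent)
      sig_p <- band_power(y[, j], tr, 0.01, 0.1)
      noi_p <- band_power(noise, tr, 0.01, 0.1)
      if (noi_p > 0 && sig_p > 0) {
        noise <- noise * sqrt(sig_p / (obs_snr * noi_p))
      }
      y[, j] <- y[, j] + noise
    }
  }
  colnames(y) <- colnames(latent)
  attr(y, "tr") <- tr
  y
}

## Unit-scale noise with two-sided spectrum proportional to f^(-beta),
## generated by FFT shaping of white Gaussian noise.
powerlaw_noise <- function(n, beta) {
  w <- stats::rnorm(n)
  if (beta == 0) return(w)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # symmetric frequency index
  shape <- c(0, f[-1]^(-beta / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}
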