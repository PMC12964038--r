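#' Shrinkage priors for cross-spectral DCM inversion
#'
#' Builds the prior mean and variance over the full latent parameter vector:
#' off-diagonal couplings (Hz), self-connection log-scalings, per-region
#' hemodynamic transit/decay log-scalings, and pooled noise parameters
#' (log-amplitudes and spectral-exponent parameters for the neuronal
#' fluctuation and observation-noise spectra).
#'
#' Prior variances follow the usual shrinkage convention for this model
#' family: couplings N(0, 1/64); self and hemodynamic log-scalings
#' N(0, 1/256); noise log-amplitudes N(0, 1/64); exponent parameters
#' N(0, 1/64), which centers the exponents at 1 (pink noise) through the
#' logistic transform.
#'
#' The reference amplitude of the observation-noise floor (\code{ge0}) is set
#' so that, at the prior mean, the band-averaged diagonal power of the noise
#' floor equals that of the neuronally driven signal: a prior-predictive
#' in-band signal-to-noise ratio of 1.
#'
#' @param n_regions number of regions.
#' @param freqs analysis frequency grid (used to calibrate \code{ge0}).
#' @param labels optional region names.
#' @param coupling_var,self_var,hemo_var,noise_amp_var,noise_exp_var prior
#'   variances per parameter class.
#' @return list of class \code{spdcm_priors} with elements \code{mean},
#'   \code{var} (named vectors), \code{types}, \code{labels}, \code{gv0},
#'   \code{ge0}, \code{f0}.
#' @export
spdcm_priors <- function(n_regions, freqs = default_freq_grid(),
                         labels = NULL,
                         coupling_var = 1 / 64, self_var = 1 / 256,
                         hemo_var = 1 / 256, noise_amp_var = 1 / 64,
                         noise_exp_var = 1 / 64) {
  if (is.null(labels)) labels <- paste0("R", seq_len(n_regions))
  stopifnot(length(labels) == n_regions)
  off <- which(!diag(n_regions), arr.ind = TRUE)   # column-major off-diagonal
  nm_off <- paste0(labels[off[, 2]], "->", labels[off[, 1]])
  nm <- c(nm_off,
          paste0("self_", labels),
          paste0("transit_", labels),
          paste0("decay_", labels),
          "ln_alpha_v", "theta_beta_v", "ln_alpha_e", "theta_beta_e")
  types <- c(rep("coupling", nrow(off)),
             rep("self", n_regions),
             rep("transit", n_regions), rep("decay", n_regions),
             "noise_amp", "noise_exp", "noise_amp", "noise_exp")
  vr <- c(coupling = coupling_var, self = self_var, transit = hemo_var,
          decay = hemo_var, noise_amp = noise_amp_var,
          noise_exp = noise_exp_var)[types]
  pr <- structure(
    list(mean = stats::setNames(numeric(length(nm)), nm),
         var = stats::setNames(as.numeric(vr), nm),
         types = stats::setNames(types, nm),
         off_index = off,
         labels = labels, n_regions = n_regions,
         gv0 = 1, ge0 = 1, f0 = 0.03),
    class = "spdcm_priors"
  )
  # calibrate ge0: prior-predictive noise-floor power = signal power
  sig <- theta_to_model(pr$mean, pr)
  K <- hemodynamic_kernel(sig$hemo, freqs)
  gs <- eval_noise_spectra(sig$noise, freqs)
  vals <- csd_from_parts(effective_matrix(sig$conn), K, gs$gv,
                         rep(0, length(freqs)), freqs)
  sig_power <- mean(Re(vals[cbind(rep(seq_along(freqs), n_regions),
                                  rep(seq_len(n_regions), each = length(freqs)),
                                  rep(seq_len(n_regions), each = length(freqs)))]))
  floor_shape <- mean((freqs / pr$f0)^(-1))
  pr$ge0 <- sig_power / floor_shape
  pr
}

## Map a named parameter vector to model components (connectivity,
## hemodynamics, noise) under a priors template.
theta_to_model <- function(theta, priors) {
  n <- priors$n_regions
  off <- priors$off_index
  th_off <- matrix(0, n, n)
  th_off[off] <- theta[seq_len(nrow(off))]
  k <- nrow(off)
  th_self <- theta[k + seq_len(n)]
  transit <- theta[k + n + seq_len(n)]
  decay <- theta[k + 2 * n + seq_len(n)]
  nz <- theta[k + 3 * n + 1:4]
  list(
    conn = dcm_connectivity(th_off, th_self, priors$labels),
    hemo = hemo_params(n, transit = transit, decay = decay),
    noise = noise_params(ln_alpha_v = nz[1], theta_beta_v = nz[2],
                         ln_alpha_e = nz[3], theta_beta_e = nz[4],
                         gv0 = priors$gv0, ge0 = priors$ge0, f0 = priors$f0)
  )
}

## Predicted feature vector (and CSD array) at theta. Returns NULL if the
## effective matrix violates the stability margin (soft penalty: the search
## rejects the proposal and raises regularization).
predict_features <- function(theta, priors, freqs, stab_margin = 1e-6) {
  mod <- theta_to_model(theta, priors)
  A <- effective_matrix(mod$conn)
  if (max_re_eig(A) > -stab_margin) return(NULL)
  K <- hemodynamic_kernel(mod$hemo, freqs)
  gs <- eval_noise_spectra(mod$noise, freqs)
  vals <- csd_from_parts(A, K, gs$gv, gs$ge, freqs)
  csd <- cross_spectrum(freqs, vals, priors$labels, validate = FALSE)
  list(csd = csd, feat = csd_features(csd))
}
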