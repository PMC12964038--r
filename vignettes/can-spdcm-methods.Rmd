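---
title: "Cross-spectral DCM of the central autonomic network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-spectral DCM of the central autonomic network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

canheart estimates resting-state effective connectivity among the six nodes
of the central autonomic network (vmPFC, ACC, anterior insula, amygdala,
hypothalamus, brainstem) from BOLD time series, and relates it to mean heart
rate across a patient and a control group. This vignette documents the
models, the numerical choices, and what the synthetic test bed does and does
not establish.

## The generative model

Neuronal activity follows a linear stochastic differential equation,
$\dot x(t) = A x(t) + v(t)$, where $A$ is the effective-connectivity matrix
in Hz: entry $(i, j)$ is the influence of region $j$ (source, column) on
region $i$ (target, row). Off-diagonal entries are free parameters with
shrinkage priors $N(0, 1/64)$. Diagonal entries are parameterized as
$A_{ii} = -0.5\,e^{\theta_i}$ with unitless log-scalings
$\theta_i \sim N(0, 1/256)$, so self-connections are inhibitory by
construction and a positive $\theta_i$ means stronger self-inhibition.

Each region's activity drives the Balloon hemodynamic model (vasodilatory
signal, inflow, venous volume, deoxyhemoglobin) with fixed constants
$\gamma = 0.32$, $\alpha = 0.32$, $E_0 = 0.4$, $V_0 = 0.04$, observation
coefficients $k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$, and per-region
free log-scalings of transit time ($\tau = 2e^{\theta_\tau}$ s) and signal
decay ($\kappa = 0.64e^{\theta_\kappa}$ s$^{-1}$), both with $N(0, 1/256)$
priors.

Because the model is fitted in the frequency domain, only the linearization
of the hemodynamics around their fixed point enters the likelihood: the
per-region transfer function $K(f) = C(i2\pi f I - J)^{-1}B$, with $J$ the
Jacobian at rest. The model-implied cross-spectral density is

$$G_y(f) = K(f)\,T(f)\,G_v(f)\,T(f)^\dagger K(f)^\dagger + G_e(f),
\qquad T(f) = (i 2\pi f I - A)^{-1},$$

with pooled power-law spectra $G_v$ (endogenous fluctuations) and $G_e$
(observation noise), each $g(f) = e^{a} g_0 (f/f_0)^{-\beta}$ at reference
frequency $f_0 = 0.03$ Hz. Log-amplitudes have $N(0, 1/64)$ priors; the
exponents are kept in $[0, 2]$ by a logistic transform centered on pink
noise ($\beta = 1$) with $N(0, 1/64)$ priors on the transformed scale. The
reference amplitude of $G_e$ is calibrated so that, at the prior mean, the
in-band noise floor equals the neuronally driven power (prior-predictive
SNR of 1); the observed spectra are rescaled to the prior-predictive
amplitude before inversion, so the overall data scale is not a free
parameter.

## Data features and inversion

The data features are parametric cross-spectra: each subject's de-meaned,
detrended series is fitted with a multivariate autoregression of order 8
and converted to a cross-spectral density on 32 frequencies from 1/128 Hz to
0.25 Hz (the resting-state band; Nyquist at TR = 0.961 s is about 0.52 Hz).
Both the order and the grid are configurable; the defaults follow the
common toolbox convention for this model family and are recorded in the run
configuration.

The real and imaginary parts of the upper triangle (diagonal: real only)
are stacked into a feature vector. Features are whitened by the sampling
scale of a spectral estimate — the standard deviation of $\hat S_{ij}(f)$
grows with $\sqrt{S_{ii}(f) S_{jj}(f)}$ — which prevents the large
low-frequency diagonal terms from dominating the fit; without this
weighting, coupling recovery degrades markedly at realistic noise levels.

Inversion is variational Laplace: a Gaussian accuracy term with one
log-precision hyperparameter per region pair (set to its conditional
optimum after every parameter step, capped at $e^{\pm 16}$), minus the KL
complexity against the priors. Optimization is Gauss–Newton with
Levenberg–Marquardt damping and a numeric Jacobian; proposals are scored
with the curvature at the current expansion point (the Jacobian is
recomputed only on acceptance, keeping the accept test free of
finite-difference jitter), and a step is accepted only if the joint update
(parameters plus precisions) increases the free energy, so the free-energy
trace is non-decreasing by construction. Proposals whose
effective matrix has a largest eigenvalue real part above $-10^{-6}$ are
rejected and the damping raised, which keeps the search inside the stable
regime without hard failures. Convergence is declared after 4 consecutive
accepted improvements below $10^{-2}$ nats, with a 128-iteration budget;
typical fits converge in 10–30 iterations. The posterior covariance is the
inverse curvature at the optimum.

Model fit is summarized as explained variance, $1 - \mathrm{SSE} /
\mathrm{SST}$ floored at zero, on the fitted cross-spectral features (the
quantity the model actually predicts). A companion time-domain value is
computed by inverse-transforming both spectra to cross-covariance sequences
and applying the same statistic, since fit quality is often quoted in
time-domain terms; both are reported and neither is treated as canonical.
Subjects are retained when the spectral explained variance is at least 0.10
(the threshold is inclusive at exactly 0.10, reading "applied a 10%
threshold" with the ≥ convention) and the inversion converged.

## Group level

Subject posteriors (couplings and self log-scalings, with their posterior
covariance) enter a parametric-empirical-Bayes GLM. The design matrix has a
constant first column; every later regressor is mean-centered. Group is
coded +1 (patients) / −1 (controls) before centering; the group-by-HR
interaction is the product of the two centered main effects, re-centered —
the convention is tested to be invariant (up to sign) to which group is
labelled +1. For the within-group HR analyses, HR is centered within the
group being analyzed; grand-mean centering is available as an option, since
either reading of "mean-centered" is defensible.

Between-subject variability is one scaled covariance component,
$e^{-\gamma} V$ with $V$ set to 1/16 of the first-level prior variance per
parameter and $\gamma$ estimated by free-energy maximization under a
$N(0, 1)$ hyperprior. This baseline (a fixed fraction of the prior
variance) keeps the degenerate one-subject case well behaved while leaving
two orders of magnitude of adjustment to the data. Priors on group-level
coefficients are zero-mean with the first-level prior variance of the
corresponding parameter.

Per (regressor, parameter) effect, a posterior probability is computed by
Bayesian model reduction: the free-energy difference between the full model
and a reduced model with that coefficient's prior variance collapsed (prior
precision inflated by $10^8$), mapped through the logistic function. Effects
are displayed only when PP exceeds 0.99, matching the display rule of the
analysis this package reproduces; the equation of PP 0.99 with "a Bayes
factor of 4" in that analysis's description is internally inconsistent (4
log-evidence units, not an evidence ratio of 4) and is not implemented as a
separate rule.

The full suite runs (1) per-group mean-only models, (2) the pooled
group-difference model, (3) per-group HR models, and (4) the pooled model
with group, HR, and their interaction, writing thresholded matrices in the
"Ep (SD)" display convention with blanks below threshold.

## Quality control and physiology

Motion is summarized by framewise displacement: the sum of absolute
backward differences of the three translations plus the three rotations
converted to arc length on a 50 mm sphere (the exclusion thresholds are
stated by the source analysis, the FD formula itself is the standard
convention and configurable). A run is excluded when mean FD exceeds 0.30
mm or more than 20% of FDs exceed 0.30 mm; both comparisons are strict.

Heart rate comes from PPG traces sampled at 500 Hz over 10 minutes:
zero-phase Butterworth filtering to 0.05–3 Hz (implemented as a cascaded
high-pass and low-pass, since a single narrow band-pass design of this
relative bandwidth is numerically ill-conditioned; the trace is de-meaned
and mirror-padded to absorb edge transients), local-maximum beat detection
with an adaptive amplitude threshold and a 0.25 s refractory period, and
mean HR defined as 60 over the mean inter-beat interval. The count-based
definition (beats per elapsed time) is reported alongside, as the two
differ under missed beats. Artifact-like irregular inter-beat intervals are
flagged but not automatically excluded.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes: a
stable base connectivity; two groups of 26 and 40 subjects; per-subject HR
drawn from group normals (means 65.06 and 74.1 bpm, SD 10); sparse
connection-specific group offsets (added with the +1/−1 coding) and HR
slopes (linear in mean-centered HR, matching the regression structure being
tested); between-subject coupling noise with stability enforced by
rejection resampling (at most 100 attempts); 750 volumes at TR = 0.961 s
with the first 4 discarded; synthetic PPG and rigid-body motion.

Deliberate simplifications, and hence limits on what passing tests show
about real data:

- Endogenous fluctuations are white by default — the analytically checkable
  case, whose stationary statistics have closed forms (an AR(1)-shaped
  option exists for realism). The inversion's pink-centered fluctuation
  prior is therefore mildly misspecified against the generator, which is
  intentional: recovery results include that mismatch penalty.
- The fluctuation amplitude is 0.1 (latent SD ≈ 0.1 at nominal
  self-decay). Larger amplitudes drive the Balloon model outside its
  flow-feedback range (sustained input below $-\gamma$ sends the flow
  fixed point negative); the integrator floors log-flow at −5 in that
  regime, a numerical guard that the default amplitude almost never
  triggers.
- Observation noise has a $1/f$ spectrum scaled to an in-band
  (0.01–0.1 Hz) signal-to-noise ratio of 1 — a free choice, recorded in
  the cohort specification, as the source analysis does not state its
  noise level.
- No cardiorespiratory coupling into BOLD, no scanner artifacts, no
  nonlinear neuronal effects; the PPG template (log-normal systolic peak,
  dicrotic bump at 35%) exercises the detector but is not a cardiovascular
  model.

Hemodynamic simulation integrates the full nonlinear Balloon equations
(RK2, log-transformed positive states, sub-stepped at ≤ 20 ms), so the
first level is tested against data generated by a richer model than the
linearized one it fits.

## Numerical choices

- Neural integration step: TR/19 ≈ 0.0506 s (an integer sub-multiple of the
  sampling interval, well below the fastest time constant at default
  couplings).
- Stability margin $10^{-6}$ on eigenvalue real parts during inversion;
  generation uses strict negativity.
- Data normalization: one global scale matching the mean observed diagonal
  power to the prior-predictive value; scale is stored with the fit.
- The precision cap at $e^{16}$ bounds the self-consistency fixed point
  (noise-free data) without affecting realistic fits.
- Exactly-on-threshold conventions: EV 0.10 included; FD rules strict; PP
  0.99 strict (a PP of exactly 0.99 is blanked).
- Problem sizes in the tests and the acceptance analysis: 3-node networks
  for recovery experiments (the inversion scales to the 6-node network,
  which the cohort generator defaults to), 10–15 recovery seeds, 66-subject
  group analyses on subject posteriors with first-level-scale uncertainty
  (SD 0.05 Hz for couplings, from the recovery experiments), and a reduced
  6-subject demo cohort for end-to-end determinism.

## Known limitations

- Group-level operating characteristics are established on constructed
  subject posteriors, not on thousands of full inversions; the full
  first-to-second-level chain is exercised end to end only at demo scale.
- Parameter recovery at the default noise level averages a
  true-versus-estimated coupling correlation of roughly 0.8 (range across
  seed sets ≈ 0.77–0.86); individual-subject estimates carry visible
  shrinkage from the $N(0, 1/64)$ coupling priors.
- VOI extraction uses fixed sphere centers (per-subject peak search would
  require subject-level statistical maps, which are out of scope); spheres
  are left-lateralized, matching the network definition.
- HRV-style variability metrics are deliberately not computed; only mean
  HR enters the analyses.
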