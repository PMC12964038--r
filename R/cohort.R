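#' Synthetic photoplethysmography trace
#'
#' A sum of stereotyped pulse waveforms placed at beat times whose inter-beat
#' interval is 60/hr plus Gaussian jitter, with slow baseline drift and
#' broadband noise. The pulse template is a log-normal-shaped systolic peak
#' followed by a dicrotic bump at 35\% amplitude — enough morphology to
#' exercise a beat detector without being a cardiovascular model.
#'
#' @param hr_bpm target mean heart rate (30-200 bpm).
#' @param duration trace length in seconds.
#' @param fs sampling rate in Hz (>= 100).
#' @param hr_jitter_sd inter-beat-interval jitter in seconds.
#' @param drift_amp,noise_sd baseline drift and broadband noise amplitudes
#'   relative to the unit pulse peak.
#' @param dicrotic relative amplitude of the dicrotic bump.
#' @param seed RNG seed.
#' @return numeric trace with attributes \code{fs} and \code{beat_times}
#'   (ground truth).
#' @export
simulate_ppg <- function(hr_bpm, duration = 600, fs = 500,
                         hr_jitter_sd = 0.02, drift_amp = 0.3,
                         noise_sd = 0.05, dicrotic = 0.35, seed = 1) {
  stopifnot(hr_bpm >= 30, hr_bpm <= 200, fs >= 100, duration > 0)
  set.seed(seed)
  ibi0 <- 60 / hr_bpm
  n_beats <- ceiling(duration / ibi0) + 5
  ibis <- ibi0 + stats::rnorm(n_beats, 0, hr_jitter_sd)
  ibis <- pmax(ibis, 0.25)
  beat_times <- cumsum(c(ibi0 / 2, ibis))
  beat_times <- beat_times[beat_times < duration - 0.6]
  n <- round(duration * fs)
  x <- numeric(n)
  # log-normal systolic peak (mode ~0.09 s) + dicrotic bump at ~0.35 s
  t_tpl <- seq(0, 0.6, by = 1 / fs)
  sys <- stats::dlnorm(t_tpl, meanlog = log(0.12), sdlog = 0.5)
  sys <- sys / max(sys)
  dic <- dicrotic * exp(-0.5 * ((t_tpl - 0.35) / 0.05)^2)
  tpl <- sys + dic
  for (bt in beat_times) {
    i0 <- round(bt * fs) + 1
    idx <- i0:min(i0 + length(tpl) - 1, n)
    x[idx] <- x[idx] + tpl[seq_along(idx)]
  }
  drift_f <- 0.02 + 0.02 * stats::runif(1)
  drift <- drift_amp * sin(2 * pi * drift_f * seq_len(n) / fs +
                             stats::runif(1, 0, 2 * pi))
  x <- x + drift + stats::rnorm(n, 0, noise_sd)
  attr(x, "fs") <- fs
  attr(x, "beat_times") <- beat_times
  x
}

#' Synthetic rigid-body motion trace
#'
#' Smooth random-walk motion parameters (3 translations in mm, 3 rotations in
#' rad) with optional step displacements ("spikes") injected at given frames.
#'
#' @param n_frames number of frames.
#' @param baseline_sd per-frame random-walk increment SD in mm (rotations get
#'   the equivalent on a 50-mm arm).
#' @param spike_frames frame indices receiving a step displacement.
#' @param spike_size step size in mm (applied to the x translation).
#' @param seed RNG seed.
#' @return frame-by-6 matrix with columns tx, ty, tz (mm), rx, ry, rz (rad).
#' @export
simulate_motion <- function(n_frames, baseline_sd = 0.01,
                            spike_frames = integer(0), spike_size = 0.5,
                            seed = 1) {
  stopifnot(all(spike_frames >= 1), all(spike_frames <= n_frames))
  set.seed(seed)
  increments <- matrix(stats::rnorm(n_frames * 6), n_frames, 6)
  increments[, 1:3] <- increments[, 1:3] * baseline_sd
  increments[, 4:6] <- increments[, 4:6] * baseline_sd / 50
  # smooth the random walk a little so it resembles slow drift
  increments <- apply(increments, 2, function(z) {
    stats::filter(z, rep(1 / 4, 4), sides = 1, circular = TRUE)
  })
  m <- apply(increments, 2, cumsum)
  # each spike is a persistent x-translation step at that frame; directions
  # alternate so the trace does not drift away
  sgn <- 1
  for (sf in sort(spike_frames)) {
    m[sf:n_frames, 1] <- m[sf:n_frames, 1] + sgn * spike_size
    sgn <- -sgn
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  m
}

#' Cohort generation specification
#'
#' Bundles every constant of the synthetic study: two groups of given sizes,
#' per-group heart-rate distributions, sparse connection-specific group and
#' HR effects added to a shared base connectivity, acquisition timing, and
#' noise levels. Defaults mirror the analyzed cohort: 26 patients vs 40
#' controls, HR means 65.06 and 74.1 bpm (SD 10), 750 volumes at TR 0.961 s
#' with the first 4 discarded.
#'
#' @param n_per_group integer pair (patients, controls).
#' @param group_labels character pair; the first group is coded +1.
#' @param n_regions network size.
#' @param base_conn optional \code{dcm_connectivity}; default drawn with
#'   [make_connectivity()].
#' @param effect_group data.frame (target, source, delta) of group effects in
#'   Hz (added for group +1, subtracted for group -1).
#' @param effect_hr data.frame (target, source, slope) of HR effects in
#'   Hz/bpm applied to mean-centered HR.
#' @param hr_mean_per_group,hr_sd HR distribution in bpm.
#' @param subject_noise_sd between-subject coupling noise in Hz.
#' @param tr_seconds,n_volumes,n_dummy acquisition timing.
#' @param fluct_sd,obs_snr neuronal fluctuation amplitude and in-band
#'   observation signal-to-noise ratio.
#' @param with_ppg,with_motion also generate PPG traces / motion tables.
#' @param ppg_duration PPG recording length in seconds.
#' @param seed master RNG seed.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_per_group = c(26, 40),
                        group_labels = c("AN", "HC"),
                        n_regions = 6,
                        base_conn = NULL,
                        effect_group = NULL,
                        effect_hr = NULL,
                        hr_mean_per_group = c(65.06, 74.1),
                        hr_sd = 10,
                        subject_noise_sd = 0.1,
                        tr_seconds = 0.961,
                        n_volumes = 750,
                        n_dummy = 4,
                        fluct_sd = 0.1,
                        obs_snr = 1,
                        with_ppg = FALSE,
                        with_motion = FALSE,
                        ppg_duration = 600,
                        seed = 1) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1),
            tr_seconds > 0, n_volumes > n_dummy)
  if (is.null(base_conn)) {
    base_conn <- make_connectivity(n_regions, coupling_sd = 0.1, seed = seed)
  }
  stopifnot(length(base_conn$labels) == n_regions)
  structure(
    list(n_per_group = n_per_group, group_labels = group_labels,
         n_regions = n_regions, base_conn = base_conn,
         effect_group = effect_group, effect_hr = effect_hr,
         hr_mean_per_group = hr_mean_per_group, hr_sd = hr_sd,
         subject_noise_sd = subject_noise_sd,
         tr_seconds = tr_seconds, n_volumes = n_volumes, n_dummy = n_dummy,
         fluct_sd = fluct_sd, obs_snr = obs_snr,
         with_ppg = with_ppg, with_motion = with_motion,
         ppg_duration = ppg_duration, seed = seed),
    class = "cohort_spec"
  )
}

effect_matrix <- function(effects, n, labels) {
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  if (is.null(effects) || nrow(effects) == 0) return(M)
  for (r in seq_len(nrow(effects))) {
    M[effects[r, 1][[1]], effects[r, 2][[1]]] <- effects[r, 3][[1]]
  }
  diag(M) <- 0
  M
}

#' Simulate a two-group cohort with known ground truth
#'
#' Per subject: group code +1/-1, heart rate drawn from the group's normal
#' distribution, subject connectivity = base + group_code * group-effect map
#' + (HR - grand mean HR) * HR-slope map + between-subject noise (resampled
#' until stable), and a BOLD run simulated through the neuronal and
#' hemodynamic models. The returned truth record is sufficient to recompute
#' every subject's coupling matrix exactly.
#'
#' @param spec a \code{cohort_spec}.
#' @param progress print per-subject progress.
#' @return list of class \code{synthetic_cohort} with \code{subjects} (each:
#'   id, group, group_code, hr_bpm, bold, and optionally ppg, motion),
#'   \code{participants} data frame, and \code{truth} (base matrix, effect
#'   maps, per-subject noise and true matrices, grand mean HR, seed).
#' @export
simulate_cohort <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_regions
  labels <- spec$base_conn$labels
  n_sub <- sum(spec$n_per_group)
  group_code <- rep(c(1, -1), spec$n_per_group)
  group <- rep(spec$group_labels, spec$n_per_group)
  set.seed(spec$seed)
  hr <- stats::rnorm(n_sub,
                     mean = rep(spec$hr_mean_per_group, spec$n_per_group),
                     sd = spec$hr_sd)
  hr_centered <- hr - mean(hr)
  G <- effect_matrix(spec$effect_group, n, labels)
  Hm <- effect_matrix(spec$effect_hr, n, labels)
  ids <- sprintf("sub-%03d", seq_len(n_sub))
  duration <- spec$n_volumes * spec$tr_seconds
  dt <- spec$tr_seconds / 19          # integer substepping of the TR
  subjects <- vector("list", n_sub)
  true_mats <- vector("list", n_sub)
  noise_mats <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    set.seed(sub_seed(spec$seed, s))
    delta <- group_code[s] * G + hr_centered[s] * Hm
    conn_s <- perturb_connectivity(spec$base_conn, delta,
                                   noise_sd = spec$subject_noise_sd)
    x <- simulate_neural(conn_s, duration, dt = dt,
                         fluct_sd = spec$fluct_sd,
                         seed = sub_seed(spec$seed, s + 10000))
    bold <- simulate_bold(x, tr = spec$tr_seconds, obs_snr = spec$obs_snr,
                          seed = sub_seed(spec$seed, s + 20000))
    bold <- bold[(spec$n_dummy + 1):spec$n_volumes, , drop = FALSE]
    stopifnot(all(is.finite(bold)))
    subj <- list(id = ids[s], group = group[s], group_code = group_code[s],
                 hr_bpm = hr[s], bold = bold)
    if (spec$with_ppg) {
      subj$ppg <- simulate_ppg(hr[s], duration = spec$ppg_duration,
                               seed = sub_seed(spec$seed, s + 30000))
    }
    if (spec$with_motion) {
      subj$motion <- simulate_motion(spec$n_volumes - spec$n_dummy,
                                     seed = sub_seed(spec$seed, s + 40000))
    }
    subjects[[s]] <- subj
    true_mats[[s]] <- effective_matrix(conn_s)
    noise_mats[[s]] <- attr(conn_s, "noise")
    if (progress) message("simulated ", ids[s])
  }
  names(subjects) <- ids
  participants <- data.frame(id = ids, group = group,
                             group_code = group_code, hr_bpm = hr,
                             stringsAsFactors = FALSE)
  structure(
    list(subjects = subjects, participants = participants,
         truth = list(base = effective_matrix(spec$base_conn),
                      theta_offdiag = spec$base_conn$theta_offdiag,
                      effect_group = G, effect_hr = Hm,
                      hr_grand_mean = mean(hr),
                      noise = noise_mats, true_matrices = true_mats,
                      seed = spec$seed),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$participants), " subjects (",
      paste(x$spec$n_per_group, x$spec$group_labels, collapse = " + "),
      "), ", x$spec$n_regions, " regions\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes per-subject \code{sub-XXX_bold.tsv} (header = region labels), and
#' when present \code{sub-XXX_ppg.tsv} (time, amplitude) and
#' \code{sub-XXX_motion.tsv}, plus \code{participants.csv} and
#' \code{truth.json}.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    write_bold_tsv(subj$bold, file.path(dir, paste0(subj$id, "_bold.tsv")))
    if (!is.null(subj$ppg)) {
      fs <- attr(subj$ppg, "fs")
      utils::write.table(
        data.frame(time = (seq_along(subj$ppg) - 1) / fs,
                   amplitude = as.numeric(subj$ppg)),
        file.path(dir, paste0(subj$id, "_ppg.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(subj$motion)) {
      utils::write.table(subj$motion,
                         file.path(dir, paste0(subj$id, "_motion.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  write_participants(cohort$participants, file.path(dir, "participants.csv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(base = truth$base, effect_group = truth$effect_group,
         effect_hr = truth$effect_hr, hr_grand_mean = truth$hr_grand_mean,
         true_matrices = truth$true_matrices, seed = truth$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
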