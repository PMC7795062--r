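#' @useDynLib bpbeat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom sd cor lm coef median quantile
#'   complete.cases p.adjust wilcox.test t.test ks.test
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed, kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

#' Construct a simulated subject
#'
#' A subject bundles demographics with the hemodynamic constants of the
#' Moens-Korteweg / Hughes arterial model: pulse wave velocity
#' \eqn{PWV = \sqrt{E_0 e^{\gamma P} h / (\rho d)}} and pulse transit time
#' \eqn{PTT = L / PWV}. Defaults give a baseline finger PTT of roughly
#' 180-260 ms and a BCG R-J interval near 155 ms, inside the detection
#' windows used downstream.
#'
#' @param subject_id identifier string.
#' @param gender `"M"` or `"F"`.
#' @param age years.
#' @param height cm.
#' @param weight kg.
#' @param e0 elastic modulus of the vessel wall at zero pressure (Pa).
#' @param gamma_vessel vessel coefficient (1/mmHg), must be positive.
#' @param rho blood density (kg/m^3).
#' @param h vessel wall thickness (m).
#' @param d vessel radius (m).
#' @param l_path heart-to-finger path length (m).
#' @param hr_base resting heart rate (beats/min).
#' @param sbp_base,dbp_base baseline systolic/diastolic pressure (mmHg).
#' @param rji_base baseline ECG R to BCG J interval (ms).
#' @param ptt_offset_ms additive transit-time measurement offset (ms), used
#'   to model inter-day sensor/calibration drift; 0 for a first visit.
#' @return an object of class `sim_subject`.
#' @export
sim_subject <- function(subject_id = "S01", gender = "M", age = 35,
                        height = 172, weight = 68, e0 = 7000,
                        gamma_vessel = 0.016, rho = 1060, h = 0.0012,
                        d = 0.004, l_path = 0.75, hr_base = 68,
                        sbp_base = 111, dbp_base = 68, rji_base = 155,
                        ptt_offset_ms = 0) {
  stopifnot(gamma_vessel > 0, e0 > 0, rho > 0, h > 0, d > 0, l_path > 0,
            sbp_base > dbp_base, dbp_base > 0, hr_base > 0)
  s <- list(subject_id = subject_id, gender = gender, age = age,
            height = height, weight = weight,
            bmi = weight / (height / 100)^2,
            e0 = e0, gamma_vessel = gamma_vessel, rho = rho, h = h, d = d,
            l_path = l_path, hr_base = hr_base,
            sbp_base = sbp_base, dbp_base = dbp_base,
            rji_base = rji_base, ptt_offset_ms = ptt_offset_ms)
  class(s) <- "sim_subject"
  s
}

#' @export
print.sim_subject <- function(x, ...) {
  cat(sprintf("<sim_subject %s: %s, %d y, BMI %.1f, BP %.0f/%.0f, PTT0 %.0f ms>\n",
              x$subject_id, x$gender, round(x$age), x$bmi,
              x$sbp_base, x$dbp_base, ptt_from_bp(x$sbp_base, x)))
  invisible(x)
}

#' Pulse transit time implied by a blood pressure
#'
#' Inverts the arterial wave-speed model: the elastic modulus stiffens
#' exponentially with pressure (`E = E0 exp(gamma P)`), the wave speed is
#' `PWV = sqrt(E h / (rho d))`, and the transit time over the subject's
#' heart-to-finger path is `PTT = L / PWV`. Strictly decreasing in `p` for
#' `gamma_vessel > 0`.
#'
#' @param p blood pressure (mmHg), vectorized.
#' @param subject a [sim_subject()].
#' @return pulse transit time in ms.
#' @export
ptt_from_bp <- function(p, subject) {
  stopifnot(inherits(subject, "sim_subject"), all(p > 0))
  pwv <- sqrt(subject$e0 * exp(subject$gamma_vessel * p) * subject$h /
                (subject$rho * subject$d))
  1000 * subject$l_path / pwv
}

#' Simulate a beatwise blood-pressure trajectory
#'
#' Generates beat times and per-beat systolic/diastolic pressures as the
#' subject baseline plus a bounded mean-reverting (AR(1)) random component
#' plus slow sinusoidal vasomotor and respiratory modulation. The
#' mean-reverting form reflects BP homeostasis: excursions are transient,
#' so two sessions of the same subject share a stationary distribution.
#' This emulates the beatwise reference stream of a volume-clamp BP
#' monitor.
#'
#' @param subject a [sim_subject()].
#' @param duration_s session length in seconds (> 0).
#' @param seed integer seed; identical seeds give identical trajectories.
#' @param walk_sd stationary SD (mmHg) of the mean-reverting random
#'   component; 0 disables it.
#' @param walk_phi its per-beat autocorrelation (0 <= phi < 1).
#' @param osc_amp amplitudes (mmHg) of the vasomotor and respiratory
#'   sinusoids.
#' @param osc_freq their frequencies (Hz).
#' @param rr_jitter_sd per-beat RR-interval jitter SD (ms).
#' @return a `bp_trajectory`: list with `beat_times` (ms, strictly
#'   increasing), `sbp`, `dbp` (mmHg per beat).
#' @export
simulate_bp_trajectory <- function(subject, duration_s, seed = 1L,
                                   walk_sd = 3, walk_phi = 0.9,
                                   osc_amp = c(3, 1.2),
                                   osc_freq = c(0.04, 0.25),
                                   rr_jitter_sd = 25) {
  stopifnot(inherits(subject, "sim_subject"))
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  with_seed(seed, {
    rr_mean <- 60000 / subject$hr_base
    n_max <- ceiling(duration_s * 1000 / (rr_mean - 4 * rr_jitter_sd)) + 2L
    rr <- pmax(rr_mean + rnorm(n_max, 0, rr_jitter_sd), 0.4 * rr_mean)
    beat_times <- cumsum(rr)
    keep <- beat_times <= duration_s * 1000
    beat_times <- beat_times[keep]
    n <- length(beat_times)
    if (n < 1L) stop("duration_s too short for a single beat", call. = FALSE)

    # mean-reverting AR(1), shared by SBP and (attenuated) DBP
    walk <- numeric(n)
    if (walk_sd > 0) {
      step_sd <- walk_sd * sqrt(1 - walk_phi^2)
      steps <- rnorm(n, 0, step_sd)
      walk[1] <- rnorm(1, 0, walk_sd)
      for (i in seq_len(n)[-1])
        walk[i] <- walk_phi * walk[i - 1] + steps[i]
    }
    ph <- runif(2, 0, 2 * pi)
    t_s <- beat_times / 1000
    osc <- osc_amp[1] * sin(2 * pi * osc_freq[1] * t_s + ph[1]) +
      osc_amp[2] * sin(2 * pi * osc_freq[2] * t_s + ph[2])
    sbp <- subject$sbp_base + walk + osc
    dbp <- subject$dbp_base + 0.6 * walk + 0.5 * osc
    sbp <- pmin(pmax(sbp, 41), 219)
    dbp <- pmin(pmax(dbp, 40), sbp - 10)
    structure(list(beat_times = beat_times, sbp = sbp, dbp = dbp),
              class = "bp_trajectory")
  })
}

#' Noise configuration for the waveform synthesizer
#'
#' @param white_sd additive white-noise SD, as a fraction of the unit
#'   template amplitude, applied to every channel.
#' @param baseline_wander_amp,baseline_wander_hz amplitude and frequency of
#'   a sinusoidal baseline drift.
#' @param powerline_amp,powerline_hz mains interference amplitude/frequency.
#' @param dropout_rate fraction of beats whose BCG or PPG pulse is
#'   suppressed (exercises missing-peak handling); in `[0, 1)`.
#' @return a `noise_config` list.
#' @export
noise_config <- function(white_sd = 0.05, baseline_wander_amp = 0.4,
                         baseline_wander_hz = 0.3, powerline_amp = 0.1,
                         powerline_hz = 50, dropout_rate = 0.05) {
  stopifnot(white_sd >= 0, baseline_wander_amp >= 0, powerline_amp >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(white_sd = white_sd,
                 baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_hz = baseline_wander_hz,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 dropout_rate = dropout_rate), class = "noise_config")
}

# Gaussian bump helper on a sample grid (times in ms)
.gauss <- function(t, mu, sigma) exp(-((t - mu)^2) / (2 * sigma^2))

#' Synthesize a multi-channel waveform record
#'
#' Renders ECG/BCG/PPG channels at `fs` Hz from a beatwise BP trajectory.
#' Per beat: a Mexican-hat QRS complex is centred at the beat time (plus a
#' low-amplitude T wave); a Gabor-shaped BCG I-J complex places its J peak
#' at `R + RJI`, where RJI tracks the pressure-dependent transit time; the
#' PPG upstroke is built by integrating a Gaussian slope pulse so that the
#' steepest-slope instant (dPPG peak) falls exactly at
#' `R + ptt_from_bp(SBP)` (plus any subject-level calibration offset).
#' Ground-truth event times and template amplitudes are recorded before
#' noise is added.
#'
#' @param subject a [sim_subject()].
#' @param traj a [simulate_bp_trajectory()] result.
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param fs sampling rate (Hz).
#' @param visit visit index (1 or 2).
#' @param amp_scale per-channel amplitude multipliers, named
#'   `c(ecg=, bcg=, ppg=)`; models inter-day sensor gain drift.
#' @param pep_mean_ms,pep_jitter_sd,pep_resp_amp pre-ejection-period
#'   offset added to the R-to-finger transit: a constant
#'   electromechanical delay, per-beat white jitter, and a respiratory
#'   (0.25 Hz) oscillation with random phase. Together with the
#'   per-fiducial placement noise these make the R-anchored PTT an
#'   imperfect BP surrogate (within-record correlation around -0.8
#'   rather than -1), as it is physiologically.
#' @param amp_bp_coupling length-2 numeric: session-specific gains tying
#'   BCG and PPG pulse amplitudes to the BP level (vasomotor tone). `NULL`
#'   draws them from `N(0, 0.25)` under the record seed; pass explicit
#'   values to control inter-session consistency.
#' @return a `waveform_record`: channels `ecg`, `bcg`, `ppg`; `fs`;
#'   `subject`; `visit`; and `truth`, a data.frame with per-beat columns
#'   `beat_time`, `r`, `i`, `j`, `dppg` (ms; `NA` where a pulse was dropped),
#'   template amplitudes and reference `sbp`, `dbp`.
#' @export
synthesize_record <- function(subject, traj, noise = noise_config(),
                              seed = 1L, fs = 1000, visit = 1L,
                              amp_scale = c(ecg = 1, bcg = 1, ppg = 1),
                              pep_mean_ms = 30, pep_jitter_sd = 3,
                              pep_resp_amp = 6, amp_bp_coupling = NULL) {
  stopifnot(inherits(traj, "bp_trajectory"))
  n_beats <- length(traj$beat_times)
  if (n_beats < 1L) stop("trajectory is empty", call. = FALSE)
  if (min(diff(c(0, traj$beat_times))) < 350)
    stop("beat interval shorter than waveform template support", call. = FALSE)
  with_seed(seed, {
    dur_ms <- max(traj$beat_times) + 1000
    n <- ceiling(dur_ms * fs / 1000)
    t_ms <- (seq_len(n) - 1) * 1000 / fs
    ecg <- numeric(n); bcg <- numeric(n); ppg <- numeric(n)

    r_t <- traj$beat_times
    # Pre-ejection period: shared electromechanical delay ahead of both
    # the BCG ejection complex and the peripheral pulse, with a
    # respiratory oscillation and white jitter. Each fiducial additionally
    # carries its own placement noise (beat-to-beat morphology change), so
    # no single-beat interval is a noise-free BP readout: the intervals
    # carry complementary information (IPI cancels the shared PEP) and
    # consecutive beats can be averaged -- the two mechanisms that make
    # multi-signal, multi-cycle models worthwhile.
    pep <- pep_mean_ms +
      pep_resp_amp * sin(2 * pi * 0.25 * r_t / 1000 + runif(1, 0, 2 * pi)) +
      rnorm(n_beats, 0, pep_jitter_sd)
    nu_vasc <- rnorm(n_beats, 0, 2)  # peripheral pulse placement noise
    nu_bcg <- rnorm(n_beats, 0, 3)   # BCG complex placement noise
    ptt_vasc <- ptt_from_bp(traj$sbp, subject) + subject$ptt_offset_ms
    ptt <- ptt_vasc + pep + nu_vasc
    ptt_base <- ptt_from_bp(subject$sbp_base, subject)
    rji <- subject$rji_base +
      0.25 * (ptt_vasc - subject$ptt_offset_ms - ptt_base) +
      (pep - pep_mean_ms) + nu_bcg
    rji <- pmin(pmax(rji, 115), 245) # keep J inside its detection window
    f_bcg <- 12                       # Hz; sets the I-J spacing of the Gabor
    ij_ms <- 1000 / (2 * f_bcg)       # I trough precedes J by half a period
    j_t <- r_t + rji
    i_t <- j_t - ij_ms
    dppg_t <- r_t + ptt

    # Distal pulse amplitudes couple to BP with a session-specific random
    # gain (vasomotor tone): informative within a visit, inconsistent
    # across visits. ECG electrode gain is BP-independent.
    kappa <- if (is.null(amp_bp_coupling)) rnorm(2, 0, 0.25)
             else amp_bp_coupling
    z_bp <- (traj$sbp - mean(traj$sbp)) / 10
    ecg_amp <- amp_scale[["ecg"]] * (1 + 0.05 * rnorm(n_beats))
    bcg_amp <- amp_scale[["bcg"]] * (1 + 0.08 * rnorm(n_beats)) *
      pmax(1 + kappa[1] * z_bp, 0.3)
    ppg_amp <- amp_scale[["ppg"]] * (1 + 0.08 * rnorm(n_beats)) *
      pmax(1 + kappa[2] * z_bp, 0.3)

    drop <- runif(n_beats) < noise$dropout_rate
    drop_chan <- ifelse(runif(n_beats) < 0.5, "bcg", "ppg")

    half_win <- 400 # ms of template support rendered on each side
    for (b in seq_len(n_beats)) {
      lo <- max(1L, floor((r_t[b] - half_win) * fs / 1000))
      hi <- min(n, ceiling((r_t[b] + 2 * half_win) * fs / 1000))
      idx <- lo:hi
      tt <- t_ms[idx]
      # ECG: Mexican hat QRS (symmetric, peak exactly at R) + T wave
      u <- (tt - r_t[b]) / 10
      ecg[idx] <- ecg[idx] + ecg_amp[b] * (1 - u^2) * exp(-u^2 / 2) +
        0.22 * ecg_amp[b] * .gauss(tt, r_t[b] + 260, 45)
      # BCG: Gabor atom, J peak at j_t, I trough half a period earlier
      if (!(drop[b] && drop_chan[b] == "bcg"))
        bcg[idx] <- bcg[idx] + bcg_amp[b] *
          cos(2 * pi * f_bcg * (tt - j_t[b]) / 1000) *
          .gauss(tt, j_t[b], 45)
      # PPG: integral of (upslope bump - broad downslope bump)
      if (!(drop[b] && drop_chan[b] == "ppg")) {
        slope <- .gauss(tt, dppg_t[b], 22) -
          (22 / 90) * .gauss(tt, dppg_t[b] + 260, 90)
        ppg[idx] <- ppg[idx] + ppg_amp[b] * cumsum(slope) / fs * 40
      }
    }

    # tissue-absorption DC level so raw-PPG intensity ratios are defined
    ppg <- ppg + 2.0

    if (noise$white_sd > 0) {
      ecg <- ecg + rnorm(n, 0, noise$white_sd)
      bcg <- bcg + rnorm(n, 0, noise$white_sd)
      ppg <- ppg + rnorm(n, 0, noise$white_sd)
    }
    if (noise$baseline_wander_amp > 0) {
      ph <- runif(3, 0, 2 * pi)
      w <- 2 * pi * noise$baseline_wander_hz * t_ms / 1000
      ecg <- ecg + noise$baseline_wander_amp * sin(w + ph[1])
      bcg <- bcg + noise$baseline_wander_amp * sin(w + ph[2])
      ppg <- ppg + noise$baseline_wander_amp * sin(w + ph[3])
    }
    if (noise$powerline_amp > 0) {
      ph <- runif(3, 0, 2 * pi)
      w <- 2 * pi * noise$powerline_hz * t_ms / 1000
      ecg <- ecg + noise$powerline_amp * sin(w + ph[1])
      bcg <- bcg + noise$powerline_amp * sin(w + ph[2])
      ppg <- ppg + noise$powerline_amp * sin(w + ph[3])
    }

    truth <- data.frame(
      beat = seq_len(n_beats), beat_time = r_t, r = r_t,
      i = ifelse(drop & drop_chan == "bcg", NA_real_, i_t),
      j = ifelse(drop & drop_chan == "bcg", NA_real_, j_t),
      dppg = ifelse(drop & drop_chan == "ppg", NA_real_, dppg_t),
      ecg_amp = ecg_amp, bcg_amp = bcg_amp, ppg_amp = ppg_amp,
      sbp = traj$sbp, dbp = traj$dbp, ptt = ptt)
    truth$ptt[drop & drop_chan == "ppg"] <- NA_real_

    structure(list(subject = subject, visit = as.integer(visit), fs = fs,
                   ecg = ecg, bcg = bcg, ppg = ppg, truth = truth,
                   seed = as.integer(seed)),
              class = "waveform_record")
  })
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record %s visit %d: %.1f min @ %d Hz, %d beats>\n",
              x$subject$subject_id, x$visit,
              length(x$ecg) / x$fs / 60, x$fs, nrow(x$truth)))
  invisible(x)
}

#' Cohort generation configuration
#'
#' Defaults emulate the study conditions the package targets: 18 adults,
#' 30-minute sessions at 1000 Hz, 15 second visits one to two weeks later,
#' and cohort SBP/DBP means near 111.2/67.7 mmHg. Inter-day drift combines
#' an additive BP baseline shift, multiplicative channel-gain drift and a
#' small additive transit-time calibration offset. The drift composition
#' is dominated by the label (BP) shift and session-specific amplitude
#' behaviour rather than timing-calibration error, so that a pooled
#' general model carries over between days while a subject-day-specific
#' model degrades -- the reproducibility pattern this package's multi-day
#' protocol is designed to expose.
#'
#' @param duration_s session length (s).
#' @param fs sampling rate (Hz).
#' @param noise a [noise_config()].
#' @param drift_bp_sd SD of the visit-2 baseline SBP shift (mmHg).
#' @param drift_dbp_sd SD of the independent component of the visit-2 DBP
#'   baseline shift; the DBP shift is `0.4 x` the SBP shift plus this
#'   component, reflecting partly decoupled day-to-day diastolic tone.
#' @param drift_amp half-width of the uniform visit-2 channel gain factor.
#' @param drift_ptt_sd SD of the visit-2 transit-time offset (ms).
#' @param drift_kappa_sd SD of the visit-2 change in the session-specific
#'   amplitude-BP coupling gains (see [synthesize_record()]); 0 keeps the
#'   coupling identical across visits.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(duration_s = 1800, fs = 1000,
                          noise = noise_config(), drift_bp_sd = 7,
                          drift_dbp_sd = 4, drift_amp = 0.10,
                          drift_ptt_sd = 3, drift_kappa_sd = 0.35) {
  structure(list(duration_s = duration_s, fs = fs, noise = noise,
                 drift_bp_sd = drift_bp_sd, drift_dbp_sd = drift_dbp_sd,
                 drift_amp = drift_amp, drift_ptt_sd = drift_ptt_sd,
                 drift_kappa_sd = drift_kappa_sd), class = "cohort_config")
}

# Sample one subject's demographics and physiology. Baseline pressures
# follow a weak linear demographic rule so that demographic inputs are
# informative for pooled models.
sample_subject <- function(id, seed) {
  with_seed(seed, {
    male <- runif(1) < 8 / 18
    age <- round(runif(1, 20, 50))
    height <- rnorm(1, if (male) 175 else 162, 6)
    bmi <- rnorm(1, 23, 2.5)
    weight <- bmi * (height / 100)^2
    sbp_base <- 100.9 + 0.25 * age + 3.5 * male + rnorm(1, 0, 7)
    dbp_base <- 61.56 + 0.15 * age + 2.0 * male + rnorm(1, 0, 5)
    dbp_base <- min(dbp_base, sbp_base - 28)
    sim_subject(subject_id = sprintf("S%02d", id),
                gender = if (male) "M" else "F",
                age = age, height = height, weight = weight,
                e0 = max(rnorm(1, 7000, 900), 4500),
                gamma_vessel = min(max(rnorm(1, 0.016, 0.002), 0.010), 0.022),
                l_path = min(max(rnorm(1, 0.75, 0.05), 0.6), 0.9),
                hr_base = min(max(rnorm(1, 68, 7), 52), 88),
                sbp_base = sbp_base, dbp_base = dbp_base,
                rji_base = min(max(rnorm(1, 155, 8), 130), 185))
  })
}

#' Generate a synthetic cohort of waveform records
#'
#' Samples `n_subjects` subjects from plausible adult ranges, renders one
#' record per subject, and for the first `n_revisit` subjects renders a
#' second visit sharing the subject's physiology but perturbed by the
#' configured inter-day drift (baseline BP shift, channel gain drift,
#' transit-time calibration offset).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_revisit number of subjects with a second visit
#'   (`0 <= n_revisit <= n_subjects`).
#' @param config a [cohort_config()].
#' @param seed cohort master seed; all per-record seeds derive from it.
#' @return list of `waveform_record` (visit-1 records first, then visit-2).
#' @export
generate_cohort <- function(n_subjects = 18, n_revisit = 15,
                            config = cohort_config(), seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  stopifnot(n_revisit >= 0, n_revisit <= n_subjects)
  records <- vector("list", n_subjects + n_revisit)
  kappa1 <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj <- sample_subject(s, derive_seed(seed, 1000 + s))
    traj <- simulate_bp_trajectory(subj, config$duration_s,
                                   seed = derive_seed(seed, 2000 + s))
    kappa1[[s]] <- with_seed(derive_seed(seed, 7000 + s),
                             rnorm(2, 0, 0.25))
    records[[s]] <- synthesize_record(subj, traj, config$noise,
                                      seed = derive_seed(seed, 3000 + s),
                                      fs = config$fs, visit = 1L,
                                      amp_bp_coupling = kappa1[[s]])
  }
  for (k in seq_len(n_revisit)) {
    base <- records[[k]]$subject
    d <- with_seed(derive_seed(seed, 4000 + k), {
      list(bp = rnorm(1, 0, config$drift_bp_sd),
           dbp = rnorm(1, 0, config$drift_dbp_sd),
           amp = runif(3, 1 - config$drift_amp, 1 + config$drift_amp),
           ptt = rnorm(1, 0, config$drift_ptt_sd),
           kappa = rnorm(2, 0, config$drift_kappa_sd))
    })
    subj2 <- base
    subj2$sbp_base <- base$sbp_base + d$bp
    subj2$dbp_base <- min(base$dbp_base + 0.4 * d$bp + d$dbp,
                          subj2$sbp_base - 20)
    subj2$ptt_offset_ms <- d$ptt
    traj2 <- simulate_bp_trajectory(subj2, config$duration_s,
                                    seed = derive_seed(seed, 5000 + k))
    records[[n_subjects + k]] <-
      synthesize_record(subj2, traj2, config$noise,
                        seed = derive_seed(seed, 6000 + k),
                        fs = config$fs, visit = 2L,
                        amp_scale = c(ecg = d$amp[1], bcg = d$amp[2],
                                      ppg = d$amp[3]),
                        amp_bp_coupling = kappa1[[k]] + d$kappa)
  }
  records
}
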