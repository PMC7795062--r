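# Shared fixtures, built once per test session.

quiet_noise <- function() {
  noise_config(white_sd = 0, baseline_wander_amp = 0, powerline_amp = 0,
               dropout_rate = 0)
}

# one clean (noiseless, dropout-free) 2-minute record
fixture_clean_record <- local({
  rec <- NULL
  function() {
    if (is.null(rec)) {
      subj <- sim_subject()
      traj <- simulate_bp_trajectory(subj, 120, seed = 101)
      rec <<- synthesize_record(subj, traj, quiet_noise(), seed = 102)
    }
    rec
  }
})

# same subject/trajectory with the default noise model
fixture_noisy_record <- local({
  rec <- NULL
  function() {
    if (is.null(rec)) {
      subj <- sim_subject()
      traj <- simulate_bp_trajectory(subj, 120, seed = 101)
      rec <<- synthesize_record(subj, traj, noise_config(), seed = 103)
    }
    rec
  }
})

# fraction of truth events matched by a detection within tol ms
match_rate <- function(detected, truth, tol) {
  detected <- detected[!is.na(detected)]
  truth <- truth[!is.na(truth)]
  if (!length(truth)) return(NA_real_)
  mean(vapply(truth, function(t0) any(abs(detected - t0) <= tol),
              logical(1)))
}

# hand-built beat_features rows with controllable validity
make_rows <- function(n, valid = rep(TRUE, n), rri = 800,
                      subject = "T01", visit = 1L, seed = 1) {
  set.seed(seed)
  data.frame(
    beat_time = seq_len(n) * rri,
    rri = rri + rnorm(n, 0, 20), ptt = 250 + rnorm(n, 0, 10),
    rji = 160 + rnorm(n, 0, 5), ipi = 120 + rnorm(n, 0, 8),
    ecg_amp = 1 + rnorm(n, 0, 0.05), bcg_amp = 1 + rnorm(n, 0, 0.08),
    ppg_amp = 1 + rnorm(n, 0, 0.08),
    ref_sbp = 110 + rnorm(n, 0, 5), ref_dbp = 68 + rnorm(n, 0, 3),
    valid = valid, subject = subject, visit = visit)
}
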