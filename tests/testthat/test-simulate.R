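test_that("transit time from pressure follows the wave-speed model", {
  s <- sim_subject()
  # independent re-implementation of PWV = sqrt(E0 e^(gamma p) h/(rho d))
  oracle <- function(p, e0, g, rho, h, d, l) {
    1000 * l / sqrt(e0 * exp(g * p) * h / (rho * d))
  }
  for (p in c(60, 85, 111, 150, 200)) {
    expect_equal(ptt_from_bp(p, s),
                 oracle(p, s$e0, s$gamma_vessel, s$rho, s$h, s$d, s$l_path),
                 tolerance = 1e-9)
  }
  # strictly decreasing over the physiologic range
  grid <- seq(60, 200, by = 1)
  expect_true(all(diff(ptt_from_bp(grid, s)) < 0))
  # quadrupling the stiffness term halves the transit time exactly
  p0 <- 100
  p1 <- p0 + log(4) / s$gamma_vessel
  expect_equal(ptt_from_bp(p1, s), ptt_from_bp(p0, s) / 2,
               tolerance = 1e-12)
})

test_that("BP trajectory honors degenerate, deterministic and bounded contracts", {
  s <- sim_subject()
  flat <- simulate_bp_trajectory(s, 60, seed = 1, walk_sd = 0,
                                 osc_amp = c(0, 0))
  expect_true(all(flat$sbp == s$sbp_base))
  expect_true(all(flat$dbp == s$dbp_base))

  a <- simulate_bp_trajectory(s, 60, seed = 7)
  b <- simulate_bp_trajectory(s, 60, seed = 7)
  expect_identical(a, b)
  c <- simulate_bp_trajectory(s, 60, seed = 8)
  expect_false(identical(a$sbp, c$sbp))

  expect_true(all(diff(a$beat_times) > 0))
  expect_true(all(a$sbp > a$dbp))
  expect_true(all(a$sbp >= 40 & a$sbp <= 220))
  expect_error(simulate_bp_trajectory(s, -1), "duration")
})

test_that("synthesized truth events are ordered and inside detection windows", {
  rec <- fixture_clean_record()
  tr <- rec$truth
  expect_true(all(tr$r < tr$i))
  expect_true(all(tr$i < tr$j))
  expect_true(all(tr$r < tr$dppg))
  expect_true(all(tr$j - tr$r > 110 & tr$j - tr$r <= 250))
  # noiseless, dropout-free: every beat has every event
  expect_true(!anyNA(tr[, c("r", "i", "j", "dppg")]))
  # same seed reproduces the record bit-identically
  rec2 <- synthesize_record(rec$subject,
                            simulate_bp_trajectory(rec$subject, 120,
                                                   seed = 101),
                            quiet_noise(), seed = 102)
  expect_identical(rec$ecg, rec2$ecg)
  expect_identical(rec$truth, rec2$truth)
})

test_that("raising the whole BP trajectory shortens transit times", {
  s <- sim_subject()
  traj <- simulate_bp_trajectory(s, 60, seed = 5)
  hi <- traj
  hi$sbp <- traj$sbp + 30
  hi$dbp <- traj$dbp + 30
  r_lo <- synthesize_record(s, traj, quiet_noise(), seed = 6)
  r_hi <- synthesize_record(s, hi, quiet_noise(), seed = 6)
  expect_lt(mean(r_hi$truth$ptt), mean(r_lo$truth$ptt))
})

test_that("pulse dropout suppresses the configured fraction of events", {
  s <- sim_subject()
  traj <- simulate_bp_trajectory(s, 240, seed = 9)
  nz <- noise_config(white_sd = 0, baseline_wander_amp = 0,
                     powerline_amp = 0, dropout_rate = 0.1)
  rec <- synthesize_record(s, traj, nz, seed = 10)
  miss <- is.na(rec$truth$j) | is.na(rec$truth$dppg)
  n <- nrow(rec$truth)
  # binomial tolerance: 4 sd around 10%
  expect_gt(mean(miss), 0.1 - 4 * sqrt(0.1 * 0.9 / n))
  expect_lt(mean(miss), 0.1 + 4 * sqrt(0.1 * 0.9 / n))
})

test_that("cohort structure matches the requested visit counts", {
  cfg <- cohort_config(duration_s = 30)
  coh <- generate_cohort(5, 3, cfg, seed = 21)
  expect_length(coh, 8L)
  expect_identical(vapply(coh, function(r) r$visit, integer(1)),
                   c(rep(1L, 5), rep(2L, 3)))
  # revisit shares the subject identity and physiology
  expect_identical(coh[[6]]$subject$subject_id, coh[[1]]$subject$subject_id)
  expect_identical(coh[[6]]$subject$e0, coh[[1]]$subject$e0)

  solo <- generate_cohort(3, 0, cfg, seed = 21)
  expect_length(solo, 3L)
  expect_error(generate_cohort(0, 0, cfg), "n_subjects")
  expect_error(generate_cohort(2, 3, cfg))
})

test_that("zero inter-day drift leaves feature distributions unchanged", {
  cfg <- cohort_config(duration_s = 420, drift_bp_sd = 0,
                       drift_dbp_sd = 0, drift_amp = 0,
                       drift_ptt_sd = 0, drift_kappa_sd = 0)
  coh <- generate_cohort(1, 1, cfg, seed = 31)
  f1 <- record_features(coh[[1]], from = "truth")
  f2 <- record_features(coh[[2]], from = "truth")
  # beats are autocorrelated (vasomotor dynamics); thin to every 4th beat
  # so the two-sample KS test's independence assumption holds
  thin <- function(x) x[seq(1, length(x), by = 4)]
  for (col in c("ptt", "rri", "rji", "bcg_amp", "ppg_amp")) {
    ks <- suppressWarnings(ks.test(thin(f1[[col]][f1$valid]),
                                   thin(f2[[col]][f2$valid])))
    expect_gt(ks$p.value, 0.01)
  }
  # sanity of power: with default drift the same test detects the shift
  coh2 <- generate_cohort(1, 1, cohort_config(duration_s = 420),
                          seed = 31)
  g1 <- record_features(coh2[[1]], from = "truth")
  g2 <- record_features(coh2[[2]], from = "truth")
  ks2 <- suppressWarnings(ks.test(thin(g1$ptt[g1$valid]),
                                  thin(g2$ptt[g2$valid])))
  expect_lt(ks2$p.value, 0.01)
})
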