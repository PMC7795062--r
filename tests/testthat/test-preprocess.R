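test_that("band-pass filtering attenuates out-of-band and keeps in-band content", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  rms <- function(x) sqrt(mean(x^2))

  mains <- sin(2 * pi * 50 * t)
  out <- bandpass(mains, filter_spec("ecg"), fs)
  # oracle: squared (zero-phase) magnitude response of the designed filter
  bf <- signal::butter(2, c(0.5, 35) / (fs / 2), type = "pass")
  zi <- exp(-1i * 2 * pi * 50 / fs * (seq_along(bf$b) - 1))
  h50 <- Mod(sum(bf$b * zi) / sum(bf$a * zi))
  expect_equal(rms(out) / rms(mains), h50^2, tolerance = 0.05)
  # a second-order band with a 35 Hz edge suppresses mains power ~5-6x
  expect_lt(rms(out), 0.25 * rms(mains))

  dc <- rep(3.7, length(t))
  out_dc <- bandpass(dc, filter_spec("ecg"), fs)
  expect_lt(max(abs(out_dc)), 1e-6 * 3.7)

  inband <- sin(2 * pi * 10 * t)
  out_ib <- bandpass(inband, filter_spec("bcg"), fs)
  expect_lt(abs(rms(out_ib) - rms(inband)) / rms(inband), 0.2)

  # length preserved; re-filtering in-band content is nearly idempotent
  expect_length(out_ib, length(inband))
  twice <- bandpass(out_ib, filter_spec("bcg"), fs)
  expect_lt(abs(rms(twice) - rms(out_ib)) / rms(out_ib), 0.25)

  expect_error(bandpass(mains, filter_spec("ecg", low_hz = 40,
                                           high_hz = 10), fs), "band")
  expect_error(bandpass(mains, filter_spec("ecg", high_hz = 600), fs),
               "band")
})

test_that("R-peak detection is exact on clean and robust on noisy records", {
  rec <- fixture_clean_record()
  ecg_f <- bandpass(rec$ecg, filter_spec("ecg"), rec$fs)
  r <- detect_r_peaks(ecg_f, rec$fs)
  expect_gte(match_rate(r, rec$truth$r, 5), 1)
  # false positives: detections not near any truth beat
  fp <- mean(vapply(r, function(d) all(abs(rec$truth$r - d) > 10),
                    logical(1)))
  expect_lte(fp, 0.01)

  expect_warning(out <- detect_r_peaks(rep(0, 3000), 1000), "flat|no R")
  expect_length(out, 0)

  noisy <- fixture_noisy_record()
  rn <- detect_r_peaks(bandpass(noisy$ecg, filter_spec("ecg"), noisy$fs),
                       noisy$fs)
  expect_gte(match_rate(rn, noisy$truth$r, 10), 0.95)
})

test_that("J-peak search takes the window maximum with the stated bounds", {
  fs <- 1000
  bcg <- rep(0, 3000)
  r_times <- 1000
  # single impulse at R+180 ms
  bcg[1000 + 180 + 1] <- 1
  j <- detect_j_peaks(bcg, r_times, fs)
  expect_equal(j$time, 1180)
  expect_true(j$valid)

  # global maximum at R+100 ms is outside the (R+110, R+250] window;
  # the secondary peak at R+150 ms must win
  bcg2 <- rep(0, 3000)
  bcg2[1000 + 100 + 1] <- 2
  bcg2[1000 + 150 + 1] <- 1
  j2 <- detect_j_peaks(bcg2, r_times, fs)
  expect_equal(j2$time, 1150)

  # window running off the record end -> invalid flag
  j3 <- detect_j_peaks(rep(0, 1100), r_times, fs)
  expect_false(j3$valid)
})

test_that("I notch is the nearest preceding local minimum", {
  fs <- 1000
  rec <- fixture_clean_record()
  bcg_f <- bandpass(rec$bcg, filter_spec("bcg"), rec$fs)
  jj <- detect_j_peaks(bcg_f, rec$truth$r, fs)
  ii <- detect_i_notches(bcg_f, jj$time, fs)
  expect_gte(match_rate(ii$time[ii$valid], rec$truth$i, 5), 0.98)

  # monotone rise before the peak: no local minimum, flagged invalid
  ramp <- c(seq(0, 1, length.out = 500), seq(1, 0, length.out = 500))
  ii2 <- detect_i_notches(ramp, 499, fs)
  expect_false(ii2$valid)
})

test_that("dPPG peak finds the steepest upstroke with earliest-tie rule", {
  fs <- 1000
  rec <- fixture_clean_record()
  ppg_f <- bandpass(rec$ppg, filter_spec("ppg"), rec$fs)
  pp <- detect_dppg_peaks(ppg_f, rec$truth$r, fs)
  expect_gte(match_rate(pp$time[pp$valid], rec$truth$dppg, 5), 0.99)

  # constant-slope ramp with a dyadic step so slopes tie exactly in
  # binary floating point; the earliest maximal sample must win
  ppg <- rep(0, 2000)
  ppg[1301:2000] <- (0:699) / 512
  p2 <- detect_dppg_peaks(ppg, 1000, fs)
  expect_lt(p2$time, 1320) # onset region of the ramp starting at R+300
  expect_true(p2$valid)
})

test_that("whole-record detection matches ground truth", {
  rec <- fixture_clean_record()
  ev <- detect_beat_events(rec)
  tr <- rec$truth
  expect_equal(nrow(ev), nrow(tr))
  expect_gte(match_rate(ev$r, tr$r, 5), 1)
  expect_gte(match_rate(ev$j[ev$valid], tr$j, 5), 1)
  expect_gte(match_rate(ev$i[ev$valid], tr$i, 5), 1)
  expect_gte(match_rate(ev$dppg[ev$valid], tr$dppg, 5), 1)
  # detected J always respects its window relative to detected R
  d <- ev$j - ev$r
  expect_true(all(d[!is.na(d)] > 110 & d[!is.na(d)] <= 250))

  noisy <- fixture_noisy_record()
  evn <- detect_beat_events(noisy)
  trn <- noisy$truth
  expect_gte(match_rate(evn$r, trn$r, 10), 0.95)
  expect_gte(match_rate(evn$j[evn$valid], trn$j[!is.na(trn$j)], 10), 0.95)
  expect_gte(match_rate(evn$dppg[evn$valid], trn$dppg[!is.na(trn$dppg)],
                        10), 0.95)
})

test_that("plausibility filter enforces physiologic bounds and is monotone", {
  rec <- fixture_clean_record()
  ev <- detect_beat_events(rec, apply_filter = FALSE)
  clean <- plausibility_filter(ev)
  expect_identical(clean$valid, ev$valid) # all-clean input unchanged

  # inject one impossible transit time
  ev2 <- ev
  ev2$dppg[10] <- ev2$r[10] + 50
  f2 <- plausibility_filter(ev2)
  expect_false(f2$valid[10])
  expect_identical(f2$valid[-10], ev$valid[-10])

  # corrupt 10 beats with artifact-scale amplitudes
  set.seed(4)
  bad_idx <- sample(nrow(ev), 10)
  ev3 <- ev
  ev3$j_amp[bad_idx] <- ev3$j_amp[bad_idx] * 8
  f3 <- plausibility_filter(ev3)
  expect_gte(sum(!f3$valid[bad_idx]), 9)
  expect_lte(sum(!f3$valid[-bad_idx]), 2)

  # monotone: filtering never re-validates an invalid beat
  ev4 <- ev
  set.seed(5)
  ev4$valid[sample(nrow(ev4), 20)] <- FALSE
  f4 <- plausibility_filter(ev4)
  expect_true(all(!f4$valid[!ev4$valid]))

  # exclusion-list file invalidates listed beats
  path <- tempfile(fileext = ".txt")
  writeLines(c("# manual review", "3", "7"), path)
  f5 <- plausibility_filter(ev, exclusion_list = path)
  expect_false(any(f5$valid[c(3, 7)]))

  # suppressed pulses (dropout) are flagged through the amplitude floor
  s <- sim_subject()
  traj <- simulate_bp_trajectory(s, 180, seed = 41)
  nz <- noise_config(dropout_rate = 0.1)
  recd <- synthesize_record(s, traj, nz, seed = 42)
  evd <- detect_beat_events(recd)
  dropped <- which(is.na(recd$truth$j) | is.na(recd$truth$dppg))
  expect_gte(mean(!evd$valid[dropped]), 0.8)
})
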