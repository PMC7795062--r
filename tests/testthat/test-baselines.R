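test_that("calibration constants satisfy their identities", {
  rows <- make_rows(30)
  cal <- calibrate(rows)
  expect_equal(cal$pp0, cal$sbp0 - cal$dbp0)
  expect_equal(cal$mbp0, cal$dbp0 + cal$pp0 / 3)
  expect_equal(cal$sbp0, mean(rows$ref_sbp))
  expect_equal(cal$ptt0, mean(rows$ptt))
  # worked identity: 120/80 -> PP 40, MBP 93.33
  r2 <- make_rows(20)
  r2$ref_sbp <- 120; r2$ref_dbp <- 80
  cal2 <- calibrate(r2)
  expect_equal(cal2$pp0, 40)
  expect_equal(cal2$mbp0, 93 + 1 / 3, tolerance = 1e-12)

  expect_error(calibrate(make_rows(5)), "10")
})

test_that("calibration recovers the generating vessel coefficient", {
  s <- sim_subject(gamma_vessel = 0.017)
  set.seed(12)
  sbp <- 111 + rnorm(200, 0, 6)
  rows <- make_rows(200)
  rows$ref_sbp <- sbp
  rows$ptt <- ptt_from_bp(sbp, s)
  cal <- calibrate(rows)
  expect_lt(abs(cal$gamma_cal - 0.017) / 0.017, 0.1)
})

test_that("classical estimators return the calibration BP at the operating point", {
  cal <- structure(list(sbp0 = 120, dbp0 = 80, pp0 = 40, mbp0 = 93 + 1 / 3,
                        ptt0 = 250, pir0 = 1.8, gamma_cal = 0.031),
                   class = "calibration_point")
  expect_equal(chen_sbp(250, cal), 120)
  p <- poon_bp(250, cal)
  expect_equal(unname(p[, "sbp"]), 120, tolerance = 1e-12)
  expect_equal(unname(p[, "dbp"]), 80, tolerance = 1e-12)
  d <- ding_bp(250, 1.8, cal)
  expect_equal(unname(d[, "sbp"]), 120)
  expect_equal(unname(d[, "dbp"]), 80)

  # monotone: shorter transit -> higher systolic estimate
  ptt <- seq(180, 320, by = 5)
  expect_true(all(diff(chen_sbp(ptt, cal)) < 0))
  expect_true(all(diff(poon_bp(ptt, cal)[, "sbp"]) < 0))

  # quadratic pulse-pressure term: at ptt0/sqrt(2), SBP - DBP = 2 PP0
  p2 <- poon_bp(250 / sqrt(2), cal)
  expect_equal(unname(p2[, "sbp"] - p2[, "dbp"]), 80, tolerance = 1e-9)

  # doubling PIR halves the diastolic estimate
  expect_equal(unname(ding_bp(250, 3.6, cal)[, "dbp"]), 40)
})

test_that("closed-form estimators match an independent re-implementation", {
  cal <- structure(list(sbp0 = 118, dbp0 = 76, pp0 = 42, mbp0 = 90,
                        ptt0 = 250, pir0 = 1.8, gamma_cal = 0.031),
                   class = "calibration_point")
  cal$mbp0 <- cal$dbp0 + cal$pp0 / 3
  for (ptt in c(200, 230, 250, 280, 310)) {
    expect_equal(chen_sbp(ptt, cal),
                 cal$sbp0 - 2 / (cal$gamma_cal * cal$ptt0) *
                   (ptt - cal$ptt0), tolerance = 1e-9)
    pp <- poon_bp(ptt, cal)
    expect_equal(unname(pp[, "sbp"]),
                 cal$mbp0 + (2 / cal$gamma_cal) * log(cal$ptt0 / ptt) +
                   (2 / 3) * cal$pp0 * (cal$ptt0 / ptt)^2,
                 tolerance = 1e-9)
    expect_equal(unname(pp[, "dbp"]),
                 cal$mbp0 + (2 / cal$gamma_cal) * log(cal$ptt0 / ptt) -
                   (1 / 3) * cal$pp0 * (cal$ptt0 / ptt)^2,
                 tolerance = 1e-9)
    for (pir in c(1.2, 1.8, 2.5)) {
      dd <- ding_bp(ptt, pir, cal)
      expect_equal(unname(dd[, "dbp"]), cal$dbp0 * cal$pir0 / pir,
                   tolerance = 1e-9)
      expect_equal(unname(dd[, "sbp"]),
                   cal$dbp0 * cal$pir0 / pir +
                     cal$pp0 * (cal$ptt0 / ptt)^2, tolerance = 1e-9)
    }
  }
})

test_that("pulse intensity ratio is the in-beat peak over preceding valley", {
  fs <- 1000
  # beats at 0, 1000, 2000 ms; each interval holds a valley of exactly 1
  # then a peak of exactly 2
  ppg <- rep(1.5, 3000)
  for (r in c(1, 1001, 2001)) {
    ppg[r + 200] <- 1
    ppg[r + 500] <- 2
  }
  pir <- compute_pir(ppg, c(0, 1000, 2000), fs)
  expect_equal(pir$pir[1:2], c(2, 2))

  # suppressed pulse: swing collapses, beat flagged invalid
  ppg2 <- ppg
  ppg2[1001:2000] <- 1.5
  pir2 <- compute_pir(ppg2, c(0, 1000, 2000), fs)
  expect_false(pir2$valid[2])
  expect_true(pir2$valid[1])

  # non-positive valley (baseline removed) cannot yield a ratio
  pir3 <- compute_pir(ppg - 1.5, c(0, 1000, 2000), fs)
  expect_false(any(pir3$valid[1:2]))
})

test_that("linear regression variants recover coefficients and nest properly", {
  set.seed(9)
  rows <- make_rows(300)
  rows$ref_sbp <- 150 - 0.2 * rows$ptt + 0.01 * rows$rri
  rows$ref_dbp <- 90 - 0.1 * rows$ptt + 0.005 * rows$rri
  fit <- mlr_fit(rows, "no_bcg")
  expect_equal(unname(fit$coef_sbp), c(150, -0.2, 0.01), tolerance = 1e-6)
  expect_equal(unname(fit$coef_dbp), c(90, -0.1, 0.005), tolerance = 1e-6)

  # nested-model training error: richer feature sets cannot fit worse
  rows2 <- make_rows(400, seed = 10)
  rows2$ref_sbp <- 150 - 0.2 * rows2$ptt + 0.05 * rows2$rji +
    rnorm(400, 0, 2)
  mse <- function(fit, rws) {
    p <- mlr_predict(fit, rws)
    mean((p[, "sbp"] - attr(p, "ref")[, "sbp"])^2)
  }
  f_no <- mlr_fit(rows2, "no_bcg")
  f_with <- mlr_fit(rows2, "with_bcg")
  expect_lte(mse(f_with, rows2), mse(f_no, rows2) + 1e-10)

  f_l1 <- mlr_fit(rows2, "lagged", n_lags = 1)
  f_l10 <- mlr_fit(rows2, "lagged", n_lags = 10)
  # compare on the lag-10 target rows, where both models are defined
  p10 <- mlr_predict(f_l10, rows2)
  p1 <- mlr_predict(f_l1, rows2)
  common <- (nrow(rows2) - nrow(p10) + 1):nrow(p1)
  mse10 <- mean((p10[, "sbp"] - attr(p10, "ref")[, "sbp"])^2)
  mse1 <- mean((p1[common, "sbp"] - attr(p1, "ref")[common, "sbp"])^2)
  expect_lte(mse10, mse1 + 1e-10)

  # collinear design is reported, naming the offending columns
  rows3 <- make_rows(100)
  rows3$rji <- rows3$ptt
  expect_error(mlr_fit(rows3, "with_bcg"), "collinear")
})
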