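test_that("regression metrics satisfy identities and match a brute-force oracle", {
  x <- c(100, 110, 120, 115, 108)
  m <- regression_metrics(x, x)
  expect_equal(m$mae, 0); expect_equal(m$rmse, 0); expect_equal(m$me, 0)
  expect_equal(m$cc, 1); expect_equal(m$r2, 1)

  m2 <- regression_metrics(x + 2, x)
  expect_equal(m2$mae, 2); expect_equal(m2$rmse, 2); expect_equal(m2$me, 2)
  expect_equal(m2$std_err, 0); expect_equal(m2$cc, 1)

  set.seed(3)
  est <- rnorm(100, 110, 8); ref <- rnorm(100, 110, 8)
  m3 <- regression_metrics(est, ref)
  err <- est - ref
  # independent elementwise recomputation
  expect_equal(m3$mae, sum(abs(err)) / 100, tolerance = 1e-12)
  expect_equal(m3$rmse, sqrt(sum(err^2) / 100), tolerance = 1e-12)
  expect_equal(m3$me, sum(err) / 100, tolerance = 1e-12)
  expect_equal(m3$std_err, sqrt(sum((err - mean(err))^2) / 99),
               tolerance = 1e-12)
  expect_equal(m3$cc,
               sum((est - mean(est)) * (ref - mean(ref))) /
                 sqrt(sum((est - mean(est))^2) * sum((ref - mean(ref))^2)),
               tolerance = 1e-12)
  expect_equal(m3$r2, 1 - sum(err^2) / sum((ref - mean(ref))^2),
               tolerance = 1e-12)

  expect_warning(mz <- regression_metrics(est, rep(110, 100)), "variance")
  expect_true(is.na(mz$cc))
})

test_that("Bland-Altman limits are bias +/- 1.96 sample SD, symmetric", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ba0), c(bias = 0, lower = 0, upper = 0))

  ba <- bland_altman(c(-1, 1), c(0, 0))
  s <- sqrt(2) # sample SD of {-1, +1}
  expect_equal(ba$bias, 0)
  expect_equal(ba$lower, -1.96 * s)
  expect_equal(ba$upper, 1.96 * s)

  set.seed(4)
  bar <- bland_altman(rnorm(50, 110, 5), rnorm(50, 110, 5))
  expect_equal(bar$upper - bar$bias, bar$bias - bar$lower,
               tolerance = 1e-12)
})

# independent brute-force grader over the published threshold table
brute_bhs <- function(abs_err) {
  p5 <- 100 * sum(abs_err <= 5) / length(abs_err)
  p10 <- 100 * sum(abs_err <= 10) / length(abs_err)
  p15 <- 100 * sum(abs_err <= 15) / length(abs_err)
  if (p5 >= 60 && p10 >= 85 && p15 >= 95) "A"
  else if (p5 >= 50 && p10 >= 75 && p15 >= 90) "B"
  else if (p5 >= 40 && p10 >= 65 && p15 >= 85) "C"
  else "D"
}

test_that("BHS grading reproduces the threshold table including boundaries", {
  g0 <- bhs_grade(rep(0, 10))
  expect_equal(g0$grade, "A")
  expect_equal(c(g0$pct5, g0$pct10, g0$pct15), c(100, 100, 100))

  # exact grade-A boundary: 60 / 85 / 95 percent
  errs <- c(rep(0, 60), rep(7, 25), rep(12, 10), rep(20, 5))
  gA <- bhs_grade(errs)
  expect_equal(c(gA$pct5, gA$pct10, gA$pct15), c(60, 85, 95))
  expect_equal(gA$grade, "A")

  # (59, 90, 99): fails A on the first threshold, meets all of B
  errs2 <- c(rep(0, 59), rep(7, 31), rep(12, 9), rep(20, 1))
  gB <- bhs_grade(errs2)
  expect_equal(gB$grade, "B")

  set.seed(5)
  for (i in 1:25) {
    e <- abs(rnorm(40, 0, runif(1, 2, 12)))
    g <- bhs_grade(e)
    expect_equal(g$grade, brute_bhs(e))
    expect_true(g$pct5 <= g$pct10 && g$pct10 <= g$pct15)
    # shrinking every error never worsens the grade
    g_shrunk <- bhs_grade(e * runif(1, 0.2, 0.9))
    expect_lte(match(g_shrunk$grade, c("A", "B", "C", "D")),
               match(g$grade, c("A", "B", "C", "D")))
  }
})

test_that("AAMI verdict applies mean-error and SD limits inclusively", {
  # construct n = 2 samples with exact mean and SD
  make <- function(me, s) me + c(-1, 1) * s / sqrt(2)
  a <- aami_check(make(-0.09, 3.15))
  expect_equal(a$me, -0.09)
  expect_equal(a$std, 3.15)
  expect_true(a$pass)

  expect_false(aami_check(make(5.01, 1))$pass)
  expect_true(aami_check(make(5.00, 8.00))$pass) # boundaries inclusive
  expect_false(aami_check(make(0, 8.01))$pass)

  ok <- aami_check(make(0, 1), n_subjects = 50)
  expect_true(ok$pass)
  expect_false(ok$population_ok)
  expect_true(aami_check(make(0, 1), n_subjects = 85)$population_ok)
})

test_that("hypertension bins are left-closed at the published cut points", {
  expect_equal(as.character(classify_hypertension(125, "sbp")),
               "Prehypertension")
  expect_equal(as.character(classify_hypertension(c(119, 120, 130, 140),
                                                  "sbp")),
               c("Normal", "Prehypertension", "Stage1", "Stage2"))
  expect_equal(as.character(classify_hypertension(c(79, 80, 90), "dbp")),
               c("Normal", "Stage1", "Stage2"))

  ref <- c(110, 125, 135, 150)
  acc <- class_accuracy(classify_hypertension(ref, "sbp"),
                        classify_hypertension(ref, "sbp"))
  expect_equal(acc$total, 1)
  expect_true(all(acc$per_class == 1))
})

test_that("evaluation reports serialize losslessly", {
  set.seed(6)
  pred <- cbind(sbp = rnorm(60, 112, 6), dbp = rnorm(60, 68, 4))
  ref <- pred + cbind(rnorm(60, 0, 3), rnorm(60, 0, 2))
  rep1 <- eval_report(pred, ref, n_subjects = 6)
  path <- tempfile(fileext = ".json")
  write_eval_report(rep1, path)
  rep2 <- read_eval_report(path)
  for (k in c("sbp", "dbp")) {
    expect_equal(rep2[[k]]$mae, rep1[[k]]$mae, tolerance = 1e-12)
    expect_equal(rep2[[k]]$rmse, rep1[[k]]$rmse, tolerance = 1e-12)
    expect_equal(rep2[[k]]$bhs$grade, rep1[[k]]$bhs$grade)
    expect_equal(rep2[[k]]$bland_altman$upper,
                 rep1[[k]]$bland_altman$upper, tolerance = 1e-12)
    expect_equal(rep2[[k]]$aami$pass, rep1[[k]]$aami$pass)
  }
})

test_that("sequence-length sweep reports coverage and per-length accuracy", {
  coh <- generate_cohort(1, 0, cohort_config(duration_s = 150), seed = 81)
  rows <- record_features(coh[[1]], from = "truth")
  cfg <- train_config(max_epochs = 3, patience = 3, n_runs = 1, seed = 82)
  sw <- sequence_length_sweep(rows, lengths = c(1L, 5L), config = cfg,
                              min_sequences = 50L)
  expect_equal(sw$length, c(1L, 5L))
  expect_true(all(diff(sw$coverage) <= 0))
  expect_true(all(sw$mae_sbp > 0))
  # a length far beyond the data is skipped with a warning
  expect_warning(
    sw2 <- sequence_length_sweep(rows, lengths = c(5L, 2000L),
                                 config = cfg, min_sequences = 50L),
    "skipped")
  expect_equal(sw2$length, 5L)
})
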