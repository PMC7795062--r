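#' Regression metrics between estimated and reference BP
#'
#' @param est,ref equal-length numeric vectors (mmHg), `n >= 2`.
#' @return list with `mae`, `rmse`, `me` (mean error), `std_err` (sample
#'   SD of errors, n-1 denominator), `cc` (Pearson correlation; `NA` with
#'   a warning when the reference has zero variance), `r2`
#'   (`1 - SSres/SStot`) and `n`.
#' @export
regression_metrics <- function(est, ref) {
  stopifnot(length(est) == length(ref), length(est) >= 2)
  err <- est - ref
  cc <- if (sd(ref) == 0 || sd(est) == 0) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else cor(est, ref)
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), me = mean(err),
       std_err = sd(err), cc = cc,
       r2 = if (sd(ref) == 0) NA_real_ else
         1 - sum(err^2) / sum((ref - mean(ref))^2),
       n = length(err))
}

#' Bland-Altman limits of agreement
#'
#' @param est,ref paired measurements (`n >= 2`).
#' @return list with `bias` (mean difference) and `lower`/`upper`
#'   (`bias -/+ 1.96 * SD` of the differences, sample SD).
#' @export
bland_altman <- function(est, ref) {
  stopifnot(length(est) == length(ref), length(est) >= 2)
  d <- est - ref
  s <- sd(d)
  list(bias = mean(d), lower = mean(d) - 1.96 * s,
       upper = mean(d) + 1.96 * s)
}

#' BHS grade from absolute errors
#'
#' Cumulative percentages of absolute errors at or under 5, 10 and 15
#' mmHg; the grade is the best of A (>= 60/85/95), B (>= 50/75/90),
#' C (>= 40/65/85) whose three thresholds are met simultaneously
#' (inclusive boundaries), else D.
#'
#' @param abs_errors vector of absolute errors (mmHg), `n >= 1`.
#' @return list with `pct5`, `pct10`, `pct15` (percent) and `grade`.
#' @export
bhs_grade <- function(abs_errors) {
  stopifnot(length(abs_errors) >= 1)
  p <- c(pct5 = 100 * mean(abs_errors <= 5),
         pct10 = 100 * mean(abs_errors <= 10),
         pct15 = 100 * mean(abs_errors <= 15))
  req <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "D"
  for (g in c("C", "B", "A")) if (all(p >= req[[g]])) grade <- g
  list(pct5 = unname(p[1]), pct10 = unname(p[2]), pct15 = unname(p[3]),
       grade = grade)
}

#' AAMI criterion check
#'
#' Passes when `|mean error| <= 5` mmHg and error SD `<= 8` mmHg. The
#' separate population criterion (`n >= 85` subjects) is reported as
#' `population_ok` but does not gate `pass`.
#'
#' @param errors signed errors (mmHg), `n >= 2`.
#' @param n_subjects number of subjects behind the errors (for the
#'   population criterion).
#' @return list with `me`, `std`, `pass`, `population_ok`.
#' @export
aami_check <- function(errors, n_subjects = NA_integer_) {
  stopifnot(length(errors) >= 2)
  me <- mean(errors); std <- sd(errors)
  list(me = me, std = std, pass = abs(me) <= 5 && std <= 8,
       population_ok = !is.na(n_subjects) && n_subjects >= 85)
}

#' Classify BP values into hypertension categories
#'
#' SBP bins: Normal `< 120`, Prehypertension `[120, 130)`, Stage 1
#' `[130, 140)`, Stage 2 `>= 140`. DBP bins: Normal `< 80`, Stage 1
#' `[80, 90)`, Stage 2 `>= 90` (no prehypertension band for DBP).
#'
#' @param values BP values (mmHg).
#' @param target `"sbp"` or `"dbp"`.
#' @return factor of class labels.
#' @export
classify_hypertension <- function(values, target = c("sbp", "dbp")) {
  target <- match.arg(target)
  if (target == "sbp") {
    cut(values, c(-Inf, 120, 130, 140, Inf), right = FALSE,
        labels = c("Normal", "Prehypertension", "Stage1", "Stage2"))
  } else {
    cut(values, c(-Inf, 80, 90, Inf), right = FALSE,
        labels = c("Normal", "Stage1", "Stage2"))
  }
}

#' Hypertension classification accuracy
#'
#' @param est_classes,ref_classes factors from [classify_hypertension()].
#' @return list with `per_class` (accuracy within each reference class)
#'   and `total` (beat-weighted overall accuracy).
#' @export
class_accuracy <- function(est_classes, ref_classes) {
  stopifnot(length(est_classes) == length(ref_classes))
  hit <- as.character(est_classes) == as.character(ref_classes)
  per <- tapply(hit, ref_classes, mean)
  list(per_class = per, total = mean(hit))
}

#' Full evaluation report for paired predictions
#'
#' Bundles regression metrics, Bland-Altman limits, BHS grade, AAMI
#' verdict and hypertension-class accuracy for SBP and DBP.
#'
#' @param pred `n x 2` matrix (or data.frame) of predicted `sbp`, `dbp`.
#' @param ref matching reference matrix.
#' @param n_subjects subject count for the AAMI population criterion.
#' @return an `eval_report` list with one entry per target.
#' @export
eval_report <- function(pred, ref, n_subjects = NA_integer_) {
  pred <- as.matrix(pred); ref <- as.matrix(ref)
  out <- lapply(c(sbp = 1L, dbp = 2L), function(k) {
    e <- pred[, k]; r <- ref[, k]
    c(regression_metrics(e, r),
      list(bland_altman = bland_altman(e, r),
           bhs = bhs_grade(abs(e - r)),
           aami = aami_check(e - r, n_subjects),
           hypertension = class_accuracy(
             classify_hypertension(e, c("sbp", "dbp")[k]),
             classify_hypertension(r, c("sbp", "dbp")[k]))))
  })
  structure(out, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  for (k in names(x)) {
    m <- x[[k]]
    cat(sprintf(
      "%s: MAE %.2f RMSE %.2f CC %.2f R2 %.2f | ME %.2f STD %.2f | BHS %s | AAMI %s\n",
      toupper(k), m$mae, m$rmse, m$cc, m$r2, m$me, m$std_err, m$bhs$grade,
      if (m$aami$pass) "pass" else "fail"))
  }
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' @param report an [eval_report()].
#' @param path JSON file path.
#' @return `read_eval_report` returns the restored `eval_report`.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in names(x)) x[[k]]$hypertension$per_class <-
    unlist(x[[k]]$hypertension$per_class)
  structure(x, class = "eval_report")
}

#' Sequence-length sweep
#'
#' Re-assembles sequences, retrains the regressor and evaluates it for
#' each requested sequence length on a fixed split policy, reporting test
#' MAE and data coverage per length. Lengths with too little data are
#' skipped with a warning.
#'
#' @param rows a `beat_features` data.frame for one subject-visit.
#' @param lengths integer vector of sequence lengths.
#' @param config a [train_config()].
#' @param spec_template a [model_spec()] supplying the architecture
#'   (its `seq_len`/`n_features` are overridden per length).
#' @param feature_set see [assemble_sequences()].
#' @param min_sequences minimum usable sequences per length (see
#'   [run_personal()]).
#' @return data.frame with `length`, `coverage`, `mae_sbp`, `mae_dbp`,
#'   `n_seq`.
#' @export
sequence_length_sweep <- function(rows, lengths = c(1L, 5L, 10L),
                                  config = train_config(),
                                  spec_template = model_spec(),
                                  feature_set = "full",
                                  min_sequences = 100L) {
  out <- data.frame()
  for (L in lengths) {
    cov <- compute_coverage(rows, L)
    res <- tryCatch(
      run_personal(rows, config = config, L = L,
                   feature_set = feature_set,
                   spec_template = spec_template,
                   min_sequences = min_sequences),
      error = function(e) {
        warning("length ", L, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) next
    out <- rbind(out, data.frame(
      length = L, coverage = cov,
      mae_sbp = mean(abs(res$pred[, 1] - res$ref[, 1])),
      mae_dbp = mean(abs(res$pred[, 2] - res$ref[, 2])),
      n_seq = nrow(res$pred)))
  }
  out
}
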