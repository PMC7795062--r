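#' Demographics table of a cohort
#'
#' @param records list of `waveform_record`.
#' @return data.frame with one row per distinct subject: `subject`,
#'   `gender`, `age`, `height`, `weight`, `bmi`.
#' @export
subject_table <- function(records) {
  rows <- lapply(records, function(r) {
    s <- r$subject
    data.frame(subject = s$subject_id, gender = s$gender, age = s$age,
               height = s$height, weight = s$weight, bmi = s$bmi)
  })
  df <- do.call(rbind, rows)
  df[!duplicated(df$subject), , drop = FALSE]
}

#' Per-beat features for a whole cohort
#'
#' @param records list of `waveform_record`.
#' @param from `"detected"` or `"truth"` (see [record_features()]).
#' @return row-bound `beat_features` across all records, time-ordered
#'   within each record.
#' @export
cohort_features <- function(records, from = "detected") {
  out <- do.call(rbind, lapply(records, record_features, from = from))
  class(out) <- c("beat_features", "data.frame")
  out
}

# demographic z-scoring stats over (training) subjects
.demo_stats <- function(subj_df) {
  cols <- c("age", "height", "weight", "bmi")
  list(mean = vapply(subj_df[cols], mean, numeric(1)),
       sd = vapply(subj_df[cols], function(x) max(sd(x), 1e-8), numeric(1)))
}

# n_seq x 5 demographics matrix (gender 0/1, then z-scored continuous)
.demo_matrix <- function(subject_ids, subj_df, stats) {
  m <- subj_df[match(subject_ids, subj_df$subject), , drop = FALSE]
  cbind(gender = as.numeric(m$gender == "M"),
        age = (m$age - stats$mean["age"]) / stats$sd["age"],
        height = (m$height - stats$mean["height"]) / stats$sd["height"],
        weight = (m$weight - stats$mean["weight"]) / stats$sd["weight"],
        bmi = (m$bmi - stats$mean["bmi"]) / stats$sd["bmi"])
}

# standardize a sequence array feature-wise
.standardize_x <- function(x, stats) {
  for (f in dimnames(x)[[3]])
    x[, , f] <- (x[, , f] - stats$mean[[f]]) / stats$sd[[f]]
  x
}

# fit standardization stats from the beat rows underlying a set of
# training windows (no validation/test rows enter the stats)
.stats_from_windows <- function(rows, seqs, train_idx) {
  row_idx <- unique(unlist(lapply(seqs$end_row[train_idx], function(e)
    (e - seqs$L + 1L):e)))
  fit_standardization(as.matrix(rows[row_idx, seqs$features, drop = FALSE]),
                      scope = "training windows")
}

# label-free per-subject feature calibration: stats fitted on the first
# `cal_s` seconds of the subject's (training-visit) rows
.calibration_stats <- function(rows_subject, features, cal_s = 60) {
  t0 <- min(rows_subject$beat_time)
  win <- rows_subject[rows_subject$valid &
                        rows_subject$beat_time <= t0 + cal_s * 1000, ,
                      drop = FALSE]
  fit_standardization(as.matrix(win[, features, drop = FALSE]),
                      scope = "calibration window")
}

# z-score feature columns of pooled rows, one stats object per subject
.standardize_rows_by_subject <- function(rows, stats_by_subject, features) {
  for (s in names(stats_by_subject)) {
    i <- rows$subject == s
    rows[i, ] <- apply_standardization(rows[i, , drop = FALSE],
                                       stats_by_subject[[s]])
  }
  rows
}

# average predictions over an ensemble of runs
.predict_avg <- function(models, x, demo = NULL) {
  preds <- lapply(models, predict_bp, x = x, demo = demo)
  Reduce(`+`, preds) / length(preds)
}

.split_indices <- function(n, split, seed) {
  idx <- with_seed(seed, sample.int(n))
  n_tr <- floor(split[1] * n)
  n_va <- floor(split[2] * n)
  list(train = idx[seq_len(n_tr)],
        val = idx[(n_tr + 1):(n_tr + n_va)],
        test = idx[(n_tr + n_va + 1):n])
}

#' Personal (subject-specific) training protocol
#'
#' Randomly splits one subject-visit's sequences 60/20/20 into
#' train/validation/test, standardizes features on the training windows
#' only, trains `config$n_runs` independently initialized models and
#' averages their test predictions. Demographics are not used.
#'
#' @param rows `beat_features` of one subject-visit.
#' @param config a [train_config()].
#' @param L sequence length.
#' @param feature_set see [assemble_sequences()].
#' @param spec_template a [model_spec()]; `seq_len`, `n_features` and
#'   `use_demographics` are overridden.
#' @param min_sequences minimum usable sequences before an
#'   insufficient-data error is raised.
#' @return list with `pred`, `ref` (test-set matrices), `models`, `stats`,
#'   `split` (index partition), `seqs`.
#' @export
run_personal <- function(rows, config = train_config(), L = 10L,
                         feature_set = "full",
                         spec_template = model_spec(),
                         min_sequences = 100L) {
  seqs <- assemble_sequences(rows, L = L, feature_set = feature_set)
  n <- dim(seqs$x)[1]
  if (n < min_sequences)
    stop("insufficient data: ", n, " sequences (< ", min_sequences, ")",
         call. = FALSE)
  sp <- .split_indices(n, config$split, derive_seed(config$seed, 11L))
  stats <- .stats_from_windows(rows, seqs, sp$train)
  x <- .standardize_x(seqs$x, stats)
  spec <- model_spec(seq_len = L, n_features = dim(x)[3],
                     hidden = spec_template$hidden,
                     fc1_units = spec_template$fc1_units,
                     dropout = spec_template$dropout,
                     use_demographics = FALSE)
  dat <- function(i) list(x = x[i, , , drop = FALSE],
                          y = seqs$y[i, , drop = FALSE])
  models <- lapply(seq_len(config$n_runs), function(run) {
    m <- build_model(spec, seed = derive_seed(config$seed, 100L + run))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 200L + run)
    train_model(m, dat(sp$train), dat(sp$val), cfg)
  })
  pred <- .predict_avg(models, x[sp$test, , , drop = FALSE])
  list(pred = pred, ref = seqs$y[sp$test, , drop = FALSE], models = models,
       stats = stats, split = sp, seqs = seqs)
}

#' Leave-one-subject-out training protocol
#'
#' Trains a pooled (general) model, with demographic inputs, on every
#' subject except `excluded_subject`; the excluded subject's data enters
#' neither training, validation nor any standardization statistic.
#' Features are standardized per subject (each training subject's rows are
#' z-scored by that subject's own statistics) so that the pooled model
#' learns the within-subject feature-to-BP relation undiluted by
#' between-subject offsets, while demographics carry the subject-level
#' baseline. When the model is later applied to the excluded subject, that
#' subject's features are calibrated from a label-free 60-second window
#' (see [predict_loso()]). Validation takes 20% of the pooled sequences,
#' stratified by subject.
#'
#' @param rows pooled `beat_features` of the whole cohort (training
#'   visit).
#' @param subjects a [subject_table()] data.frame.
#' @param excluded_subject subject id to hold out.
#' @param config a [train_config()].
#' @inheritParams run_personal
#' @return a `bp_loso` object: `models` (one per run), `stats`,
#'   `demo_stats`, `subjects`, `excluded`, `spec`, `L`, `feature_set`.
#' @export
run_loso <- function(rows, subjects, excluded_subject,
                     config = train_config(), L = 10L,
                     feature_set = "full", spec_template = model_spec()) {
  if (!excluded_subject %in% subjects$subject)
    stop("unknown subject id: ", excluded_subject, call. = FALSE)
  if (length(unique(subjects$subject)) < 2L)
    stop("need at least 2 subjects", call. = FALSE)
  pool <- rows[rows$subject != excluded_subject, , drop = FALSE]
  train_subjects <- subjects[subjects$subject != excluded_subject, ,
                             drop = FALSE]
  feats <- if (length(feature_set) == 1L &&
               feature_set %in% names(FEATURE_SETS))
    FEATURE_SETS[[feature_set]] else feature_set
  stats_by <- lapply(split(pool, pool$subject), function(r)
    fit_standardization(as.matrix(r[r$valid, feats, drop = FALSE]),
                        scope = r$subject[1]))
  poolz <- .standardize_rows_by_subject(pool, stats_by, feats)
  seqs <- assemble_sequences(poolz, L = L, feature_set = feature_set)
  n <- dim(seqs$x)[1]
  if (n < 20L) stop("insufficient pooled data", call. = FALSE)
  # 80/20 train/validation stratified by subject
  va <- integer(0)
  with_seed(derive_seed(config$seed, 21L), {
    for (s in unique(seqs$subject)) {
      i <- which(seqs$subject == s)
      va <- c(va, sample(i, max(1L, floor(0.2 * length(i)))))
    }
  })
  tr <- setdiff(seq_len(n), va)
  x <- seqs$x
  demo_stats <- .demo_stats(train_subjects)
  demo <- .demo_matrix(seqs$subject, train_subjects, demo_stats)
  spec <- model_spec(seq_len = L, n_features = dim(x)[3],
                     hidden = spec_template$hidden,
                     fc1_units = spec_template$fc1_units,
                     dropout = spec_template$dropout,
                     use_demographics = TRUE)
  dat <- function(i) list(x = x[i, , , drop = FALSE],
                          y = seqs$y[i, , drop = FALSE],
                          demo = demo[i, , drop = FALSE])
  models <- lapply(seq_len(config$n_runs), function(run) {
    m <- build_model(spec, seed = derive_seed(config$seed, 300L + run))
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 400L + run)
    train_model(m, dat(tr), dat(va), cfg)
  })
  structure(list(models = models, stats_by_subject = stats_by,
                 demo_stats = demo_stats, subjects = subjects,
                 excluded = excluded_subject, spec = spec, L = L,
                 feature_set = feature_set, features = feats,
                 cal_s = 60,
                 train_fingerprint = sort(seqs$end_beat_time)),
            class = "bp_loso")
}

# assemble + standardize the excluded subject's sequences under a
# per-subject calibration; `stats` defaults to the label-free calibration
# window of `rows_subject` itself (one-day use); pass visit-A stats for
# multi-day use.
.loso_subject_seqs <- function(loso, rows_subject, stats = NULL) {
  if (is.null(stats))
    stats <- .calibration_stats(rows_subject, loso$features, loso$cal_s)
  z <- apply_standardization(rows_subject, stats)
  seqs <- assemble_sequences(z, L = loso$L, feature_set = loso$feature_set)
  demo <- .demo_matrix(seqs$subject, loso$subjects, loso$demo_stats)
  list(seqs = seqs, x = seqs$x, demo = demo, stats = stats)
}

#' Predict with a LOSO model on the excluded subject
#'
#' The excluded subject's features are z-scored with label-free statistics
#' from the recording's first `loso$cal_s` seconds (a deployment-style
#' feature calibration); sequences ending inside that window are excluded
#' from evaluation so no evaluated sequence contributes to its own
#' calibration.
#'
#' @param loso a [run_loso()] result.
#' @param rows_subject `beat_features` of the excluded subject.
#' @param stats optional pre-computed `standardization_stats` (e.g. the
#'   training visit's calibration when testing on a later visit).
#' @return list with `pred`, `ref` matrices.
#' @export
predict_loso <- function(loso, rows_subject, stats = NULL) {
  own_cal <- is.null(stats)
  d <- .loso_subject_seqs(loso, rows_subject, stats)
  i <- seq_len(dim(d$x)[1])
  if (own_cal) {
    t0 <- min(rows_subject$beat_time)
    i <- i[d$seqs$end_beat_time > t0 + loso$cal_s * 1000]
  }
  list(pred = .predict_avg(loso$models, d$x[i, , , drop = FALSE],
                           d$demo[i, , drop = FALSE]),
       ref = d$seqs$y[i, , drop = FALSE])
}

#' Fine-tune a LOSO model on the excluded subject
#'
#' Freezes the recurrent block and retrains only the fully connected head
#' on a random `fraction` (default 20%) of the excluded subject's
#' sequences. A disjoint 20% test portion is reserved; `pred`/`ref` (and
#' `pred_untuned`) are reported on it so tuned and untuned models are
#' compared on identical data.
#'
#' @param loso a [run_loso()] result.
#' @param rows_subject `beat_features` of the excluded subject.
#' @param fraction fraction of the subject's sequences used for tuning.
#' @param config a [train_config()] for the tuning runs.
#' @return list with `models` (tuned, one per run), `pred`, `ref`,
#'   `pred_untuned`, `tune_idx`, `test_idx`.
#' @export
fine_tune <- function(loso, rows_subject, fraction = 0.2,
                      config = train_config(max_epochs = 100L,
                                            patience = 15L,
                                            batch_size = 16L)) {
  stopifnot(fraction > 0, fraction < 1)
  d <- .loso_subject_seqs(loso, rows_subject)
  # sequences ending inside the calibration window stay out of both the
  # tuning and test pools
  t0 <- min(rows_subject$beat_time)
  pool <- which(d$seqs$end_beat_time > t0 + loso$cal_s * 1000)
  n <- length(pool)
  n_tune <- floor(fraction * n)
  if (n_tune < 1L) stop("tuning set is empty", call. = FALSE)
  idx <- pool[with_seed(derive_seed(config$seed, 31L), sample.int(n))]
  tune_idx <- idx[seq_len(n_tune)]
  test_idx <- idx[(n_tune + 1):min(n, n_tune + max(1L, floor(0.2 * n)))]
  tune <- list(x = d$x[tune_idx, , , drop = FALSE],
               y = d$seqs$y[tune_idx, , drop = FALSE],
               demo = d$demo[tune_idx, , drop = FALSE])
  models <- lapply(seq_along(loso$models), function(run) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 500L + run)
    fine_tune_model(loso$models[[run]], tune, cfg)
  })
  list(models = models,
       pred = .predict_avg(models, d$x[test_idx, , , drop = FALSE],
                           d$demo[test_idx, , drop = FALSE]),
       pred_untuned = .predict_avg(loso$models,
                                   d$x[test_idx, , , drop = FALSE],
                                   d$demo[test_idx, , drop = FALSE]),
       ref = d$seqs$y[test_idx, , drop = FALSE],
       tune_idx = tune_idx, test_idx = test_idx)
}

#' Multi-day (inter-visit) evaluation protocol
#'
#' Trains on one visit and tests on the other for a subject with two
#' recordings. `personal`: subject's train-visit data only. `loso`: pooled
#' model without the subject (other subjects' train-visit data).
#' `tuned_loso`: that LOSO model with its head fine-tuned on 20% of the
#' subject's train-visit sequences. Both directions (1 to 2, 2 to 1) are
#' supported; the pooled report concatenates their per-sequence
#' predictions (a sample-size-weighted combination).
#'
#' @param rows pooled `beat_features` of the cohort with a `visit` column
#'   covering both visits.
#' @param subjects a [subject_table()] data.frame.
#' @param subject the subject id under test (must have both visits).
#' @param protocol `"personal"`, `"loso"` or `"tuned_loso"`.
#' @param config a [train_config()].
#' @param tune_config a [train_config()] for the fine-tuning stage; small
#'   tuning sets train best with smaller batches and more epochs (each
#'   epoch is few gradient steps).
#' @param directions subset of `c("1to2", "2to1")`.
#' @inheritParams run_personal
#' @return list of per-direction results (`pred`, `ref`) plus `pooled`.
#' @export
run_multi_day <- function(rows, subjects, subject,
                          protocol = c("personal", "loso", "tuned_loso"),
                          config = train_config(),
                          tune_config = NULL,
                          directions = c("1to2", "2to1"), L = 10L,
                          feature_set = "full",
                          spec_template = model_spec(),
                          min_sequences = 100L) {
  protocol <- match.arg(protocol)
  if (is.null(tune_config)) {
    tune_config <- config
    tune_config$batch_size <- 16L
    tune_config$max_epochs <- max(config$max_epochs, 100L)
    tune_config$patience <- max(config$patience, 15L)
  }
  for (v in 1:2)
    if (!any(rows$subject == subject & rows$visit == v))
      stop("subject ", subject, " is missing visit ", v, call. = FALSE)
  out <- list()
  for (dir in directions) {
    v_train <- if (dir == "1to2") 1L else 2L
    v_test <- 3L - v_train
    rows_train <- rows[rows$subject == subject & rows$visit == v_train, ,
                       drop = FALSE]
    rows_test <- rows[rows$subject == subject & rows$visit == v_test, ,
                      drop = FALSE]
    if (protocol == "personal") {
      res <- run_personal(rows_train, config = config, L = L,
                          feature_set = feature_set,
                          spec_template = spec_template,
                          min_sequences = min_sequences)
      seqs_te <- assemble_sequences(rows_test, L = L,
                                    feature_set = feature_set)
      x_te <- .standardize_x(seqs_te$x, res$stats)
      out[[dir]] <- list(pred = .predict_avg(res$models, x_te),
                         ref = seqs_te$y)
    } else {
      pool <- rows[rows$visit == v_train, , drop = FALSE]
      loso <- run_loso(pool, subjects, subject, config = config, L = L,
                       feature_set = feature_set,
                       spec_template = spec_template)
      # the subject's feature calibration comes from the training visit
      # and is reused, unchanged, on the test visit
      cal <- .calibration_stats(rows_train, loso$features, loso$cal_s)
      if (protocol == "loso") {
        out[[dir]] <- predict_loso(loso, rows_test, stats = cal)
      } else {
        tuned <- fine_tune(loso, rows_train, fraction = 0.2,
                           config = tune_config)
        d_te <- .loso_subject_seqs(loso, rows_test, stats = cal)
        out[[dir]] <- list(
          pred = .predict_avg(tuned$models, d_te$x, d_te$demo),
          ref = d_te$seqs$y)
      }
    }
  }
  out$pooled <- list(pred = do.call(rbind, lapply(out[directions],
                                                  `[[`, "pred")),
                     ref = do.call(rbind, lapply(out[directions],
                                                 `[[`, "ref")))
  out
}
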