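#' Write a waveform record to disk
#'
#' One record becomes three plain-text files in `dir`:
#' `<subject>_v<visit>_signals.csv` (`time_ms, ecg, bcg, ppg`),
#' `<subject>_v<visit>_beats.csv` (per-beat reference BP and ground-truth
#' event times) and `<subject>_v<visit>_meta.json` (demographics,
#' physiology, visit, sampling rate, seed).
#'
#' @param record a `waveform_record`.
#' @param dir output directory (created if missing).
#' @return the three file paths, invisibly.
#' @export
write_record <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_v%d", record$subject$subject_id,
                                 record$visit))
  n <- length(record$ecg)
  sig <- data.frame(time_ms = (seq_len(n) - 1) * 1000 / record$fs,
                    ecg = record$ecg, bcg = record$bcg, ppg = record$ppg)
  utils::write.csv(sig, paste0(stem, "_signals.csv"), row.names = FALSE)
  utils::write.csv(record$truth, paste0(stem, "_beats.csv"),
                   row.names = FALSE)
  meta <- record$subject
  class(meta) <- NULL
  jsonlite::write_json(list(subject = meta, visit = record$visit,
                            fs = record$fs, seed = record$seed),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, c("_signals.csv", "_beats.csv", "_meta.json")))
}

#' Read a waveform record written by [write_record()]
#'
#' @param dir directory containing the record files.
#' @param subject subject id.
#' @param visit visit index.
#' @return the reconstructed `waveform_record`.
#' @export
read_record <- function(dir, subject, visit = 1L) {
  stem <- file.path(dir, sprintf("%s_v%d", subject, visit))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  subj <- meta$subject
  subj_obj <- sim_subject(subject_id = subj$subject_id,
                          gender = subj$gender, age = subj$age,
                          height = subj$height, weight = subj$weight,
                          e0 = subj$e0, gamma_vessel = subj$gamma_vessel,
                          rho = subj$rho, h = subj$h, d = subj$d,
                          l_path = subj$l_path, hr_base = subj$hr_base,
                          sbp_base = subj$sbp_base, dbp_base = subj$dbp_base,
                          rji_base = subj$rji_base,
                          ptt_offset_ms = subj$ptt_offset_ms)
  sig <- utils::read.csv(paste0(stem, "_signals.csv"))
  truth <- utils::read.csv(paste0(stem, "_beats.csv"))
  structure(list(subject = subj_obj, visit = as.integer(meta$visit),
                 fs = meta$fs, ecg = sig$ecg, bcg = sig$bcg, ppg = sig$ppg,
                 truth = truth, seed = meta$seed),
            class = "waveform_record")
}

#' Write / read detected beat events
#'
#' @param events a `beat_events` data.frame.
#' @param path CSV file path.
#' @return `read_events` returns the `beat_events` data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  class(ev) <- c("beat_events", "data.frame")
  ev
}

#' Write / read per-beat feature rows
#'
#' @param rows a `beat_features` data.frame.
#' @param path CSV file path.
#' @return `read_features` returns the `beat_features` data.frame.
#' @export
write_features <- function(rows, path) {
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  rows <- utils::read.csv(path)
  class(rows) <- c("beat_features", "data.frame")
  rows
}

#' Write / read assembled sequences
#'
#' Each sequence is one CSV row: metadata, labels, then the flattened
#' `L x F` matrix in beat-major order (`f1_b1, f2_b1, ..., fF_bL`).
#'
#' @param seqs a `feature_sequences` object.
#' @param path CSV file path.
#' @return `read_sequences` returns the `feature_sequences` object.
#' @export
write_sequences <- function(seqs, path) {
  n <- dim(seqs$x)[1]; L <- seqs$L; nf <- length(seqs$features)
  flat <- matrix(aperm(seqs$x, c(3, 2, 1)), nrow = n, byrow = TRUE)
  colnames(flat) <- paste0(rep(seqs$features, L), "_b",
                           rep(seq_len(L), each = nf))
  df <- data.frame(subject = seqs$subject, visit = seqs$visit,
                   end_beat_time = seqs$end_beat_time,
                   end_row = seqs$end_row,
                   label_sbp = seqs$y[, 1], label_dbp = seqs$y[, 2])
  utils::write.csv(cbind(df, as.data.frame(flat)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  df <- utils::read.csv(path)
  meta_cols <- c("subject", "visit", "end_beat_time", "end_row",
                 "label_sbp", "label_dbp")
  flat_cols <- setdiff(names(df), meta_cols)
  feats <- unique(sub("_b[0-9]+$", "", flat_cols))
  L <- length(flat_cols) / length(feats)
  n <- nrow(df)
  x <- aperm(array(t(as.matrix(df[, flat_cols])),
                   c(length(feats), L, n),
                   dimnames = list(feats, NULL, NULL)), c(3, 2, 1))
  structure(list(x = x, y = cbind(sbp = df$label_sbp, dbp = df$label_dbp),
                 subject = df$subject, visit = df$visit,
                 end_beat_time = df$end_beat_time, end_row = df$end_row,
                 features = feats, L = as.integer(L)),
            class = "feature_sequences")
}
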