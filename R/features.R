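#' @title Per-beat feature names
#' @description The seven per-cycle features: four intervals between
#'   characteristic points (RRI, PTT, RJI, IPI) and three peak amplitudes
#'   (ECG R, BCG J, dPPG).
#' @export
FEATURE_NAMES <- c("rri", "ptt", "rji", "ipi",
                   "ecg_amp", "bcg_amp", "ppg_amp")

#' Named feature subsets for input ablation
#'
#' `ecg` = RRI + ECGamp; `ecg_bcg` adds RJI + BCGamp; `ecg_ppg` adds
#' PTT + PPGamp; `full` uses all seven features.
#' @export
FEATURE_SETS <- list(
  ecg = c("rri", "ecg_amp"),
  ecg_bcg = c("rri", "rji", "ecg_amp", "bcg_amp"),
  ecg_ppg = c("rri", "ptt", "ecg_amp", "ppg_amp"),
  full = c("rri", "ptt", "rji", "ipi", "ecg_amp", "bcg_amp", "ppg_amp"))

#' Extract per-beat features from detected events
#'
#' Computes, per cardiac cycle: RRI (R to previous R), PTT (R to dPPG peak),
#' RJI (R to BCG J peak), IPI (BCG I notch to dPPG peak) and the three peak
#' amplitudes. Rows start from the second beat (RRI needs a predecessor).
#' A row is valid only when every constituent event is present, the source
#' beat passed the plausibility filter, and all intervals are positive;
#' partial quantities are still recorded on invalid rows.
#'
#' @param events a `beat_events` data.frame ([detect_beat_events()]).
#' @param ref_bp data.frame with `beat_time` (ms), `sbp`, `dbp`: the
#'   beatwise reference stream. Each row is labelled with the reference
#'   beat at or nearest after its R peak.
#' @param subject,visit optional identifiers carried on every row.
#' @return a `beat_features` data.frame: `beat_time`, the seven features,
#'   `ref_sbp`, `ref_dbp`, `valid`, `subject`, `visit`.
#' @export
extract_beat_features <- function(events, ref_bp, subject = NA_character_,
                                  visit = NA_integer_) {
  n <- nrow(events)
  if (is.null(n) || n < 2L) {
    out <- data.frame(beat_time = numeric(0), rri = numeric(0),
                      ptt = numeric(0), rji = numeric(0), ipi = numeric(0),
                      ecg_amp = numeric(0), bcg_amp = numeric(0),
                      ppg_amp = numeric(0), ref_sbp = numeric(0),
                      ref_dbp = numeric(0), valid = logical(0),
                      subject = character(0), visit = integer(0))
    class(out) <- c("beat_features", "data.frame")
    return(out)
  }
  idx <- 2:n
  rri <- events$r[idx] - events$r[idx - 1L]
  ptt <- events$dppg[idx] - events$r[idx]
  rji <- events$j[idx] - events$r[idx]
  ipi <- events$dppg[idx] - events$i[idx]
  # label: reference beat at or after this R peak, nearest in time
  lab <- vapply(events$r[idx], function(r) {
    k <- which(ref_bp$beat_time >= r - 1e-9)
    if (length(k)) k[1] else NA_integer_
  }, integer(1))
  valid <- events$valid[idx] & events$valid[idx - 1L] &
    !is.na(rri) & !is.na(ptt) & !is.na(rji) & !is.na(ipi) & !is.na(lab)
  valid <- valid & !is.na(valid)
  pos <- rep(TRUE, length(idx))
  ok <- !is.na(rri) & !is.na(ptt) & !is.na(rji) & !is.na(ipi)
  pos[ok] <- rri[ok] > 0 & ptt[ok] > 0 & rji[ok] > 0 & ipi[ok] > 0
  valid <- valid & pos
  out <- data.frame(
    beat_time = events$r[idx], rri = rri, ptt = ptt, rji = rji, ipi = ipi,
    ecg_amp = events$r_amp[idx], bcg_amp = events$j_amp[idx],
    ppg_amp = events$dppg_amp[idx],
    ref_sbp = ifelse(is.na(lab), NA_real_, ref_bp$sbp[lab]),
    ref_dbp = ifelse(is.na(lab), NA_real_, ref_bp$dbp[lab]),
    valid = valid, subject = subject, visit = visit)
  class(out) <- c("beat_features", "data.frame")
  out
}

#' Extract features from a record via detection or ground truth
#'
#' @param record a `waveform_record`.
#' @param from `"detected"` runs the full detection pipeline;
#'   `"truth"` uses the simulator's ground-truth events (oracle path).
#' @param ... passed to [detect_beat_events()].
#' @return a `beat_features` data.frame.
#' @export
record_features <- function(record, from = c("detected", "truth"), ...) {
  from <- match.arg(from)
  ref <- record$truth[, c("beat_time", "sbp", "dbp")]
  if (from == "detected") {
    ev <- detect_beat_events(record, ...)
  } else {
    tr <- record$truth
    ev <- data.frame(beat = tr$beat, r = tr$r, i = tr$i, j = tr$j,
                     dppg = tr$dppg, r_amp = tr$ecg_amp, j_amp = tr$bcg_amp,
                     dppg_amp = tr$ppg_amp,
                     valid = !is.na(tr$i) & !is.na(tr$j) & !is.na(tr$dppg))
    class(ev) <- c("beat_events", "data.frame")
  }
  extract_beat_features(ev, ref, subject = record$subject$subject_id,
                        visit = record$visit)
}

#' Fit feature standardization statistics
#'
#' Per-feature mean and standard deviation computed on (training) rows
#' only; reuse the returned object on validation/test rows so that no test
#' information leaks into the scaling.
#'
#' @param rows a `beat_features` data.frame (only `valid` rows are used) or
#'   a numeric matrix with named columns.
#' @param features character vector of feature columns.
#' @param scope free-text identifier of what the stats were fitted on.
#' @return a `standardization_stats` list with `mean`, `sd`, `features`.
#' @export
fit_standardization <- function(rows, features = FEATURE_NAMES,
                                scope = "") {
  m <- if (is.matrix(rows)) rows else {
    r <- rows[rows$valid, features, drop = FALSE]
    as.matrix(r)
  }
  if (nrow(m) < 2L) stop("need at least 2 valid rows", call. = FALSE)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv <= 0 | !is.finite(sdv))) {
    bad <- colnames(m)[sdv <= 0 | !is.finite(sdv)]
    stop("degenerate (zero-variance) feature: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = mu, sd = sdv, features = colnames(m),
                 scope = scope), class = "standardization_stats")
}

#' Apply (or invert) feature standardization
#'
#' @param rows `beat_features` data.frame or matrix with the stats'
#'   feature columns.
#' @param stats a [fit_standardization()] result.
#' @param invert undo the transform instead of applying it.
#' @return object of the same shape with transformed feature columns.
#' @export
apply_standardization <- function(rows, stats, invert = FALSE) {
  f <- stats$features
  if (is.matrix(rows)) {
    m <- rows[, f, drop = FALSE]
    m <- if (invert) sweep(sweep(m, 2, stats$sd[f], "*"), 2, stats$mean[f], "+")
    else sweep(sweep(m, 2, stats$mean[f], "-"), 2, stats$sd[f], "/")
    rows[, f] <- m
    return(rows)
  }
  for (k in f) {
    rows[[k]] <- if (invert) rows[[k]] * stats$sd[[k]] + stats$mean[[k]]
    else (rows[[k]] - stats$mean[[k]]) / stats$sd[[k]]
  }
  rows
}

# which row indices terminate a valid L-window (all L rows valid,
# consecutive in time with inter-beat gaps below max_gap_s, same
# subject/visit)
.window_ends <- function(rows, L, max_gap_s = 3) {
  n <- nrow(rows)
  if (n < L) return(integer(0))
  ok <- rows$valid
  eq_or_na <- function(a, b) (!is.na(a) & !is.na(b) & a == b) |
    (is.na(a) & is.na(b))
  same <- c(FALSE, eq_or_na(rows$subject[-1], rows$subject[-n]) &
              eq_or_na(rows$visit[-1], rows$visit[-n]) &
              diff(rows$beat_time) > 0 &
              diff(rows$beat_time) <= max_gap_s * 1000)
  ends <- integer(0)
  run <- 0L
  for (i in seq_len(n)) {
    if (!ok[i]) run <- 0L
    else if (i > 1L && same[i]) run <- run + 1L
    else run <- 1L
    if (run >= L) ends <- c(ends, i)
  }
  ends
}

#' Assemble labelled feature sequences
#'
#' Slides a stride-1 window of `L` consecutive cardiac cycles over the
#' feature rows; a sequence is emitted only when all `L` rows are valid,
#' consecutive, within one subject-visit and free of gaps longer than
#' `max_gap_s`. Each sequence is labelled with the reference SBP/DBP
#' aligned to its final beat (the reference value immediately after the
#' last peak of the window).
#'
#' @param rows a time-ordered `beat_features` data.frame.
#' @param L sequence length in cardiac cycles (>= 1).
#' @param feature_set a name from [FEATURE_SETS] or a character vector of
#'   feature columns.
#' @param max_gap_s maximum allowed gap between consecutive beats (s).
#' @return a `feature_sequences` object: `x` an array
#'   `[n_seq, L, n_features]`, `y` an `n_seq x 2` matrix (SBP, DBP),
#'   `subject`, `visit`, `end_beat_time`, `end_row` vectors, and
#'   `features`, `L` metadata.
#' @export
assemble_sequences <- function(rows, L = 10L, feature_set = "full",
                               max_gap_s = 3) {
  if (!is.numeric(L) || L < 1) stop("L must be >= 1", call. = FALSE)
  L <- as.integer(L)
  feats <- if (length(feature_set) == 1L && feature_set %in% names(FEATURE_SETS))
    FEATURE_SETS[[feature_set]] else feature_set
  stopifnot(all(feats %in% names(rows)))
  ends <- .window_ends(rows, L, max_gap_s)
  nf <- length(feats)
  x <- array(NA_real_, dim = c(length(ends), L, nf),
             dimnames = list(NULL, NULL, feats))
  fm <- as.matrix(rows[, feats, drop = FALSE])
  for (s in seq_along(ends)) {
    x[s, , ] <- fm[(ends[s] - L + 1L):ends[s], , drop = FALSE]
  }
  y <- cbind(sbp = rows$ref_sbp[ends], dbp = rows$ref_dbp[ends])
  structure(list(x = x, y = y, subject = rows$subject[ends],
                 visit = rows$visit[ends],
                 end_beat_time = rows$beat_time[ends], end_row = ends,
                 features = feats, L = L),
            class = "feature_sequences")
}

#' @export
print.feature_sequences <- function(x, ...) {
  cat(sprintf("<feature_sequences: %d sequences of %d beats x %d features>\n",
              dim(x$x)[1], x$L, dim(x$x)[3]))
  invisible(x)
}

#' Subset a feature_sequences object
#' @param seqs a `feature_sequences` object.
#' @param i integer or logical index over sequences.
#' @return the subset `feature_sequences`.
#' @export
subset_sequences <- function(seqs, i) {
  structure(list(x = seqs$x[i, , , drop = FALSE],
                 y = seqs$y[i, , drop = FALSE],
                 subject = seqs$subject[i], visit = seqs$visit[i],
                 end_beat_time = seqs$end_beat_time[i],
                 end_row = seqs$end_row[i],
                 features = seqs$features, L = seqs$L),
            class = "feature_sequences")
}

#' Combine feature_sequences objects
#' @param ... `feature_sequences` objects with identical `L` and features.
#' @return the concatenated `feature_sequences`.
#' @export
bind_sequences <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], "feature_sequences")) xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  L <- xs[[1]]$L; feats <- xs[[1]]$features
  for (s in xs) stopifnot(s$L == L, identical(s$features, feats))
  n <- sum(vapply(xs, function(s) dim(s$x)[1], numeric(1)))
  x <- array(NA_real_, dim = c(n, L, length(feats)),
             dimnames = list(NULL, NULL, feats))
  y <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("sbp", "dbp")))
  subject <- character(n); visit <- integer(n)
  ebt <- numeric(n); er <- integer(n)
  at <- 0L
  for (s in xs) {
    k <- dim(s$x)[1]
    if (k) {
      x[(at + 1):(at + k), , ] <- s$x
      y[(at + 1):(at + k), ] <- s$y
      subject[(at + 1):(at + k)] <- s$subject
      visit[(at + 1):(at + k)] <- s$visit
      ebt[(at + 1):(at + k)] <- s$end_beat_time
      er[(at + 1):(at + k)] <- s$end_row
    }
    at <- at + k
  }
  structure(list(x = x, y = y, subject = subject, visit = visit,
                 end_beat_time = ebt, end_row = er,
                 features = feats, L = L), class = "feature_sequences")
}

#' Sequence coverage of a feature-row set
#'
#' Fraction of beats that terminate a valid `L`-cycle sequence; decreases
#' as `L` grows because longer windows are more likely to include an
#' undetected beat.
#'
#' @param rows a `beat_features` data.frame.
#' @param L sequence length.
#' @param max_gap_s see [assemble_sequences()].
#' @return fraction in `[0, 1]`.
#' @export
compute_coverage <- function(rows, L, max_gap_s = 3) {
  if (!nrow(rows)) stop("rows is empty", call. = FALSE)
  length(.window_ends(rows, L, max_gap_s)) / nrow(rows)
}
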