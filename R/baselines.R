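#' One-point calibration for classical PTT models
#'
#' Computes per-subject calibration constants from an initial window of
#' beats: `sbp0`, `dbp0`, pulse pressure `pp0 = sbp0 - dbp0`, mean pressure
#' `mbp0 = dbp0 + pp0/3`, `ptt0`, `pir0` (when a PIR column is present),
#' and the vessel coefficient `gamma_cal` fitted by least squares of
#' `ln(PTT)` on reference SBP (slope `-gamma/2` under the exponential
#' wall-stiffening model).
#'
#' @param rows a `beat_features` data.frame (valid rows with reference BP);
#'   typically the first 60 s of a recording. May carry a `pir` column.
#' @return a `calibration_point` list.
#' @export
calibrate <- function(rows) {
  r <- rows[rows$valid & !is.na(rows$ref_sbp) & !is.na(rows$ptt), ,
            drop = FALSE]
  if (nrow(r) < 10L)
    stop("need >= 10 valid calibration beats", call. = FALSE)
  sbp0 <- mean(r$ref_sbp); dbp0 <- mean(r$ref_dbp)
  pp0 <- sbp0 - dbp0
  slope <- if (sd(r$ref_sbp) > 0) coef(lm(log(r$ptt) ~ r$ref_sbp))[2] else 0
  structure(list(sbp0 = sbp0, dbp0 = dbp0, pp0 = pp0,
                 mbp0 = dbp0 + pp0 / 3, ptt0 = mean(r$ptt),
                 pir0 = if (!is.null(r$pir)) mean(r$pir, na.rm = TRUE)
                        else NA_real_,
                 gamma_cal = as.numeric(-2 * slope), n = nrow(r)),
            class = "calibration_point")
}

#' Chen linearized PTT model (SBP only)
#'
#' `SBP = SBP0 - (2 / (gamma * PTT0)) * (PTT - PTT0)`: the first-order
#' expansion of the exponential wall model around the calibration point.
#'
#' @param ptt pulse transit time (ms), vectorized.
#' @param calib a [calibrate()] result.
#' @return estimated SBP (mmHg).
#' @export
chen_sbp <- function(ptt, calib) {
  stopifnot(all(ptt > 0))
  calib$sbp0 - (2 / (calib$gamma_cal * calib$ptt0)) * (ptt - calib$ptt0)
}

#' Poon logarithmic PTT model (SBP and DBP)
#'
#' `SBP = MBP0 + (2/gamma) ln(PTT0/PTT) + (2/3) PP0 (PTT0/PTT)^2`,
#' `DBP = MBP0 + (2/gamma) ln(PTT0/PTT) - (1/3) PP0 (PTT0/PTT)^2`,
#' so that `SBP - DBP = PP0 (PTT0/PTT)^2` by construction.
#'
#' @inheritParams chen_sbp
#' @return matrix with columns `sbp`, `dbp` (mmHg).
#' @export
poon_bp <- function(ptt, calib) {
  stopifnot(all(ptt > 0))
  lg <- (2 / calib$gamma_cal) * log(calib$ptt0 / ptt)
  q <- calib$pp0 * (calib$ptt0 / ptt)^2
  cbind(sbp = calib$mbp0 + lg + (2 / 3) * q,
        dbp = calib$mbp0 + lg - (1 / 3) * q)
}

#' Ding PIR + PTT model (SBP and DBP)
#'
#' `DBP = DBP0 * PIR0 / PIR`; `SBP = DBP + PP0 * (PTT0/PTT)^2`.
#'
#' @param ptt pulse transit time (ms).
#' @param pir pulse intensity ratio (dimensionless, > 0).
#' @param calib a [calibrate()] result with a finite `pir0`.
#' @return matrix with columns `sbp`, `dbp` (mmHg).
#' @export
ding_bp <- function(ptt, pir, calib) {
  stopifnot(all(ptt > 0), all(pir > 0), is.finite(calib$pir0))
  dbp <- calib$dbp0 * calib$pir0 / pir
  cbind(sbp = dbp + calib$pp0 * (calib$ptt0 / ptt)^2, dbp = dbp)
}

#' Per-beat pulse intensity ratio from the PPG
#'
#' PIR is the per-beat ratio of the PPG pulse peak value to the preceding
#' valley value, both taken within the beat's R-R interval. The ratio is
#' meaningful only on a signal that keeps its physical (positive)
#' intensity baseline, such as the raw PPG; it is not invariant to
#' baseline shifts, so zero-mean band-passed input will yield invalid
#' beats. Beats whose pulse is missing (peak-to-valley swing under 20% of
#' the rolling median swing) or whose valley is non-positive are flagged
#' invalid.
#'
#' @param ppg PPG signal with its intensity baseline intact.
#' @param r_times sorted R-peak times (ms).
#' @param fs sampling rate (Hz).
#' @return data.frame with `pir` (> 0 where valid) and `valid` per beat.
#' @export
compute_pir <- function(ppg, r_times, fs) {
  n_b <- length(r_times)
  out <- data.frame(pir = rep(NA_real_, n_b), valid = FALSE)
  swing <- rep(NA_real_, n_b)
  pk <- rep(NA_real_, n_b); vl <- rep(NA_real_, n_b)
  for (b in seq_len(n_b)) {
    lo <- round(r_times[b] * fs / 1000) + 1L
    hi <- if (b < n_b) round(r_times[b + 1L] * fs / 1000) else length(ppg)
    if (lo < 1L || hi > length(ppg) || hi <= lo) next
    seg <- ppg[lo:hi]
    kmax <- which.max(seg)
    kmin <- which.min(seg[seq_len(max(kmax - 1L, 1L))]) # valley before peak
    pk[b] <- seg[kmax]; vl[b] <- seg[kmin]
    swing[b] <- pk[b] - vl[b]
  }
  med_swing <- .roll_median(swing)
  for (b in seq_len(n_b)) {
    if (is.na(swing[b]) || is.na(med_swing[b]) || is.na(vl[b])) next
    if (med_swing[b] > 0 && swing[b] < 0.2 * med_swing[b]) next # dropped
    if (vl[b] <= 0) next
    out$pir[b] <- pk[b] / vl[b]
    out$valid[b] <- TRUE
  }
  out
}

#' Fit a multiple linear regression BP model
#'
#' Ordinary least squares fitted independently for SBP and DBP on the
#' interval features: `no_bcg` uses PTT + RRI, `with_bcg` adds RJI + IPI,
#' and `lagged` stacks each `with_bcg` feature at lags 0..N-1 over the
#' previous N cardiac cycles.
#'
#' @param rows a `beat_features` data.frame (valid rows are used).
#' @param variant `"no_bcg"`, `"with_bcg"` or `"lagged"`.
#' @param n_lags lag depth for the lagged variant.
#' @return an `mlr_model` with `fit_sbp`, `fit_dbp`, `variant`, `terms`.
#' @export
mlr_fit <- function(rows, variant = c("no_bcg", "with_bcg", "lagged"),
                    n_lags = 10L) {
  variant <- match.arg(variant)
  df <- .mlr_design(rows, variant, n_lags)
  need <- 2L * (ncol(df) - 2L)
  if (nrow(df) < need)
    stop("need at least ", need, " training rows", call. = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("ref_sbp", "ref_dbp")),
                    drop = FALSE])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1L) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- c("(Intercept)", colnames(x))[-keep]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit_sbp <- lm(df$ref_sbp ~ x)
  fit_dbp <- lm(df$ref_dbp ~ x)
  structure(list(coef_sbp = coef(fit_sbp), coef_dbp = coef(fit_dbp),
                 variant = variant, n_lags = as.integer(n_lags),
                 terms = colnames(x)), class = "mlr_model")
}

.mlr_design <- function(rows, variant, n_lags) {
  r <- rows[rows$valid & complete.cases(rows[, c("ptt", "rri", "rji", "ipi",
                                                 "ref_sbp", "ref_dbp")]), ,
            drop = FALSE]
  feats <- switch(variant, no_bcg = c("ptt", "rri"),
                  with_bcg = c("ptt", "rri", "rji", "ipi"),
                  lagged = c("ptt", "rri", "rji", "ipi"))
  if (variant != "lagged") {
    df <- r[, c(feats, "ref_sbp", "ref_dbp")]
    return(df)
  }
  n <- nrow(r)
  if (n <= n_lags) stop("too few rows for lag depth", call. = FALSE)
  idx <- n_lags:n
  cols <- list()
  for (f in feats) for (lag in 0:(n_lags - 1L))
    cols[[paste0(f, "_lag", lag)]] <- r[[f]][idx - lag]
  df <- as.data.frame(cols)
  df$ref_sbp <- r$ref_sbp[idx]
  df$ref_dbp <- r$ref_dbp[idx]
  df
}

#' Predict from a fitted MLR model
#'
#' @param model an [mlr_fit()] result.
#' @param rows a `beat_features` data.frame.
#' @return matrix with columns `sbp`, `dbp`; one row per usable input row
#'   (attribute `row_index` maps back to `rows`).
#' @export
mlr_predict <- function(model, rows) {
  df <- .mlr_design(rows, model$variant, model$n_lags)
  x <- cbind(1, as.matrix(df[, model$terms, drop = FALSE]))
  out <- cbind(sbp = as.numeric(x %*% model$coef_sbp),
               dbp = as.numeric(x %*% model$coef_dbp))
  attr(out, "ref") <- cbind(sbp = df$ref_sbp, dbp = df$ref_dbp)
  out
}
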