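#' Band-pass filter specification for one channel
#'
#' The standard bands are 0.5-35 Hz for ECG, 4-15 Hz for BCG and 0.5-8 Hz
#' for PPG, realized as a second-order Butterworth filter.
#'
#' @param channel `"ecg"`, `"bcg"` or `"ppg"`; sets the default band.
#' @param low_hz,high_hz band edges (Hz); override the channel default.
#' @param order filter order.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(channel = c("ecg", "bcg", "ppg"),
                        low_hz = NULL, high_hz = NULL, order = 2) {
  channel <- match.arg(channel)
  default <- switch(channel, ecg = c(0.5, 35), bcg = c(4, 15),
                    ppg = c(0.5, 8))
  low_hz <- if (is.null(low_hz)) default[1] else low_hz
  high_hz <- if (is.null(high_hz)) default[2] else high_hz
  structure(list(channel = channel, low_hz = low_hz, high_hz = high_hz,
                 order = order), class = "filter_spec")
}

#' Zero-phase band-pass filtering
#'
#' Applies the Butterworth band-pass forward and backward
#' ([signal::filtfilt()]) so that event timing is preserved; the effective
#' magnitude response is the squared single-pass response. The signal is
#' extended by odd reflection at both ends before filtering (and trimmed
#' after) to confine start-up transients to the padding.
#'
#' @param x numeric signal.
#' @param spec a [filter_spec()].
#' @param fs sampling rate (Hz).
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, spec, fs) {
  if (!(spec$low_hz > 0 && spec$low_hz < spec$high_hz &&
        spec$high_hz < fs / 2))
    stop("invalid band edges: need 0 < low < high < fs/2", call. = FALSE)
  n <- length(x)
  if (n < 3 * ceiling(fs / spec$low_hz))
    stop("signal too short for the filter transient", call. = FALSE)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  p <- min(n - 1L, 3L * ceiling(fs / spec$low_hz))
  head_pad <- 2 * x[1] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(p + 1L):(p + n)]
}

# Local-maximum test at index i (strict against at least one neighbour,
# non-strict against the other, so plateaus of width 2 still count).
.is_local_max <- function(x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(FALSE)
  (x[i] > x[i - 1L] && x[i] >= x[i + 1L]) ||
    (x[i] >= x[i - 1L] && x[i] > x[i + 1L])
}

#' Detect ECG R peaks (Pan-Tompkins)
#'
#' Implements the Pan-Tompkins stages: 5-15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, then adaptive
#' signal/noise thresholding with a 200 ms refractory period and a
#' search-back pass at half threshold when an expected beat is missed.
#' Each detection is refined to the local maximum of the input ECG within
#' +/- 100 ms.
#'
#' @param ecg filtered ECG signal.
#' @param fs sampling rate (Hz).
#' @return numeric vector of R-peak times in ms (empty, with a warning, if
#'   nothing is found).
#' @export
detect_r_peaks <- function(ecg, fs) {
  if (length(ecg) < 2 * fs) stop("need at least 2 s of ECG", call. = FALSE)
  if (all(abs(ecg - ecg[1]) < 1e-12)) {
    warning("flat ECG: no R peaks found")
    return(numeric(0))
  }
  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, ecg))
  # five-point derivative (1/8)[-1 -2 0 2 1] as in the original algorithm
  d <- stats::filter(y, c(1, 2, 0, -2, -1) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- round(0.150 * fs)
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  refr <- round(0.200 * fs)
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) {
    warning("no R peaks found")
    return(numeric(0))
  }
  spki <- max(mwi[seq_len(min(length(mwi), 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(length(mwi), 2 * fs))]) * 0.5
  peaks <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  i <- 1L
  while (i <= length(cand)) {
    p <- cand[i]
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[p] >= thr && (p - last) > refr) {
      # search-back: if the gap since the last beat is long, rescan it
      if (length(rr_hist) >= 2 && is.finite(last)) {
        rr_avg <- mean(utils::tail(rr_hist, 8))
        if ((p - last) > 1.66 * rr_avg) {
          back <- cand[cand > last + refr & cand < p]
          back <- back[mwi[back] >= thr / 2]
          if (length(back)) {
            bb <- back[which.max(mwi[back])]
            rr_hist <- c(rr_hist, bb - last)
            peaks <- c(peaks, bb)
            last <- bb
          }
        }
      }
      if (length(peaks)) rr_hist <- c(rr_hist, p - last)
      peaks <- c(peaks, p)
      last <- p
      spki <- 0.125 * mwi[p] + 0.875 * spki
    } else if (mwi[p] >= thr && (p - last) <= refr) {
      # within refractory: keep the larger of the two
      if (length(peaks) && mwi[p] > mwi[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- p
        last <- p
      }
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    i <- i + 1L
  }
  if (!length(peaks)) {
    warning("no R peaks found")
    return(numeric(0))
  }
  # refine to the local ECG maximum near each integrated-signal peak
  half <- round(0.100 * fs)
  ref <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p) - half)
    hi <- min(length(ecg), as.integer(p) + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, numeric(1))
  ref <- sort(unique(ref))
  ref <- ref[c(TRUE, diff(ref) > refr)]
  (ref - 1L) * 1000 / fs
}

#' Detect BCG J peaks
#'
#' For each R peak, returns the time of the maximum BCG sample in the
#' half-open window `(R + 110, R + 250]` ms. A beat is flagged invalid when
#' the window runs off the record or the window maximum is not a local
#' maximum of the signal.
#'
#' @param bcg filtered BCG signal.
#' @param r_times sorted R-peak times (ms).
#' @param fs sampling rate (Hz).
#' @return data.frame with `time` (ms), `amp`, `valid` per beat.
#' @export
detect_j_peaks <- function(bcg, r_times, fs) {
  stopifnot(!is.unsorted(r_times))
  n <- length(bcg)
  out <- data.frame(time = rep(NA_real_, length(r_times)),
                    amp = NA_real_, valid = FALSE)
  for (b in seq_along(r_times)) {
    lo <- floor((r_times[b] + 110) * fs / 1000) + 2L # strictly > R+110
    hi <- floor((r_times[b] + 250) * fs / 1000) + 1L # <= R+250
    if (lo < 1L || hi > n || hi <= lo) next
    k <- lo + which.max(bcg[lo:hi]) - 1L
    if (!.is_local_max(bcg, k)) next
    out$time[b] <- (k - 1L) * 1000 / fs
    out$amp[b] <- bcg[k]
    out$valid[b] <- TRUE
  }
  out
}

#' Detect BCG I notches
#'
#' The I notch is taken as the nearest local minimum of the BCG preceding
#' each J peak by at most 100 ms; beats with no such minimum are flagged
#' invalid.
#'
#' @param bcg filtered BCG signal.
#' @param j_times J-peak times (ms; `NA` allowed).
#' @param fs sampling rate (Hz).
#' @return data.frame with `time` (ms), `valid` per beat.
#' @export
detect_i_notches <- function(bcg, j_times, fs) {
  n <- length(bcg)
  out <- data.frame(time = rep(NA_real_, length(j_times)), valid = FALSE)
  for (b in seq_along(j_times)) {
    if (is.na(j_times[b])) next
    jk <- round(j_times[b] * fs / 1000) + 1L
    lo <- max(2L, jk - round(0.100 * fs))
    if (jk - 1L <= lo) next
    seg <- lo:(jk - 1L)
    mins <- seg[vapply(seg, function(k)
      k > 1L && k < n && bcg[k] < bcg[k - 1L] && bcg[k] <= bcg[k + 1L],
      logical(1))]
    if (!length(mins)) next
    k <- max(mins) # nearest preceding local minimum
    out$time[b] <- (k - 1L) * 1000 / fs
    out$valid[b] <- TRUE
  }
  out
}

#' Detect dPPG peaks (steepest PPG upstroke)
#'
#' Differentiates the PPG with a central difference (one-sided at the
#' endpoints, scaled by `fs` to units/s) and, for each R peak, returns the
#' time of the maximum derivative in the window `(R + 100, R + 600]` ms.
#' Ties break to the earliest sample.
#'
#' @param ppg filtered PPG signal.
#' @param r_times sorted R-peak times (ms).
#' @param fs sampling rate (Hz).
#' @return data.frame with `time` (ms), `amp` (dPPG value), `valid`.
#' @export
detect_dppg_peaks <- function(ppg, r_times, fs) {
  stopifnot(!is.unsorted(r_times))
  n <- length(ppg)
  d <- numeric(n)
  if (n >= 3) {
    d[2:(n - 1)] <- (ppg[3:n] - ppg[1:(n - 2)]) * fs / 2
    d[1] <- (ppg[2] - ppg[1]) * fs
    d[n] <- (ppg[n] - ppg[n - 1]) * fs
  }
  out <- data.frame(time = rep(NA_real_, length(r_times)),
                    amp = NA_real_, valid = FALSE)
  for (b in seq_along(r_times)) {
    lo <- floor((r_times[b] + 100) * fs / 1000) + 2L
    hi <- floor((r_times[b] + 600) * fs / 1000) + 1L
    if (lo < 1L || hi > n || hi <= lo) next
    k <- lo + which.max(d[lo:hi]) - 1L # which.max takes the earliest tie
    out$time[b] <- (k - 1L) * 1000 / fs
    out$amp[b] <- d[k]
    out$valid[b] <- TRUE
  }
  out
}

#' Detect all characteristic points of a record
#'
#' Convenience pipeline: band-pass each channel with its standard band,
#' run the R/J/I/dPPG detectors, align the three distal detections to the
#' R beats and apply [plausibility_filter()].
#'
#' @param record a `waveform_record` (or any list with `ecg`, `bcg`, `ppg`,
#'   `fs`).
#' @param apply_filter run [plausibility_filter()] on the result.
#' @param exclusion_list optional integer beat indices to invalidate (the
#'   reproducible replacement for manual false-positive editing).
#' @return a `beat_events` data.frame: per beat `r`, `i`, `j`, `dppg` times
#'   (ms), `r_amp`, `j_amp`, `dppg_amp`, and a logical `valid` flag.
#' @export
detect_beat_events <- function(record, apply_filter = TRUE,
                               exclusion_list = NULL) {
  fs <- record$fs
  ecg_f <- bandpass(record$ecg, filter_spec("ecg"), fs)
  bcg_f <- bandpass(record$bcg, filter_spec("bcg"), fs)
  ppg_f <- bandpass(record$ppg, filter_spec("ppg"), fs)
  r_times <- detect_r_peaks(ecg_f, fs)
  if (!length(r_times))
    return(structure(data.frame(), class = c("beat_events", "data.frame")))
  r_idx <- round(r_times * fs / 1000) + 1L
  jj <- detect_j_peaks(bcg_f, r_times, fs)
  ii <- detect_i_notches(bcg_f, jj$time, fs)
  pp <- detect_dppg_peaks(ppg_f, r_times, fs)
  ev <- data.frame(beat = seq_along(r_times), r = r_times,
                   i = ii$time, j = jj$time, dppg = pp$time,
                   r_amp = ecg_f[r_idx], j_amp = jj$amp, dppg_amp = pp$amp,
                   valid = jj$valid & ii$valid & pp$valid)
  class(ev) <- c("beat_events", "data.frame")
  if (apply_filter) ev <- plausibility_filter(ev, exclusion_list)
  ev
}

# rolling median with window k (odd), edges padded by the nearest value
.roll_median <- function(x, k = 31L) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(rep(median(x, na.rm = TRUE), n))
  half <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    median(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Automated plausibility filter for detected beats
#'
#' Replaces manual false-positive exclusion with reproducible rules: a beat
#' is invalidated when its R-R interval falls outside [300, 2000] ms, its
#' pulse transit time (dPPG - R) falls outside [100, 600] ms, any detected
#' amplitude falls outside 1/5x to 5x its rolling median (31-beat window,
#' catching both artifact spikes and missing pulses), or its index appears
#' in `exclusion_list`. The filter never re-validates a beat.
#'
#' @param events a `beat_events` data.frame from [detect_beat_events()].
#' @param exclusion_list integer beat indices, or a path to a text file of
#'   indices (one per line, `#` comments allowed).
#' @return the filtered `beat_events`.
#' @export
plausibility_filter <- function(events, exclusion_list = NULL) {
  if (!nrow(events)) return(events)
  if (is.character(exclusion_list)) {
    lines <- readLines(exclusion_list, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    exclusion_list <- as.integer(lines[nzchar(trimws(lines))])
  }
  bad <- rep(FALSE, nrow(events))
  rri <- c(NA, diff(events$r))
  bad <- bad | (!is.na(rri) & (rri < 300 | rri > 2000))
  ptt <- events$dppg - events$r
  bad <- bad | (!is.na(ptt) & (ptt < 100 | ptt > 600))
  for (col in c("r_amp", "j_amp", "dppg_amp")) {
    a <- abs(events[[col]])
    med <- .roll_median(a)
    out_of_range <- !is.na(a) & !is.na(med) & med > 0 &
      (a > 5 * med | a < med / 5)
    bad <- bad | out_of_range
  }
  if (length(exclusion_list))
    bad <- bad | events$beat %in% exclusion_list
  events$valid <- events$valid & !bad
  events
}
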