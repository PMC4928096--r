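#' Single-lead ECG trace
#'
#' @param samples amplitude sequence (arbitrary units), finite.
#' @param sampling_rate sampling rate, Hz, > 0.
#' @export
ecg_trace <- function(samples, sampling_rate) {
  if (length(sampling_rate) != 1 || !is.finite(sampling_rate) ||
      sampling_rate <= 0)
    stop("sampling_rate must be a positive scalar")
  if (length(samples) == 0) stop("empty ECG trace")
  if (any(!is.finite(samples))) stop("non-finite ECG samples")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate),
            class = "ecg_trace")
}

#' Detect R peaks in a single-lead ECG (Pan-Tompkins)
#'
#' The classical Pan-Tompkins stages: band-pass filtering (default
#' 5-15 Hz Butterworth, zero phase), five-point derivative, squaring,
#' moving-window integration (~150 ms), and adaptive dual thresholds on
#' the integrated signal with a 200 ms refractory constraint. The fiducial
#' point of each accepted detection is refined to the local maximum of the
#' band-passed signal within +/-100 ms.
#'
#' @param ecg an [ecg_trace()]; `sampling_rate >= 100` Hz and at least 2 s
#'   of signal.
#' @param band band-pass corner frequencies, Hz.
#' @param integration_window integration window, seconds.
#' @param refractory minimum spacing between detections, seconds.
#' @return an [event_series()] of detected beat times, or an empty series
#'   marker (a list with zero times) if nothing is detected.
#' @export
detect_r_peaks <- function(ecg, band = c(5, 15),
                           integration_window = 0.150,
                           refractory = 0.200) {
  if (!inherits(ecg, "ecg_trace")) stop("ecg must be an ecg_trace")
  fs <- ecg$sampling_rate
  if (fs < 100) stop("sampling_rate must be >= 100 Hz")
  x <- ecg$samples
  if (length(x) < 2 * fs) stop("trace shorter than 2 s")

  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  # five-point derivative, squared, moving-window integrated
  der <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  nw <- max(1L, round(integration_window * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / nw, nw), sides = 2))
  mwi[is.na(mwi)] <- 0

  if (max(mwi) <= 0) {
    return(structure(list(event_times = numeric(0),
                          rr_intervals = numeric(0),
                          quality_flags = character(0),
                          t_start = 0,
                          t_end = length(x) / fs),
                     class = "event_series"))
  }

  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  # adaptive dual thresholds (signal / noise running estimates)
  spki <- max(mwi[seq_len(min(length(mwi), 2 * fs))]) / 3
  npki <- mean(mwi[seq_len(min(length(mwi), 2 * fs))]) / 2
  peaks <- integer(0)
  ref_n <- round(refractory * fs)
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[i] >= thr) {
      if (length(peaks) == 0 || (i - peaks[length(peaks)]) >= ref_n) {
        peaks <- c(peaks, i)
        spki <- 0.125 * mwi[i] + 0.875 * spki
      } else if (mwi[i] > mwi[peaks[length(peaks)]]) {
        # stronger peak inside the refractory window replaces the weaker
        peaks[length(peaks)] <- i
        spki <- 0.125 * mwi[i] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) {
    return(structure(list(event_times = numeric(0),
                          rr_intervals = numeric(0),
                          quality_flags = character(0),
                          t_start = 0, t_end = length(x) / fs),
                     class = "event_series"))
  }
  # fiducial refinement on the band-passed signal
  half <- as.integer(round(0.100 * fs))
  fid <- vapply(peaks, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(length(xf), as.integer(i) + half)
    lo + which.max(xf[lo:hi]) - 1L
  }, integer(1))
  fid <- sort(unique(fid))
  fid <- fid[c(TRUE, diff(fid) >= ref_n)]
  times <- (fid - 1) / fs
  if (length(times) < 2) {
    return(structure(list(event_times = times, rr_intervals = numeric(0),
                          quality_flags = rep("ok", length(times)),
                          t_start = 0, t_end = length(x) / fs),
                     class = "event_series"))
  }
  event_series(times, t_start = 0, t_end = length(x) / fs)
}

#' Detect and correct erroneous beats in an R-R series
#'
#' A beat's interval is suspect when its probability under the local
#' predictive inverse-Gaussian density — fitted robustly on the
#' surrounding `window` seconds, excluding the interval itself — falls in
#' an extreme tail (below `tail_quantile` on either side). Suspect short
#' interval pairs whose sum is locally plausible are merged (a spurious
#' detection deleted); suspect long intervals close to a multiple of the
#' local mean are split by inserting beats (missed detections). The
#' procedure is iterated until no further change, so it is idempotent.
#'
#' The correction policy (merge/insert against a predictive-density tail
#' criterion) is this package's own testable stand-in for real-time
#' ectopic-beat preprocessing; it is not a reimplementation of any
#' specific published corrector.
#'
#' @param events an [event_series()] with at least 20 beats.
#' @param tail_quantile per-side tail probability, default 1e-4.
#' @param window local fitting window, seconds, default 90.
#' @return list with `events` (corrected series) and `report`
#'   (counts: `suspect`, `merged`, `inserted`).
#' @export
correct_artifacts <- function(events, tail_quantile = 1e-4, window = 90) {
  if (!inherits(events, "event_series")) stop("events must be an event_series")
  if (length(events$event_times) < 20) stop("need at least 20 beats")
  times <- events$event_times
  flags <- events$quality_flags
  n_merged <- 0L; n_inserted <- 0L; n_suspect <- 0L

  for (pass in 1:10) {
    rr <- diff(times)
    mid <- (times[-1] + times[-length(times)]) / 2
    changed <- FALSE
    j <- 1L
    while (j <= length(rr)) {
      near <- which(abs(mid - mid[j]) <= window / 2)
      near <- setdiff(near, j)
      if (length(near) >= 10) {
        loc <- rr[near]
        mu_hat <- stats::median(loc)
        sd_hat <- max(stats::mad(loc), 1e-4)
        shape_hat <- max(mu_hat^3 / sd_hat^2, 1)
        p <- pinvgauss(rr[j], mu_hat, shape_hat)
        if (p < tail_quantile || p > 1 - tail_quantile) {
          n_suspect <- n_suspect + 1L
          if (p < tail_quantile && j < length(rr) &&
              abs(rr[j] + rr[j + 1] - mu_hat) < 3 * sd_hat + 0.5 * mu_hat) {
            # spurious extra detection: drop the beat between the two
            times <- times[-(j + 1)]
            flags <- flags[-(j + 1)]
            k <- max(1, j)
            flags[min(k + 1, length(flags))] <- "corrected"
            n_merged <- n_merged + 1L
            changed <- TRUE
            break
          }
          if (p > 1 - tail_quantile) {
            m <- round(rr[j] / mu_hat)
            if (m >= 2 && abs(rr[j] / m - mu_hat) < 3 * sd_hat + 0.25 * mu_hat) {
              ins <- times[j] + (1:(m - 1)) * rr[j] / m
              times <- sort(c(times, ins))
              flags <- append(flags, rep("inserted", m - 1), after = j)
              n_inserted <- n_inserted + as.integer(m - 1)
              changed <- TRUE
              break
            }
          }
        }
      }
      j <- j + 1L
    }
    if (!changed) break
  }
  list(events = event_series(times, t_start = events$t_start,
                             t_end = max(events$t_end, times[length(times)]),
                             quality_flags = flags),
       report = list(suspect = n_suspect, merged = n_merged,
                     inserted = n_inserted))
}
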