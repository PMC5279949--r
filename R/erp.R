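# Single-channel ERP preprocessing and N1/P2 quantification.
#
# Pipeline: zero-phase 1-30 Hz band-pass -> amplitude-based artifact
# rejection on the continuous (non-segmented) signal -> 2000 ms epochs from
# -500 ms before first-tone onset -> baseline correction by the -500..-150 ms
# pre-stimulus mean -> grand average per block -> trapezoidal area of the
# average over the component window (N1: 70-130 ms, P2: 150-250 ms after
# first-tone onset), in uV*ms.

N1_WINDOW <- c(0.070, 0.130)
P2_WINDOW <- c(0.150, 0.250)

component_window <- function(component) {
  switch(component, n1 = N1_WINDOW, p2 = P2_WINDOW,
         stop_config("unknown component: ", component))
}

#' Construct a single-channel EEG recording
#'
#' @param samples Numeric amplitude series in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param events Data frame with columns `onset_s` and `kind`
#'   (`"tone1"`/`"tone2"`); onsets must fall inside the recording.
#' @param block_id Optional block identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, events, block_id = NA) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), sampling_rate > 0,
            is.data.frame(events),
            all(c("onset_s", "kind") %in% names(events)))
  dur <- length(samples) / sampling_rate
  if (nrow(events) > 0 &&
      (any(events$onset_s < 0) || any(events$onset_s > dur))) {
    stop_config("event onsets must lie within the recording span")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 events = events, block_id = block_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %.1f s at %g Hz, %d events, block %s\n",
              length(x$samples) / x$sampling_rate, x$sampling_rate,
              nrow(x$events), as.character(x$block_id)))
  invisible(x)
}

#' Zero-phase band-pass filter (1-30 Hz)
#'
#' Butterworth design applied forward and backward (`signal::filtfilt`), so
#' the passband attenuation is the squared magnitude response and the phase
#' is zero (no component-latency shift). Removes DC and slow drift along
#' with high-frequency noise.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Passband edges in Hz.
#' @param order Butterworth order per edge (default 2).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low = 1, high = 30, order = 2L) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs < 100) stop_config("sampling rate too low for a 1-30 Hz passband")
  if (high >= fs / 2) stop_config("passband infeasible for this sampling rate")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  rec$samples <- as.numeric(signal::filtfilt(bf, rec$samples))
  rec
}

# Rolling max/min over a short window via shifted pmax/pmin (O(w * n) with
# small w; windows are ~13 samples at 256 Hz).
roll_range_exceeds <- function(x, w, thresh) {
  n <- length(x)
  if (w >= n) w <- n
  hi <- x[seq_len(n - w + 1L)]
  lo <- hi
  for (k in seq_len(w - 1L)) {
    seg <- x[(1L + k):(n - w + 1L + k)]
    hi <- pmax(hi, seg)
    lo <- pmin(lo, seg)
  }
  which(hi - lo > thresh)  # window start indices
}

mark_spans <- function(n, centers_start, centers_end, pad) {
  # union of [start - pad, end + pad] intervals as a logical mask
  mask <- logical(n)
  if (length(centers_start) == 0L) return(mask)
  lo <- pmax(1L, centers_start - pad)
  hi <- pmin(n, centers_end + pad)
  delta <- integer(n + 1L)
  delta[lo] <- delta[lo] + 1L
  delta[hi + 1L] <- delta[hi + 1L] - 1L
  cumsum(delta)[seq_len(n)] > 0L
}

#' Detect artifacts on the continuous signal
#'
#' Applies three amplitude rules to the non-segmented (filtered) signal and
#' returns the union of their rejection spans:
#' 1. any sample exceeding +/-100 uV rejects +/-300 ms around it;
#' 2. a max-min range above 100 uV within any 50 ms window rejects +/-200 ms
#'    around that window;
#' 3. a difference above 50 uV between adjacent samples rejects +/-300 ms
#'    around the pair.
#'
#' @param rec A (filtered) [eeg_recording()].
#' @param abs_thresh,range_thresh,step_thresh Rule thresholds in uV.
#' @return A `rejection_mask`: logical per-sample flags plus per-rule span
#'   bookkeeping (`spans` data frame with `rule`, `start`, `end` indices).
#' @export
detect_artifacts <- function(rec, abs_thresh = 100, range_thresh = 100,
                             step_thresh = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  fs <- rec$sampling_rate
  n <- length(x)
  pad300 <- round(0.3 * fs)
  pad200 <- round(0.2 * fs)
  w50 <- max(2L, round(0.05 * fs) + 1L)

  hits1 <- which(abs(x) > abs_thresh)
  m1 <- mark_spans(n, hits1, hits1, pad300)

  starts2 <- roll_range_exceeds(x, w50, range_thresh)
  m2 <- mark_spans(n, starts2, starts2 + w50 - 1L, pad200)

  hits3 <- which(abs(diff(x)) > step_thresh)
  m3 <- mark_spans(n, hits3, hits3 + 1L, pad300)

  span_df <- function(mask, rule) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(rule = rule, start = starts[keep], end = ends[keep])
  }
  spans <- rbind(span_df(m1, "abs_100uV"), span_df(m2, "range_100uV_50ms"),
                 span_df(m3, "step_50uV"))
  structure(list(mask = m1 | m2 | m3,
                 spans = spans %||% data.frame(rule = character(),
                                               start = integer(),
                                               end = integer())),
            class = "rejection_mask")
}

#' @export
print.rejection_mask <- function(x, ...) {
  cat(sprintf("<rejection_mask> %d/%d samples rejected (%d spans)\n",
              sum(x$mask), length(x$mask), nrow(x$spans)))
  invisible(x)
}

#' Cut epochs around first-tone onsets and baseline-correct them
#'
#' Epochs span 2000 ms starting 500 ms before each `tone1` onset. Epochs
#' containing any rejected sample, or extending beyond the recording, are
#' dropped. Each surviving epoch has the mean of its -500..-150 ms
#' pre-stimulus period subtracted.
#'
#' @param rec A (filtered) [eeg_recording()].
#' @param mask A [detect_artifacts()] result, or `NULL` for no rejection.
#' @param pre Seconds before onset (default 0.5).
#' @param duration Epoch length in seconds (default 2).
#' @param baseline Baseline interval relative to onset (default
#'   `c(-0.5, -0.15)`).
#' @return List with `epochs` (matrix, one row per surviving epoch), `time_s`
#'   (within-epoch time axis relative to onset), `n_total`, `n_dropped`.
#' @export
epoch_and_baseline <- function(rec, mask = NULL, pre = 0.5, duration = 2,
                               baseline = c(-0.5, -0.15)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  n <- length(rec$samples)
  len <- round(duration * fs)
  pre_n <- round(pre * fs)
  onsets <- rec$events$onset_s[rec$events$kind == "tone1"]
  time_s <- (seq_len(len) - 1L - pre_n) / fs
  base_idx <- which(time_s >= baseline[1] - 1e-9 & time_s <= baseline[2] + 1e-9)
  rej <- if (is.null(mask)) logical(n) else mask$mask
  rows <- list()
  dropped <- 0L
  for (on in onsets) {
    i0 <- round(on * fs) + 1L - pre_n
    i1 <- i0 + len - 1L
    if (i0 < 1L || i1 > n || any(rej[i0:i1])) {
      dropped <- dropped + 1L
      next
    }
    ep <- rec$samples[i0:i1]
    rows[[length(rows) + 1L]] <- ep - mean(ep[base_idx])
  }
  list(epochs = if (length(rows)) do.call(rbind, rows) else
         matrix(numeric(0), 0L, len),
       time_s = time_s, n_total = length(onsets), n_dropped = dropped)
}

# Trapezoidal integral of a sampled curve over a closed time window, mapped
# to nearest-sample indices; returns uV*ms.
trapz_area_ms <- function(y, time_s, window_s, fs) {
  i_lo <- which.min(abs(time_s - window_s[1]))
  i_hi <- which.min(abs(time_s - window_s[2]))
  idx <- i_lo:i_hi
  v <- y[idx]
  sum((v[-1] + v[-length(v)]) / 2) * (1000 / fs)
}

#' Grand-average waveform and component area
#'
#' Averages surviving epochs and integrates the average (trapezoidal rule)
#' over the component window: 70-130 ms post-onset for N1, 150-250 ms for P2.
#'
#' @param ep An [epoch_and_baseline()] result with at least one epoch.
#' @param component `"n1"` or `"p2"`.
#' @param sampling_rate Sampling rate (Hz) of the epochs.
#' @return List with `component`, `area` (uV*ms), `n_epochs`, and the
#'   `average` waveform.
#' @export
average_and_area <- function(ep, component = c("p2", "n1"), sampling_rate) {
  component <- match.arg(component)
  if (nrow(ep$epochs) < 1L) {
    stop(errorCondition("no surviving epochs: block excluded",
                        class = c("memdecay_empty_block", "error")))
  }
  avg <- colMeans(ep$epochs)
  area <- trapz_area_ms(avg, ep$time_s, component_window(component),
                        sampling_rate)
  list(component = component, area = area, n_epochs = nrow(ep$epochs),
       average = avg, time_s = ep$time_s)
}

#' Run the full ERP pipeline on one recording
#'
#' Filter, reject, epoch, baseline, average, and measure both component
#' areas.
#'
#' @param rec An [eeg_recording()] (unfiltered).
#' @param components Components to quantify.
#' @return Data frame with one row per component: `block_id`, `component`,
#'   `area_uv_ms`, `n_epochs`, `n_dropped`.
#' @export
erp_block_areas <- function(rec, components = c("n1", "p2")) {
  filt <- bandpass_filter(rec)
  mask <- detect_artifacts(filt)
  ep <- epoch_and_baseline(filt, mask)
  rows <- lapply(components, function(cmp) {
    aa <- average_and_area(ep, cmp, rec$sampling_rate)
    data.frame(block_id = rec$block_id, component = cmp,
               area_uv_ms = aa$area, n_epochs = aa$n_epochs,
               n_dropped = ep$n_dropped)
  })
  do.call(rbind, rows)
}
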