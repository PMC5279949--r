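# Synthetic single-channel EEG with planted N1/P2 adaptation dynamics.
#
# Each auditory event evokes two fixed-shape raised-cosine deflections: a
# negative one centered 100 ms post-onset (N1, half-width 30 ms, support
# exactly the 70-130 ms analysis window) and a positive one centered 200 ms
# post-onset (P2, half-width 50 ms, support the 150-250 ms window). The
# component's windowed area for an event follows the recovery-from-adaptation
# law
#
#   area(dt) = alpha_gen + beta_gen * exp(-dt / tau_gen)
#
# with dt the time since the previous event (dt = Inf for the first event of
# a block: fully recovered). Additive white Gaussian noise and blink-like
# high-amplitude artifacts complete the signal.

#' Generative parameters for synthetic EEG
#'
#' `n1` and `p2` each carry `alpha` (asymptotic area, uV*ms), `beta`
#' (adaptation magnitude, uV*ms) and `tau` (s). Signs follow the component
#' polarity: P2 has `alpha >= 0, beta <= 0`; N1 `alpha <= 0, beta >= 0`.
#'
#' `area_calibration` selects what "area" means for amplitude scaling:
#' `"pipeline"` (default) plants areas as measured by the full ERP pipeline
#' (band-pass filter, epoching, baseline correction), solving a 2x2 linear
#' system built from the pipeline's unit-kernel responses, so that noise-free
#' round trips land on the generative curve; `"raw"` plants the plain
#' trapezoidal area of the clean kernel over the analysis window. The
#' band-pass filter redistributes a few percent of each kernel's area into
#' neighbouring windows and the baseline, so the two conventions differ by a
#' fixed linear map.
#'
#' @param n1,p2 Lists with `alpha`, `beta`, `tau`.
#' @param noise_sd White-noise SD in uV (default 2).
#' @param artifact_rate Artifact events per minute (default 0.5).
#' @param sampling_rate Hz (default 256).
#' @param area_calibration `"pipeline"` or `"raw"`.
#' @return Object of class `erp_gen_params`.
#' @export
erp_gen_params <- function(n1 = list(alpha = -131, beta = 497, tau = 5.1),
                           p2 = list(alpha = 396, beta = -696, tau = 8.5),
                           noise_sd = 2, artifact_rate = 0.5,
                           sampling_rate = 256,
                           area_calibration = c("pipeline", "raw")) {
  area_calibration <- match.arg(area_calibration)
  check_comp <- function(x, name, a_sign, b_sign) {
    stopifnot(all(c("alpha", "beta", "tau") %in% names(x)))
    if (x$tau <= 0) stop_config(name, ": tau must be > 0")
    if (a_sign * x$alpha < 0 || b_sign * x$beta < 0) {
      stop_config(name, ": alpha/beta signs violate the component polarity")
    }
  }
  check_comp(p2, "p2", +1, -1)
  check_comp(n1, "n1", -1, +1)
  stopifnot(noise_sd >= 0, artifact_rate >= 0, sampling_rate > 0)
  structure(list(n1 = n1, p2 = p2, noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 sampling_rate = sampling_rate,
                 area_calibration = area_calibration),
            class = "erp_gen_params")
}

#' @export
print.erp_gen_params <- function(x, ...) {
  cat(sprintf(
    "<erp_gen_params> N1(%g, %g, %g s) P2(%g, %g, %g s), noise %g uV, %g artifacts/min, %g Hz [%s]\n",
    x$n1$alpha, x$n1$beta, x$n1$tau, x$p2$alpha, x$p2$beta, x$p2$tau,
    x$noise_sd, x$artifact_rate, x$sampling_rate, x$area_calibration))
  invisible(x)
}

KERNEL_SPECS <- list(
  n1 = list(center = 0.100, half_width = 0.030),
  p2 = list(center = 0.200, half_width = 0.050)
)

# Raised-cosine deflection of unit peak amplitude sampled on the recording
# grid; returns indices and values. Continuous-time area of the unit kernel
# equals its half-width (in time units).
kernel_samples <- function(event_onset, comp, fs, n_total) {
  ks <- KERNEL_SPECS[[comp]]
  t0 <- event_onset + ks$center
  i_lo <- max(1L, floor((t0 - ks$half_width) * fs) + 1L)
  i_hi <- min(n_total, ceiling((t0 + ks$half_width) * fs) + 1L)
  if (i_lo > i_hi) return(NULL)
  tt <- (seq(i_lo, i_hi) - 1L) / fs - t0
  v <- ifelse(abs(tt) <= ks$half_width,
              0.5 * (1 + cos(pi * tt / ks$half_width)), 0)
  list(idx = seq(i_lo, i_hi), val = v)
}

# Unit amplitude -> uV*ms area scale of the clean kernel over its own
# analysis window (raw calibration): half-width in ms.
raw_area_scale <- function(comp) KERNEL_SPECS[[comp]]$half_width * 1000

# Measured-area responses of unit-amplitude kernels through the full
# pipeline (filter + epoch + baseline + window integration). The zero-phase
# high-pass spreads a few percent of each kernel's area over roughly +/-1 s,
# so at short SOAs the neighbouring events and the second tones of a trial
# leak into the analysis windows and the baseline. Responses are therefore
# computed in a periodic steady state matching the block's schedule:
#   M[window, kernel] for a train of unit kernels at every first-tone onset,
#   L[window, kernel] for a train of unit kernels at every second-tone onset.
# All matrices are cached per (sampling rate, soa, active) context.
.unit_response_cache <- new.env(parent = emptyenv())

measure_unit_train <- function(fs, onsets, epoch_onsets) {
  n <- round((max(onsets) + 3) * fs)
  M <- matrix(0, 2, 2, dimnames = list(c("n1", "p2"), c("n1", "p2")))
  ev <- data.frame(onset_s = epoch_onsets, kind = "tone1")
  for (comp in c("n1", "p2")) {
    x <- numeric(n)
    for (on in onsets) {
      k <- kernel_samples(on, comp, fs, n)
      if (!is.null(k)) x[k$idx] <- x[k$idx] + k$val
    }
    filt <- bandpass_filter(eeg_recording(x, fs, ev))
    ep <- epoch_and_baseline(filt, NULL)
    avg <- colMeans(ep$epochs)
    for (win in c("n1", "p2")) {
      M[win, comp] <- trapz_area_ms(avg, ep$time_s, component_window(win), fs)
    }
  }
  M
}

pipeline_unit_response <- function(fs, soa = NULL, active = FALSE,
                                   inter_tone = 0.6) {
  key <- paste("fs", fs, "soa", soa %||% "none", "act", active, sep = "_")
  got <- .unit_response_cache[[key]]
  if (!is.null(got)) return(got)
  if (is.null(soa)) {
    # isolated event: self response only
    res <- list(M = measure_unit_train(fs, 6, 6), L = NULL)
  } else {
    n_train <- max(9L, ceiling(3 / soa) * 2L + 5L)
    on1 <- 4 + (seq_len(n_train) - 1L) * soa
    mid <- on1[c(-1L, -n_train)]
    M <- measure_unit_train(fs, on1, mid)
    L <- if (active) measure_unit_train(fs, on1 + inter_tone, mid) else NULL
    res <- list(M = M, L = L)
  }
  .unit_response_cache[[key]] <- res
  res
}

# Solve kernel amplitudes for target (n1, p2) areas under a calibration mode
# and schedule context. `tone2_amps` are the (already chosen) second-tone
# kernel amplitudes whose steady-state leakage is subtracted before solving.
amplitudes_for_areas <- function(target_n1, target_p2, fs, mode,
                                 soa = NULL, active = FALSE,
                                 tone2_amps = NULL) {
  if (mode == "raw") {
    return(c(n1 = target_n1 / raw_area_scale("n1"),
             p2 = target_p2 / raw_area_scale("p2")))
  }
  ur <- pipeline_unit_response(fs, soa, active)
  target <- c(target_n1, target_p2)
  if (!is.null(ur$L) && !is.null(tone2_amps)) {
    target <- target - drop(ur$L %*% tone2_amps)
  }
  a <- unname(solve(ur$M, target))
  c(n1 = a[1], p2 = a[2])
}

#' Generate a synthetic EEG recording for an event schedule
#'
#' @param schedule Data frame with `onset_s` (strictly increasing) and `kind`
#'   (`"tone1"`/`"tone2"`), or a numeric onset vector (all `"tone1"`).
#' @param p An [erp_gen_params()].
#' @param seed Optional RNG seed.
#' @param pad Seconds of recording kept before the first and after the last
#'   event (default 2; must cover the epoch span).
#' @param block_id Optional block identifier.
#' @return An [eeg_recording()].
#' @export
#' @examples
#' p <- erp_gen_params(noise_sd = 0, artifact_rate = 0)
#' rec <- generate_eeg(c(2, 4, 6), p)
#' erp_block_areas(rec)
generate_eeg <- function(schedule, p, seed = NULL, pad = 2, block_id = NA) {
  stopifnot(inherits(p, "erp_gen_params"))
  if (is.numeric(schedule)) {
    schedule <- data.frame(onset_s = schedule, kind = "tone1")
  }
  onsets <- schedule$onset_s
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop_config("schedule onsets must be strictly increasing")
  }
  if (any(diff(onsets) < 0.5)) {
    warning("events closer than 500 ms: component kernels overlap")
  }
  fs <- p$sampling_rate
  t_start <- onsets[1] - pad
  shift <- if (t_start < 0) -t_start else 0
  schedule$onset_s <- onsets + shift
  onsets <- schedule$onset_s
  n <- round((onsets[length(onsets)] + pad) * fs)
  x <- numeric(n)

  dt <- c(Inf, diff(onsets))
  area_at <- function(dt_i) {
    if (is.finite(dt_i)) {
      c(p$n1$alpha + p$n1$beta * exp(-dt_i / p$n1$tau),
        p$p2$alpha + p$p2$beta * exp(-dt_i / p$p2$tau))
    } else {
      c(p$n1$alpha, p$p2$alpha)
    }
  }

  # Steady-state context for pipeline calibration: periodic first-tone grid.
  on1 <- schedule$onset_s[schedule$kind == "tone1"]
  gaps <- diff(on1)
  periodic <- p$area_calibration == "pipeline" && length(gaps) >= 2 &&
    max(gaps) - min(gaps) < 1e-9
  active <- any(schedule$kind == "tone2")
  steady <- NULL
  tone2_amps <- NULL
  if (periodic) {
    soa <- gaps[1]
    if (active) {
      itt <- schedule$onset_s[schedule$kind == "tone2"][1] - on1[1]
      ar2 <- area_at(itt)
      tone2_amps <- amplitudes_for_areas(ar2[1], ar2[2], fs,
                                         p$area_calibration)
    }
    ar1 <- area_at(if (active) soa - (schedule$onset_s[schedule$kind == "tone2"][1] - on1[1]) else soa)
    steady <- amplitudes_for_areas(ar1[1], ar1[2], fs, p$area_calibration,
                                   soa = soa, active = active,
                                   tone2_amps = tone2_amps)
  }

  for (i in seq_len(nrow(schedule))) {
    kind_i <- schedule$kind[i]
    amps <- if (periodic && kind_i == "tone1" && is.finite(dt[i])) {
      steady
    } else if (periodic && kind_i == "tone2") {
      tone2_amps
    } else {
      ar <- area_at(dt[i])
      amplitudes_for_areas(ar[1], ar[2], fs, p$area_calibration)
    }
    for (comp in c("n1", "p2")) {
      k <- kernel_samples(schedule$onset_s[i], comp, fs, n)
      if (!is.null(k)) x[k$idx] <- x[k$idx] + amps[[comp]] * k$val
    }
  }

  with_seed(seed, {
    if (p$noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, p$noise_sd)
    }
    if (p$artifact_rate > 0) {
      dur_min <- n / fs / 60
      n_art <- stats::rpois(1, p$artifact_rate * dur_min)
      if (n_art > 0) {
        at <- stats::runif(n_art, 0.5, n / fs - 0.5)
        for (a in at) {
          # blink-like pulse: 240 ms raised cosine, 150-200 uV, random sign;
          # large enough to exceed the 100 uV rejection threshold even after
          # the 1-30 Hz band-pass.
          amp <- sample(c(-1, 1), 1) * stats::runif(1, 150, 200)
          i_lo <- max(1L, round((a - 0.12) * fs))
          i_hi <- min(n, round((a + 0.12) * fs))
          tt <- (seq(i_lo, i_hi) - 1L) / fs - a
          x[i_lo:i_hi] <- x[i_lo:i_hi] +
            amp * 0.5 * (1 + cos(pi * tt / 0.12))
        }
      }
    }
    eeg_recording(x, fs, schedule, block_id = block_id)
  })
}

#' Event schedule for an active or passive block
#'
#' Active blocks are two-tone trials (second tone `inter_tone` after the
#' first); passive blocks present single tones. `soa` is the onset-to-onset
#' interval between consecutive first tones.
#'
#' @param n_events Number of trials (active) or tones (passive).
#' @param soa Stimulus-onset asynchrony in seconds.
#' @param active Logical: include second tones.
#' @param t0 Onset of the first event (default 2 s).
#' @param inter_tone Within-trial onset gap (s, default 0.6).
#' @return Schedule data frame for [generate_eeg()].
#' @export
block_schedule <- function(n_events, soa, active = TRUE, t0 = 2,
                           inter_tone = 0.6) {
  on1 <- t0 + (seq_len(n_events) - 1L) * soa
  if (!active) {
    return(data.frame(onset_s = on1, kind = "tone1"))
  }
  df <- rbind(data.frame(onset_s = on1, kind = "tone1"),
              data.frame(onset_s = on1 + inter_tone, kind = "tone2"))
  df[order(df$onset_s), ]
}

#' Write / read EEG interchange files
#'
#' The signal goes to a one-column CSV (`uv`), the metadata to a JSON
#' sidecar `{sampling_rate_hz, unit, events:[{onset_s, kind}]}` at
#' `paste0(path, ".json")`.
#'
#' @param rec An [eeg_recording()].
#' @param path CSV path.
#' @export
write_eeg_csv <- function(rec, path) {
  utils::write.csv(data.frame(uv = rec$samples), path, row.names = FALSE)
  side <- list(sampling_rate_hz = rec$sampling_rate, unit = "uV",
               events = rec$events,
               block_id = rec$block_id)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @return `read_eeg_csv()` returns the reconstructed [eeg_recording()].
#' @export
read_eeg_csv <- function(path) {
  x <- utils::read.csv(path)$uv
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  eeg_recording(x, side$sampling_rate_hz, as.data.frame(side$events),
                block_id = side$block_id %||% NA)
}
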