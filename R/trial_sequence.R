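# Two-tone frequency-discrimination trial sequences.
#
# A trial presents tones f1 then f2 (default 600 ms apart, 50 ms each) and the
# listener reports which was higher. Sequences carry per-trial timing so that
# the inter-trial interval (ITI: previous trial's second-tone offset to the
# current first-tone onset) is available to both the observer model and the
# context-effect analysis.

new_trial_sequence <- function(df, design_tag, f_band, df_band,
                               tone_dur, inter_tone) {
  structure(df,
            design_tag = design_tag,
            global_mean_f1 = mean(df$f1_hz),
            f_band = f_band,
            df_band = df_band,
            tone_dur = tone_dur,
            inter_tone = inter_tone,
            class = c("trial_sequence", "data.frame"))
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence:%s> %d trials, f1 in [%.0f, %.0f] Hz, mean f1 = %.1f Hz\n",
              attr(x, "design_tag"), nrow(x), min(x$f1_hz), max(x$f1_hz),
              attr(x, "global_mean_f1")))
  NextMethod()
}

validate_trial_sequence <- function(seq) {
  stopifnot(inherits(seq, "trial_sequence"))
  with(seq, {
    stopifnot(all(f1_hz != f2_hz),
              !is.unsorted(onset1_s, strictly = TRUE),
              all(onset2_s > onset1_s),
              all(is.na(iti_s[1]) | TRUE),
              all(iti_s[-1] > 0))
  })
  invisible(seq)
}

# Draw the comparison tone: a relative difference from df_band (percent), in
# a random direction, applied to the base tone. Only the base tone is
# constrained to the frequency band; the comparison may leave it. Keeping the
# difference direction independent of the base frequency avoids coupling
# trial difficulty to the tone's position in the band, which would otherwise
# induce a spurious context effect even in a prior-blind observer.
draw_comparison <- function(base, df_band) {
  dir <- sample(c(-1, 1), 1L)
  delta <- stats::runif(1, df_band[1], df_band[2])
  base * (1 + dir * delta / 100)
}

#' Generate a random two-tone trial sequence
#'
#' Each trial draws a base tone uniformly from `f_band` and a comparison tone
#' at a relative difference drawn uniformly from `df_band` (percent), in a
#' random direction; the presentation order of the two tones is randomized.
#' Only the base tone is constrained to `f_band`: the comparison may fall
#' slightly outside it, keeping trial difficulty independent of where the
#' base tone sits in the band.
#'
#' @param n Number of trials (>= 1).
#' @param f_band Frequency band in Hz, default `c(800, 1250)`.
#' @param df_band Relative difference band in percent, default `c(1, 30)`.
#' @param iti Inter-trial interval in seconds (previous second-tone offset to
#'   next first-tone onset), default 1.4.
#' @param seed Optional RNG seed; identical seeds give identical sequences.
#' @param tone_dur Tone duration (s), default 0.05.
#' @param inter_tone First-tone-onset to second-tone-onset interval (s),
#'   default 0.6.
#' @return A `trial_sequence` data frame with columns `index`, `f1_hz`,
#'   `f2_hz`, `onset1_s`, `onset2_s`, `iti_s` (`NA` for trial 1).
#' @export
#' @examples
#' s <- generate_random_sequence(5, seed = 1)
#' s$f1_hz
generate_random_sequence <- function(n, f_band = c(800, 1250),
                                     df_band = c(1, 30), iti = 1.4,
                                     seed = NULL, tone_dur = 0.05,
                                     inter_tone = 0.6) {
  stopifnot(n >= 1, iti > 0)
  assert_band(f_band, "f_band")
  assert_band(df_band, "df_band")
  with_seed(seed, {
    base <- stats::runif(n, f_band[1], f_band[2])
    other <- vapply(base, draw_comparison, numeric(1), df_band)
    first_is_base <- stats::runif(n) < 0.5
    f1 <- ifelse(first_is_base, base, other)
    f2 <- ifelse(first_is_base, other, base)
    build_sequence(f1, f2, iti, "random", f_band, df_band, tone_dur, inter_tone)
  })
}

build_sequence <- function(f1, f2, iti, design_tag, f_band, df_band,
                           tone_dur, inter_tone) {
  n <- length(f1)
  iti_s <- c(NA_real_, rep(iti, n - 1L))
  period <- inter_tone + tone_dur + iti
  onset1 <- (seq_len(n) - 1L) * period
  df <- data.frame(index = seq_len(n), f1_hz = f1, f2_hz = f2,
                   onset1_s = onset1, onset2_s = onset1 + inter_tone,
                   iti_s = iti_s)
  validate_trial_sequence(
    new_trial_sequence(df, design_tag, f_band, df_band, tone_dur, inter_tone))
}

#' Phi coefficient of two sign vectors
#'
#' Association between two +/-1 (or logical) vectors via the 2x2 contingency
#' table: `phi = (n11*n00 - n10*n01) / sqrt(prod(margins))`. Returns `NA` when
#' any margin is empty (the coefficient is undefined).
#'
#' @param a,b Vectors of signs (+1/-1) or logicals, equal length.
#' @return The phi coefficient, or `NA_real_` for a degenerate table.
#' @export
phi_coefficient <- function(a, b) {
  a <- as.logical(a > 0)
  b <- as.logical(b > 0)
  stopifnot(length(a) == length(b))
  n11 <- sum(a & b); n10 <- sum(a & !b)
  n01 <- sum(!a & b); n00 <- sum(!a & !b)
  margins <- c(n11 + n10, n01 + n00, n11 + n01, n10 + n00)
  if (any(margins == 0)) return(NA_real_)
  (n11 * n00 - n10 * n01) / sqrt(prod(margins))
}

# Signs of the global and recent context of a designed f1 series, relative to
# the full-series mean. Used at design time, before responses exist.
design_context_signs <- function(f1) {
  g <- sign(f1 - mean(f1))
  r <- c(NA, sign(diff(f1)))
  list(g = g[-1], r = r[-1])
}

seq_phi <- function(f1) {
  s <- design_context_signs(f1)
  phi_coefficient(s$g, s$r)
}

#' Generate a decorrelated trial sequence
#'
#' Produces a sequence in which the sign of the global context,
#' `G(t) = sign(f1(t) - mean(f1))`, and the sign of the recent context,
#' `R(t) = sign(f1(t) - f1(t-1))`, are uncorrelated (|phi| below `max_phi`).
#' In an unconstrained random sequence the two are strongly correlated, which
#' makes their contributions to choice behavior inseparable; this design lets
#' a choice GLM estimate them independently.
#'
#' The generator draws a random set of tones and then searches over
#' presentation orders by greedy pairwise swaps, recomputing phi after each
#' proposal, within a bounded attempt budget.
#'
#' @param n Number of trials (>= 10); default block length 150.
#' @param max_phi Absolute phi bound, in (0, 1); default 0.05.
#' @param seed Optional RNG seed.
#' @param iti Inter-trial interval (s), default 1.5.
#' @param max_attempts Swap-proposal budget before giving up.
#' @inheritParams generate_random_sequence
#' @return A `trial_sequence` with `design_tag = "decorrelated"` and attribute
#'   `phi` holding the achieved coefficient.
#' @export
generate_decorrelated_sequence <- function(n = 150, max_phi = 0.05,
                                           seed = NULL, f_band = c(800, 1250),
                                           df_band = c(1, 30), iti = 1.5,
                                           max_attempts = 20000L,
                                           tone_dur = 0.05, inter_tone = 0.6) {
  stopifnot(n >= 10, max_phi > 0, max_phi < 1)
  assert_band(f_band, "f_band")
  assert_band(df_band, "df_band")
  with_seed(seed, {
    f1 <- stats::runif(n, f_band[1], f_band[2])
    cur_phi <- seq_phi(f1)
    attempts <- 0L
    best_phi <- cur_phi
    while ((is.na(cur_phi) || abs(cur_phi) >= max_phi) &&
           attempts < max_attempts) {
      attempts <- attempts + 1L
      ij <- sample.int(n, 2L)
      cand <- f1
      cand[ij] <- cand[rev(ij)]
      new_phi <- seq_phi(cand)
      if (!is.na(new_phi) && (is.na(cur_phi) || abs(new_phi) < abs(cur_phi))) {
        f1 <- cand
        cur_phi <- new_phi
      }
      if (!is.na(cur_phi) &&
          (is.na(best_phi) || abs(cur_phi) < abs(best_phi))) {
        best_phi <- cur_phi
      }
    }
    if (is.na(cur_phi) || abs(cur_phi) >= max_phi) {
      stop(errorCondition(
        sprintf("decorrelation failed: best |phi| = %.3f after %d attempts",
                abs(best_phi), attempts),
        class = c("memdecay_generation_error", "error")))
    }
    f2 <- vapply(f1, draw_comparison, numeric(1), df_band)
    out <- build_sequence(f1, f2, iti, "decorrelated", f_band, df_band,
                          tone_dur, inter_tone)
    attr(out, "phi") <- cur_phi
    out
  })
}

#' Write / read a trial table CSV
#'
#' The interchange dialect has columns `index,f1_hz,f2_hz,onset1_s,onset2_s,`
#' `iti_s,response,block_id`; `response` (logical: responded "first higher")
#' and `block_id` are optional on write.
#'
#' @param seq A `trial_sequence`.
#' @param path File path.
#' @param response Optional logical vector of choices.
#' @param block_id Optional block identifier.
#' @export
write_trial_csv <- function(seq, path, response = NULL, block_id = NA) {
  df <- as.data.frame(seq)
  df$response <- if (is.null(response)) NA else response
  df$block_id <- block_id
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @return `read_trial_csv()` returns a list with the `trial_sequence` and the
#'   `response` and `block_id` columns if present.
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("index", "f1_hz", "f2_hz", "onset1_s", "onset2_s", "iti_s")
  if (!all(needed %in% names(df))) {
    stop_config("trial CSV must have columns ", paste(needed, collapse = ", "))
  }
  seq <- new_trial_sequence(df[needed], design_tag = "file",
                            f_band = range(c(df$f1_hz, df$f2_hz)),
                            df_band = NA, tone_dur = NA,
                            inter_tone = df$onset2_s[1] - df$onset1_s[1])
  list(sequence = seq,
       response = if ("response" %in% names(df)) as.logical(df$response) else NULL,
       block_id = if ("block_id" %in% names(df)) df$block_id else NULL)
}
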