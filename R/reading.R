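# Repetition-priming analysis of oral reading latencies.

#' Pair first and second presentations of repeated non-words
#'
#' One pair per twice-presented token with both presentations read correctly
#' (pairs with an error at either presentation are dropped by default). The
#' lag `delta_t` runs from the first presentation's voice offset to the
#' second presentation's visual onset; `lag_def = "onset_onset"` switches to
#' visual-onset-to-visual-onset.
#'
#' @param session A `reading_session`.
#' @param drop_errors Drop pairs containing an incorrect reading (default
#'   `TRUE`).
#' @param lag_def `"offset_onset"` (default) or `"onset_onset"`.
#' @return Data frame of `repetition_pair` rows: `token`, `rt_first`,
#'   `rt_second` (ms), `delta_t` (s), `n_intervening`.
#' @export
pair_repetitions <- function(session, drop_errors = TRUE,
                             lag_def = c("offset_onset", "onset_onset")) {
  lag_def <- match.arg(lag_def)
  stopifnot(inherits(session, "data.frame"))
  counts <- table(session$token)
  if (any(counts > 2L)) {
    stop_config("token(s) appear more than twice: ",
                paste(utils::head(names(counts)[counts > 2L]), collapse = ", "))
  }
  rep_toks <- names(counts)[counts == 2L]
  if (length(rep_toks) == 0L) {
    return(data.frame(token = character(), rt_first = numeric(),
                      rt_second = numeric(), delta_t = numeric(),
                      n_intervening = integer()))
  }
  ord <- order(session$visual_onset_ms)
  s <- session[ord, ]
  s$pos <- seq_len(nrow(s))
  rows <- lapply(rep_toks, function(tok) {
    pr <- s[s$token == tok, ]
    if (drop_errors && !all(pr$correct)) return(NULL)
    rt <- pr$voice_onset_ms - pr$visual_onset_ms
    dt <- switch(lag_def,
      offset_onset = (pr$visual_onset_ms[2] - pr$voice_offset_ms[1]) / 1000,
      onset_onset = (pr$visual_onset_ms[2] - pr$visual_onset_ms[1]) / 1000)
    data.frame(token = tok, rt_first = rt[1], rt_second = rt[2],
               delta_t = dt, n_intervening = pr$pos[2] - pr$pos[1] - 1L)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(token = character(), rt_first = numeric(),
                      rt_second = numeric(), delta_t = numeric(),
                      n_intervening = integer()))
  }
  if (any(out$n_intervening < 1L)) {
    stop_config("found a consecutive repetition: invalid session")
  }
  out[order(out$delta_t), ]
}

#' Repetition benefit per lag bin
#'
#' The millisecond benefit is `rt_first - rt_second`; the percentage benefit
#' `100 * (rt_first - rt_second) / rt_first`, which is invariant to a
#' uniform multiplicative slowdown of all RTs and therefore comparable
#' between groups with different baseline reading speeds.
#'
#' @param pairs Output of [pair_repetitions()].
#' @param bins Bin edges in seconds (default `c(0, 2, Inf)`: the "<2 s" and
#'   ">2 s" bins).
#' @return Data frame per bin: `bin_lo`, `bin_hi`, `mean_benefit_pct`,
#'   `mean_benefit_ms`, `mean_delta_t`, `n`, `flagged` (empty bin).
#' @export
#' @examples
#' pr <- data.frame(token = "x", rt_first = 800, rt_second = 600,
#'                  delta_t = 1.5, n_intervening = 1L)
#' repetition_benefit(pr)
repetition_benefit <- function(pairs, bins = c(0, 2, Inf)) {
  stopifnot(length(bins) >= 2, !is.unsorted(bins, strictly = TRUE))
  idx <- findInterval(pairs$delta_t, bins, rightmost.closed = FALSE)
  rows <- lapply(seq_len(length(bins) - 1L), function(b) {
    sel <- idx == b
    if (!any(sel)) {
      return(data.frame(bin_lo = bins[b], bin_hi = bins[b + 1L],
                        mean_benefit_pct = NA_real_,
                        mean_benefit_ms = NA_real_,
                        mean_delta_t = NA_real_, n = 0L, flagged = TRUE))
    }
    pct <- 100 * (pairs$rt_first[sel] - pairs$rt_second[sel]) /
      pairs$rt_first[sel]
    ms <- pairs$rt_first[sel] - pairs$rt_second[sel]
    data.frame(bin_lo = bins[b], bin_hi = bins[b + 1L],
               mean_benefit_pct = mean(pct), mean_benefit_ms = mean(ms),
               mean_delta_t = mean(pairs$delta_t[sel]), n = sum(sel),
               flagged = FALSE)
  })
  do.call(rbind, rows)
}
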