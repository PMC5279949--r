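# Synthetic self-paced oral reading sessions with decaying repetition
# priming.
#
# Non-words are disyllabic (CV+CVC or CVC+CV). Presentation is self-paced:
# each word appears `inter_word_gap` ms after the voice offset of the
# previous one, and stays until the current voice offset. A word read for
# the second time is read faster; the relative benefit decays with the time
# elapsed from the first reading's voice offset to the second presentation's
# visual onset:
#
#   benefit(dt) = benefit_floor + (benefit0 - benefit_floor) * exp(-dt / tau_read)

#' Generative parameters for a reading session
#'
#' @param n_blocks Blocks per session (default 6).
#' @param words_per_block Words per block (default 120).
#' @param rt_base_mean,rt_base_sd First-presentation reaction time mean and
#'   trial-to-trial SD (ms).
#' @param speech_dur_mean,speech_dur_sd Voice onset-to-offset duration (ms).
#' @param benefit0 Repetition benefit at zero lag (%).
#' @param tau_read Benefit decay time constant (s).
#' @param benefit_floor Asymptotic benefit (%); `0 <= floor <= benefit0 <= 100`.
#' @param inter_word_gap Gap from previous voice offset to next visual onset
#'   (ms, default 500).
#' @param error_rate Probability that a trial is read incorrectly.
#' @return Object of class `reading_gen_params`.
#' @export
reading_gen_params <- function(n_blocks = 6L, words_per_block = 120L,
                               rt_base_mean = 725, rt_base_sd = 120,
                               speech_dur_mean = 250, speech_dur_sd = 40,
                               benefit0 = 30, tau_read = 6,
                               benefit_floor = 12, inter_word_gap = 500,
                               error_rate = 0.014) {
  stopifnot(n_blocks >= 1, words_per_block >= 4,
            rt_base_mean > 0, rt_base_sd >= 0, tau_read > 0,
            inter_word_gap >= 0, error_rate >= 0, error_rate < 1)
  if (!(benefit_floor >= 0 && benefit_floor <= benefit0 && benefit0 <= 100)) {
    stop_config("need 0 <= benefit_floor <= benefit0 <= 100")
  }
  structure(as.list(environment()), class = "reading_gen_params")
}

#' @export
print.reading_gen_params <- function(x, ...) {
  cat(sprintf(
    "<reading_gen_params> %dx%d words, RT %g +/- %g ms, benefit %g%% -> %g%% (tau %g s)\n",
    x$n_blocks, x$words_per_block, x$rt_base_mean, x$rt_base_sd,
    x$benefit0, x$benefit_floor, x$tau_read))
  invisible(x)
}

DEFAULT_CONSONANTS <- c("b", "g", "d", "v", "z", "ch", "t", "y", "k", "l",
                        "m", "n", "s", "p", "r", "sh", "tz")
DEFAULT_VOWELS <- c("a", "e", "i", "o", "u")

#' Generate unique disyllabic non-words
#'
#' Each token is a conjunction of two syllables, one CV and one CVC, in
#' either order; all tokens are unique.
#'
#' @param k Number of tokens.
#' @param consonants,vowels Character inventories.
#' @param seed Optional RNG seed.
#' @return Character vector of `k` unique tokens.
#' @export
#' @examples
#' generate_nonwords(4, consonants = c("b", "d"), vowels = c("a", "o"), seed = 1)
generate_nonwords <- function(k, consonants = DEFAULT_CONSONANTS,
                              vowels = DEFAULT_VOWELS, seed = NULL) {
  stopifnot(k >= 0)
  if (length(consonants) == 0L || length(vowels) == 0L) {
    stop_config("consonant and vowel inventories must be non-empty")
  }
  capacity <- 2 * length(consonants)^3 * length(vowels)^2
  if (k > capacity) {
    stop_config("k = ", k, " exceeds the combinatorial capacity (", capacity,
                ") of the inventory")
  }
  if (k == 0L) return(character(0))
  with_seed(seed, {
    out <- character(0)
    while (length(out) < k) {
      need <- k - length(out)
      cv <- paste0(sample(consonants, need, TRUE), sample(vowels, need, TRUE))
      cvc <- paste0(sample(consonants, need, TRUE), sample(vowels, need, TRUE),
                    sample(consonants, need, TRUE))
      first_cv <- stats::runif(need) < 0.5
      tok <- ifelse(first_cv, paste0(cv, cvc), paste0(cvc, cv))
      out <- unique(c(out, tok))
    }
    out[seq_len(k)]
  })
}

#' Build a repetition lag plan for one block
#'
#' Assigns word slots of a block to repeated pairs and fillers. Short pairs
#' have exactly one intervening word (the closest repetition the design
#' allows: never consecutive); long pairs have `5 + Geometric` intervening
#' words (capped at 100), giving re-reading lags from a few seconds up to a
#' few minutes with a mean around 40 s at typical self-paced word rates.
#'
#' @param words_per_block Slots in the block.
#' @param short_pairs,long_pairs Number of pairs of each kind.
#' @param long_gap_mean Mean of the geometric part of the long-pair gap.
#' @param seed Optional RNG seed.
#' @return Data frame `first_pos`, `second_pos`, one row per pair.
#' @export
make_lag_plan <- function(words_per_block = 120L, short_pairs = 2L,
                          long_pairs = 36L, long_gap_mean = 30,
                          seed = NULL) {
  stopifnot(2L * (short_pairs + long_pairs) <= words_per_block)
  with_seed(seed, {
    free <- rep(TRUE, words_per_block)
    firsts <- seconds <- integer(0)
    place <- function(gap_fn) {
      for (attempt in seq_len(400L)) {
        i <- sample(which(free), 1L)
        j <- i + gap_fn() + 1L
        if (j <= words_per_block && free[j]) {
          free[c(i, j)] <<- FALSE
          firsts <<- c(firsts, i)
          seconds <<- c(seconds, j)
          return(invisible(TRUE))
        }
      }
      stop(errorCondition("could not place repetition pair within budget",
                          class = c("memdecay_generation_error", "error")))
    }
    for (p in seq_len(long_pairs)) {
      place(function() min(5L + stats::rgeom(1L, 1 / long_gap_mean), 100L))
    }
    for (p in seq_len(short_pairs)) {
      place(function() 1L)
    }
    data.frame(first_pos = firsts, second_pos = seconds)
  })
}

validate_lag_plan <- function(plan, words_per_block) {
  if (any(plan$second_pos - plan$first_pos < 2L)) {
    stop_config("lag plan contains a consecutive repetition")
  }
  pos <- c(plan$first_pos, plan$second_pos)
  if (any(duplicated(pos)) || any(pos < 1L) || any(pos > words_per_block)) {
    stop_config("lag plan positions must be unique and within the block")
  }
  invisible(plan)
}

#' Generate a reading session
#'
#' Simulates `n_blocks` self-paced blocks with repeated non-words placed per
#' `lag_plan` (one plan per block, regenerated from the seed when `NULL`).
#' Second presentations are faster by `benefit(dt)` percent of the realized
#' first-presentation RT, where `dt` is the lag from the first reading's
#' voice offset to the second presentation's visual onset.
#'
#' @param p A [reading_gen_params()].
#' @param lag_plan Optional single-block lag plan applied to every block.
#' @param seed Optional RNG seed.
#' @return A `reading_session` data frame: `token`, `block`,
#'   `visual_onset_ms`, `voice_onset_ms`, `voice_offset_ms`, `correct`.
#' @export
generate_reading_session <- function(p, lag_plan = NULL, seed = NULL) {
  stopifnot(inherits(p, "reading_gen_params"))
  if (!is.null(lag_plan)) validate_lag_plan(lag_plan, p$words_per_block)
  with_seed(seed, {
    plans <- lapply(seq_len(p$n_blocks), function(b) {
      plan <- lag_plan %||% make_lag_plan(p$words_per_block)
      validate_lag_plan(plan, p$words_per_block)
      plan
    })
    # one session-wide vocabulary: tokens are unique across blocks so that a
    # token is presented at most twice in the session
    n_per_block <- vapply(plans, function(pl) p$words_per_block - nrow(pl),
                          integer(1))
    vocab <- generate_nonwords(sum(n_per_block))
    vocab_off <- c(0L, cumsum(n_per_block))
    rows <- list()
    clock <- 0
    for (blk in seq_len(p$n_blocks)) {
      plan <- plans[[blk]]
      toks <- vocab[(vocab_off[blk] + 1L):vocab_off[blk + 1L]]
      slot_tok <- character(p$words_per_block)
      slot_tok[plan$first_pos] <- toks[seq_len(nrow(plan))]
      slot_tok[plan$second_pos] <- toks[seq_len(nrow(plan))]
      slot_tok[slot_tok == ""] <- toks[(nrow(plan) + 1L):length(toks)]
      first_seen <- new.env(parent = emptyenv())
      for (w in seq_len(p$words_per_block)) {
        visual <- clock + p$inter_word_gap
        tok <- slot_tok[w]
        prev <- first_seen[[tok]]
        if (!is.null(prev)) {
          # second presentation: mean RT is the *realized* first RT scaled
          # down by the benefit at the realized lag
          dt_s <- (visual - prev$offset) / 1000
          ben <- p$benefit_floor +
            (p$benefit0 - p$benefit_floor) * exp(-dt_s / p$tau_read)
          rt <- prev$rt * (1 - ben / 100) +
            stats::rnorm(1, 0, p$rt_base_sd / 2)
        } else {
          rt <- stats::rnorm(1, p$rt_base_mean, p$rt_base_sd)
        }
        rt <- max(rt, 150)
        dur <- max(stats::rnorm(1, p$speech_dur_mean, p$speech_dur_sd), 80)
        voice_on <- visual + rt
        voice_off <- voice_on + dur
        if (is.null(prev)) first_seen[[tok]] <- list(rt = rt, offset = voice_off)
        rows[[length(rows) + 1L]] <- data.frame(
          token = tok, block = blk, visual_onset_ms = visual,
          voice_onset_ms = voice_on, voice_offset_ms = voice_off,
          correct = stats::runif(1) >= p$error_rate)
        clock <- voice_off
      }
      clock <- clock + 5000  # inter-block pause
    }
    out <- do.call(rbind, rows)
    class(out) <- c("reading_session", "data.frame")
    out
  })
}

#' Write / read a reading-session CSV
#'
#' Columns: `token,block,visual_onset_ms,voice_onset_ms,voice_offset_ms,correct`.
#'
#' @param session A `reading_session`.
#' @param path File path.
#' @export
write_reading_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reading_csv
#' @export
read_reading_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("token", "block", "visual_onset_ms", "voice_onset_ms",
              "voice_offset_ms", "correct")
  if (!all(needed %in% names(df))) {
    stop_config("reading CSV must have columns ", paste(needed, collapse = ", "))
  }
  df$correct <- as.logical(df$correct)
  class(df) <- c("reading_session", "data.frame")
  df
}
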