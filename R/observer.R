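# Contraction-bias observer for two-tone frequency discrimination.
#
# The observer holds an implicit prior over tone frequency, formed from the
# first tones of previous trials: a mixture of the most recent f1 (recency
# component, weight gamma) and the running mean of all previous f1 (global
# component). Because the first tone must be retained across the inter-tone
# interval, its percept is contracted toward that prior; the contraction
# weight decays with the time elapsed since the previous trial:
#
#   w(t) = w_floor + (w0 - w_floor) * exp(-ITI / tau_mem)
#
# so the behavioral footprint of the prior fades as trials are spaced further
# apart. Decay acts on the weight (the *magnitude* of the bias), not on the
# prior's value.

#' Observer parameters for the contraction-bias decision model
#'
#' @param sigma Decision-noise SD as a fraction of f1 (dimensionless, >= 0).
#' @param w0 Prior weight at ITI = 0, in `[0, 1]`.
#' @param tau_mem Memory-decay time constant (s, > 0).
#' @param gamma Mixing weight of the most recent f1 versus the running mean in
#'   the prior estimate, in `[0, 1]`; default 0.6 (recency-dominated).
#' @param w_floor Asymptotic prior weight as ITI grows, in `[0, w0]`.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma = 0.05, w0 = 0.3, tau_mem = 6,
                            gamma = 0.6, w_floor = 0.05) {
  stopifnot(sigma >= 0, tau_mem > 0)
  for (w in c(w0 = w0, gamma = gamma, w_floor = w_floor)) {
    if (w < 0 || w > 1) stop_config("observer weights must lie in [0, 1]")
  }
  if (w_floor > w0) stop_config("`w_floor` must not exceed `w0`")
  structure(list(sigma = sigma, w0 = w0, tau_mem = tau_mem,
                 gamma = gamma, w_floor = w_floor),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> sigma = %.3g, w0 = %.3g, w_floor = %.3g, tau_mem = %.3g s, gamma = %.2g\n",
    x$sigma, x$w0, x$w_floor, x$tau_mem, x$gamma))
  invisible(x)
}

# Per-trial effective contraction weight and prior estimate. Trial 1 has no
# prior (w = 0 by convention: nothing precedes it).
observer_state <- function(seq, p) {
  f1 <- seq$f1_hz
  n <- length(f1)
  runmean <- cumsum(f1) / seq_len(n)
  prior <- c(NA_real_,
             p$gamma * f1[-n] + (1 - p$gamma) * runmean[-n])
  w <- p$w_floor + (p$w0 - p$w_floor) * exp(-seq$iti_s / p$tau_mem)
  w[1] <- 0
  prior[1] <- f1[1]  # unused: weight is zero on trial 1
  list(prior = prior, w = w)
}

#' Probability of responding "first higher" for each trial
#'
#' Closed-form choice probabilities of the observer on a sequence: the first
#' tone's percept is `f1* = (1 - w) * f1 + w * prior`, and the response is
#' "first higher" when `f1* + e > f2` with `e ~ N(0, sigma * f1)`. With
#' `sigma = 0` the probabilities are 0/1 (deterministic comparison).
#'
#' @param seq A `trial_sequence`.
#' @param p An [observer_params()].
#' @return Numeric vector of per-trial probabilities.
#' @export
observer_choice_probs <- function(seq, p) {
  stopifnot(inherits(seq, "trial_sequence"), inherits(p, "observer_params"))
  st <- observer_state(seq, p)
  f1_star <- (1 - st$w) * seq$f1_hz + st$w * st$prior
  margin <- f1_star - seq$f2_hz
  if (p$sigma == 0) {
    as.numeric(margin > 0)
  } else {
    stats::pnorm(margin / (p$sigma * seq$f1_hz))
  }
}

#' Simulate observer choices on a trial sequence
#'
#' @inheritParams observer_choice_probs
#' @param seed Optional RNG seed; identical seeds give identical choices.
#' @return Logical vector: `TRUE` where the observer responded "first higher".
#' @export
#' @examples
#' s <- generate_random_sequence(50, seed = 1)
#' ch <- simulate_observer(s, observer_params(), seed = 2)
#' mean(ch == (s$f1_hz > s$f2_hz))  # accuracy
simulate_observer <- function(seq, p, seed = NULL) {
  stopifnot(nrow(seq) >= 2)
  probs <- observer_choice_probs(seq, p)
  with_seed(seed, stats::runif(length(probs)) < probs)
}
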