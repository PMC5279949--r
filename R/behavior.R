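# Behavioral analysis of two-tone discrimination: signal-detection
# sensitivity, Bias+/Bias- labeling of trials by whether contraction toward
# the prior helps or hurts, the per-ITI context effect (delta d'), and the
# three-predictor choice GLM used on decorrelated sequences.

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(HR) - qnorm(FA)` where HR is the probability of responding
#' "first higher" when the first tone really was higher and FA the same
#' probability when it was lower. Rates of exactly 0 or 1 are corrected to
#' `1/(2N)` and `1 - 1/(2N)` (N = trials in that condition) before the
#' quantile transform, the standard correction that keeps d' finite.
#'
#' @param response Logical vector: responded "first higher".
#' @param first_higher Logical vector: the first tone was truly higher.
#' @return A single finite d' value.
#' @export
#' @examples
#' compute_dprime(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
compute_dprime <- function(response, first_higher) {
  stopifnot(is.logical(response), is.logical(first_higher),
            length(response) == length(first_higher))
  n_sig <- sum(first_higher)
  n_noi <- sum(!first_higher)
  if (n_sig == 0L || n_noi == 0L) {
    stop(errorCondition("d' undefined: a stimulus condition has zero trials",
                        class = c("memdecay_undefined_measure", "error")))
  }
  rate <- function(k, n) {
    r <- k / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  hr <- rate(sum(response & first_higher), n_sig)
  fa <- rate(sum(response & !first_higher), n_noi)
  stats::qnorm(hr) - stats::qnorm(fa)
}

#' Per-trial prior estimates
#'
#' The recent prior is always the previous trial's first tone. The global
#' prior depends on `mode`: `"running"` is the mean of all previous first
#' tones, `"exclude_recent"` the mean of all previous except the most recent
#' one, and `"full"` the leave-one-out mean over the whole designed sequence.
#' Trials for which a prior is not yet defined get `NA` and are excluded
#' downstream.
#'
#' @param seq A `trial_sequence` with at least 3 trials.
#' @param mode One of `"running"`, `"full"`, `"exclude_recent"`.
#' @return Data frame with columns `global_prior` and `recent_prior` (Hz).
#' @export
prior_estimates <- function(seq, mode = c("running", "full", "exclude_recent")) {
  mode <- match.arg(mode)
  stopifnot(nrow(seq) >= 3)
  f1 <- seq$f1_hz
  n <- length(f1)
  recent <- c(NA_real_, f1[-n])
  csum <- cumsum(f1)
  global <- switch(mode,
    running = c(NA_real_, csum[-n] / seq_len(n - 1L)),
    exclude_recent = c(NA_real_, NA_real_,
                       csum[seq_len(n - 2L)] / seq_len(n - 2L)),
    full = (sum(f1) - f1) / (n - 1L)
  )
  data.frame(global_prior = global, recent_prior = recent)
}

#' Label a trial Bias+ / Bias- / Neutral
#'
#' Contraction of the first tone toward the prior widens the perceived
#' within-trial difference when the prior lies on the far side of f1 from f2
#' (`Bias+`, discrimination helped) and shrinks it when the prior lies toward
#' f2 (`Bias-`, discrimination hurt). `Neutral` only when the prior equals f1
#' exactly (probability zero under continuous generation).
#'
#' @param f1,f2 Tone frequencies (Hz); `f1 != f2` elementwise.
#' @param prior Prior estimate (Hz).
#' @return Factor with levels `BiasPlus`, `BiasMinus`, `Neutral`.
#' @export
#' @examples
#' label_bias(1000, 980, 1100)  # prior beyond f1: helps -> BiasPlus
label_bias <- function(f1, f2, prior) {
  if (any(f1 == f2)) {
    stop(errorCondition("invalid trial: f1 == f2",
                        class = c("memdecay_invalid_trial", "error")))
  }
  s <- sign(prior - f1) * sign(f1 - f2)
  factor(ifelse(s > 0, "BiasPlus", ifelse(s < 0, "BiasMinus", "Neutral")),
         levels = c("BiasPlus", "BiasMinus", "Neutral"))
}

#' Context effect (delta d') per ITI block
#'
#' Splits trials of each ITI into Bias+ and Bias- subsets by whether
#' contraction toward the prior helps or hurts, computes d' separately in
#' each, and reports the difference. In sequences without a designed
#' decorrelation the recent and global context act as one unified,
#' recency-dominated prior, so the default labels trials by the previous
#' trial's first tone (`prior_mode = "recent"`); the global-prior modes of
#' [prior_estimates()] are available as alternatives. Blocks where either
#' subset has fewer than `min_per_label` trials after exclusions are flagged
#' and carry `NA`, so they drop out of downstream decay fitting.
#'
#' @param seq A `trial_sequence` (one or more ITI levels in `iti_s`).
#' @param choices Logical vector of "first higher" responses.
#' @param prior_mode Labeling prior: `"recent"` (previous trial's f1) or one
#'   of the global modes of [prior_estimates()].
#' @param min_per_label Minimum trials per label per block (default 10).
#' @return Data frame with one row per ITI: `iti`, `dprime_plus`,
#'   `dprime_minus`, `delta_dprime`, `n_plus`, `n_minus`, `flagged`.
#' @export
context_effect <- function(seq, choices,
                           prior_mode = c("recent", "running", "full",
                                          "exclude_recent"),
                           min_per_label = 10L) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(length(choices) == nrow(seq))
  if (prior_mode == "recent") {
    prior <- prior_estimates(seq, "running")$recent_prior
  } else {
    prior <- prior_estimates(seq, prior_mode)$global_prior
  }
  ok <- !is.na(prior)
  lab <- rep(NA_character_, nrow(seq))
  lab[ok] <- as.character(label_bias(seq$f1_hz[ok], seq$f2_hz[ok], prior[ok]))
  first_higher <- seq$f1_hz > seq$f2_hz
  itis <- sort(unique(seq$iti_s[!is.na(seq$iti_s)]))
  rows <- lapply(itis, function(it) {
    in_block <- !is.na(seq$iti_s) & seq$iti_s == it & ok
    plus <- in_block & lab == "BiasPlus"
    minus <- in_block & lab == "BiasMinus"
    n_p <- sum(plus); n_m <- sum(minus)
    usable <- function(idx) sum(first_higher[idx]) >= 1 &&
      sum(!first_higher[idx]) >= 1
    if (n_p < min_per_label || n_m < min_per_label ||
        !usable(plus) || !usable(minus)) {
      return(data.frame(iti = it, dprime_plus = NA_real_,
                        dprime_minus = NA_real_, delta_dprime = NA_real_,
                        n_plus = n_p, n_minus = n_m, flagged = TRUE))
    }
    dp <- compute_dprime(choices[plus], first_higher[plus])
    dm <- compute_dprime(choices[minus], first_higher[minus])
    data.frame(iti = it, dprime_plus = dp, dprime_minus = dm,
               delta_dprime = dp - dm, n_plus = n_p, n_minus = n_m,
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the three-predictor design matrix for the choice GLM
#'
#' Predictors per trial: `x_df`, the absolute within-trial frequency
#' difference as a percentage of the lower tone; `c_global`, +1 when
#' contraction toward the global prior is beneficial for the trial and -1
#' when disruptive (`-sign(f1 - prior_global) * sign(f1 - f2)`); and
#' `c_recent`, the same congruence coding for contraction toward the previous
#' trial's first tone. The outcome is trial correctness.
#'
#' @inheritParams context_effect
#' @return Data frame with `x_df`, `c_global`, `c_recent`, `correct`; trials
#'   with undefined priors are dropped.
#' @export
build_design_matrix <- function(seq, choices, prior_mode = "exclude_recent") {
  stopifnot(length(choices) == nrow(seq))
  pri <- prior_estimates(seq, prior_mode)
  keep <- !is.na(pri$global_prior) & !is.na(pri$recent_prior)
  f1 <- seq$f1_hz[keep]; f2 <- seq$f2_hz[keep]
  sgn_df <- sign(f1 - f2)
  data.frame(
    x_df = 100 * abs(f1 - f2) / pmin(f1, f2),
    c_global = -sign(f1 - pri$global_prior[keep]) * sgn_df,
    c_recent = -sign(f1 - pri$recent_prior[keep]) * sgn_df,
    correct = as.integer(choices[keep] == (f1 > f2))
  )
}

#' Fit the three-predictor choice GLM
#'
#' Binomial GLM with logit link of trial correctness on `x_df`, `c_global`
#' and `c_recent` (congruence-coded context predictors), with intercept.
#' On (quasi-)separation the model is refit with a small ridge penalty via
#' iteratively reweighted least squares and flagged.
#'
#' @param design Output of [build_design_matrix()]; needs >= 30 rows.
#' @param ridge Ridge penalty used only in the fallback refit.
#' @return A `glm_fit`: coefficients (`beta_df`, `beta_global`,
#'   `beta_recent`), standard errors, `n_trials`, `ridged` flag.
#' @export
fit_choice_glm <- function(design, ridge = 1e-2) {
  stopifnot(all(c("x_df", "c_global", "c_recent", "correct") %in% names(design)))
  if (nrow(design) < 30L) {
    stop_config("fit_choice_glm() needs at least 30 usable trials")
  }
  fit <- withCallingHandlers(
    stats::glm(correct ~ x_df + c_global + c_recent,
               family = stats::binomial(), data = design),
    warning = function(w) invokeRestart("muffleWarning"))
  co <- stats::coef(fit)
  separated <- !fit$converged || any(abs(co) > 15)
  if (separated) {
    rf <- ridge_logistic(design, ridge)
    co <- rf$coef
    se <- rf$se
  } else {
    se <- sqrt(diag(stats::vcov(fit)))
  }
  structure(list(
    beta_df = unname(co["x_df"]),
    beta_global = unname(co["c_global"]),
    beta_recent = unname(co["c_recent"]),
    intercept = unname(co["(Intercept)"]),
    se = c(df = unname(se["x_df"]), global = unname(se["c_global"]),
           recent = unname(se["c_recent"])),
    n_trials = nrow(design),
    ridged = separated
  ), class = "glm_fit")
}

# Ridge-penalized logistic regression by IRLS; penalty excludes the intercept.
ridge_logistic <- function(design, lambda, max_iter = 100L) {
  X <- cbind("(Intercept)" = 1, x_df = design$x_df,
             c_global = design$c_global, c_recent = design$c_recent)
  y <- design$correct
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- solve(H, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  H <- crossprod(X, X * w) + pen
  se <- sqrt(diag(solve(H)))
  names(se) <- colnames(X)
  list(coef = beta, se = se)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf(
    "<glm_fit> beta_df = %.3f (SE %.3f), beta_global = %.3f (SE %.3f), beta_recent = %.3f (SE %.3f), n = %d%s\n",
    x$beta_df, x$se["df"], x$beta_global, x$se["global"],
    x$beta_recent, x$se["recent"], x$n_trials,
    if (x$ridged) " [ridge fallback]" else ""))
  invisible(x)
}
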