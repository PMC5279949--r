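test_that("d' matches the normal-quantile oracle", {
  # symmetric rates: d' = 0
  resp <- c(rep(TRUE, 5), rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 5))
  truth <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(compute_dprime(resp, truth), 0)
  # constructed counts: HR = 21/25, FA = 4/25
  resp2 <- c(rep(TRUE, 21), rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 21))
  truth2 <- rep(c(TRUE, FALSE), each = 25)
  expect_equal(compute_dprime(resp2, truth2),
               qnorm(21 / 25) - qnorm(4 / 25), tolerance = 1e-12)
})

test_that("extreme rates are clamped to 1/(2N) before the transform", {
  # HR = 1 with N = 20 -> corrected to 0.975; FA = 0.5
  resp <- c(rep(TRUE, 20), rep(TRUE, 5), rep(FALSE, 5))
  truth <- c(rep(TRUE, 20), rep(FALSE, 10))
  expect_equal(compute_dprime(resp, truth), qnorm(0.975) - qnorm(0.5),
               tolerance = 1e-12)
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
})

test_that("d' is antisymmetric under response relabeling", {
  set.seed(42)
  truth <- runif(60) < 0.5
  resp <- runif(60) < 0.7
  expect_equal(compute_dprime(!resp, truth), -compute_dprime(resp, truth),
               tolerance = 1e-12)
  expect_error(compute_dprime(resp[truth], truth[truth]),
               class = "memdecay_undefined_measure")
})

test_that("prior estimates follow their mode definitions", {
  s <- make_seq(f1 = c(1000, 1100, 900, 1050), f2 = c(990, 1120, 880, 1030))
  pr <- prior_estimates(s, "running")
  expect_equal(pr$global_prior, c(NA, 1000, 1050, 1000))
  expect_equal(pr$recent_prior, c(NA, 1000, 1100, 900))
  pe <- prior_estimates(s, "exclude_recent")
  expect_equal(pe$global_prior, c(NA, NA, 1000, 1050))
  pf <- prior_estimates(s, "full")
  # leave-one-out oracle
  f1 <- s$f1_hz
  loo <- vapply(seq_along(f1), function(i) mean(f1[-i]), numeric(1))
  expect_equal(pf$global_prior, loo)
})

test_that("bias labels encode whether contraction helps", {
  expect_equal(as.character(label_bias(1000, 980, 1100)), "BiasPlus")
  expect_equal(as.character(label_bias(1000, 980, 900)), "BiasMinus")
  expect_equal(as.character(label_bias(1000, 1020, 900)), "BiasPlus")
  expect_equal(as.character(label_bias(1000, 1020, 1000)), "Neutral")
  expect_error(label_bias(1000, 1000, 900), class = "memdecay_invalid_trial")
})

test_that("context effect equals an independent subset recomputation", {
  s <- generate_random_sequence(200, seed = 31)
  p <- observer_params(sigma = 0.03, w0 = 0.4, w_floor = 0.2, tau_mem = 5)
  ch <- simulate_observer(s, p, seed = 32)
  ce <- context_effect(s, ch, prior_mode = "recent")
  # recompute by hand from the labeled subsets
  prior <- c(NA, s$f1_hz[-nrow(s)])
  lab <- sign(prior - s$f1_hz) * sign(s$f1_hz - s$f2_hz)
  fh <- s$f1_hz > s$f2_hz
  plus <- which(lab > 0)
  minus <- which(lab < 0)
  dd <- compute_dprime(ch[plus], fh[plus]) - compute_dprime(ch[minus], fh[minus])
  expect_equal(ce$delta_dprime, dd, tolerance = 1e-12)
  expect_equal(ce$n_plus, length(plus))
  expect_equal(ce$delta_dprime, ce$dprime_plus - ce$dprime_minus)
})

test_that("degenerate blocks are flagged rather than fit", {
  # strictly decreasing f1 with f2 below f1: every labeled trial is Bias+
  f1 <- seq(1200, 900, length.out = 30)
  s <- make_seq(f1 = f1, f2 = f1 - 20)
  ch <- rep(TRUE, 30)
  ce <- context_effect(s, ch, prior_mode = "recent", min_per_label = 5)
  expect_true(ce$flagged)
  expect_true(is.na(ce$delta_dprime))
})

test_that("design-matrix congruence coding follows the sign algebra", {
  # f1 = 1000, f2 = 980, global mean 1100 -> G = -1, sign(df) = +1 -> c_global = +1
  s <- make_seq(f1 = c(1150, 1050, 1000), f2 = c(1130, 1030, 980))
  d <- build_design_matrix(s, choices = c(TRUE, TRUE, TRUE),
                           prior_mode = "running")
  # trial 3: global prior = mean(1150, 1050) = 1100 > f1, recent = 1050 > f1
  expect_equal(d$c_global[2], 1)
  expect_equal(d$c_recent[2], 1)
  expect_equal(d$x_df[2], 100 * 20 / 980)
  # f1 = 1000, f2 = 980, previous f1 = 900 -> R = +1 -> c_recent = -1
  s2 <- make_seq(f1 = c(900, 1000), f2 = c(880, 980))
  d2 <- build_design_matrix(make_seq(f1 = c(900, 950, 1000),
                                     f2 = c(880, 930, 980)),
                            choices = rep(TRUE, 3), prior_mode = "running")
  expect_equal(d2$c_recent[2], -1)
})

test_that("c_global agrees with label_bias on every trial", {
  s <- generate_random_sequence(150, seed = 77)
  ch <- simulate_observer(s, observer_params(), seed = 78)
  d <- build_design_matrix(s, ch, prior_mode = "running")
  pr <- prior_estimates(s, "running")
  keep <- !is.na(pr$global_prior) & !is.na(pr$recent_prior)
  lab <- label_bias(s$f1_hz[keep], s$f2_hz[keep], pr$global_prior[keep])
  expect_equal(d$c_global, ifelse(lab == "BiasPlus", 1, -1))
})

test_that("choice GLM recovers null and planted context structure", {
  # null observer: context coefficients within 2 SE of zero
  p0 <- observer_params(sigma = 0.05, w0 = 0, w_floor = 0, tau_mem = 5)
  design <- do.call(rbind, lapply(1:4, function(b) {
    s <- generate_decorrelated_sequence(150, seed = 500 + b)
    ch <- simulate_observer(s, p0, seed = 600 + b)
    build_design_matrix(s, ch)
  }))
  f <- fit_choice_glm(design)
  expect_lt(abs(f$beta_global), 2 * f$se["global"])
  expect_lt(abs(f$beta_recent), 2 * f$se["recent"])
  expect_gt(f$beta_df, 0)  # difficulty always matters when sigma is finite

  # recency-only prior (gamma = 1, slow decay): recent beats global
  p1 <- observer_params(sigma = 0.05, w0 = 0.45, w_floor = 0.45,
                        tau_mem = 50, gamma = 1)
  fits <- lapply(1:6, function(i) {
    d <- do.call(rbind, lapply(1:2, function(b) {
      s <- generate_decorrelated_sequence(150, seed = 700 + 10 * i + b)
      ch <- simulate_observer(s, p1, seed = 800 + 10 * i + b)
      build_design_matrix(s, ch)
    }))
    fit_choice_glm(d)
  })
  br <- mean(vapply(fits, `[[`, numeric(1), "beta_recent"))
  bg <- mean(vapply(fits, `[[`, numeric(1), "beta_global"))
  expect_gt(br, 0)
  expect_gt(br, bg)
})

test_that("difficulty-blind responses zero the difficulty coefficient", {
  # enormous sigma: outcome independent of x_df
  p <- observer_params(sigma = 5, w0 = 0, w_floor = 0, tau_mem = 5)
  design <- do.call(rbind, lapply(1:3, function(b) {
    s <- generate_random_sequence(150, seed = 900 + b)
    ch <- simulate_observer(s, p, seed = 950 + b)
    build_design_matrix(s, ch, prior_mode = "running")
  }))
  f <- fit_choice_glm(design)
  expect_lt(abs(f$beta_df), 2 * f$se["df"])
})

test_that("decorrelated designs keep predictors estimable", {
  # the design decorrelates signs relative to the full-sequence mean, so the
  # leave-one-out ("full") prior matches the design target
  s <- generate_decorrelated_sequence(150, seed = 41)
  ch <- simulate_observer(s, observer_params(), seed = 42)
  d <- build_design_matrix(s, ch, prior_mode = "full")
  expect_lt(abs(cor(d$c_global, d$c_recent)), 0.1)
  expect_error(fit_choice_glm(d[1:10, ]), class = "memdecay_config_error")
})
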