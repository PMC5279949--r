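test_that("contraction arithmetic follows the perceptual update rule", {
  # prior 900 (previous f1), current trial f1 = 1000, f2 = 995
  s <- make_seq(f1 = c(900, 1000), f2 = c(850, 995))
  # w = 0.02: f1* = 998 > 995 -> "first higher" (correct)
  p <- observer_params(sigma = 0, w0 = 0.02, w_floor = 0.02, tau_mem = 1,
                       gamma = 0.6)
  # gamma-mixture of a single previous trial collapses to that f1 (= 900)
  expect_equal(observer_choice_probs(s, p)[2], 1)
  # w = 0.2: f1* = 980 < 995 -> contraction-induced error
  p2 <- observer_params(sigma = 0, w0 = 0.2, w_floor = 0.2, tau_mem = 1)
  expect_equal(observer_choice_probs(s, p2)[2], 0)
})

test_that("trial 1 uses no prior and sigma = 0 is deterministic", {
  s <- make_seq(f1 = c(1000, 1000), f2 = c(1100, 995))
  p <- observer_params(sigma = 0, w0 = 1, w_floor = 1, tau_mem = 1)
  pr <- observer_choice_probs(s, p)
  expect_equal(pr[1], 0)  # f1 < f2, no contraction on trial 1
  ch <- simulate_observer(s, p, seed = 1)
  expect_identical(ch, pr == 1)
})

test_that("observer simulation is reproducible under a seed", {
  s <- generate_random_sequence(100, seed = 4)
  p <- observer_params()
  expect_identical(simulate_observer(s, p, seed = 10),
                   simulate_observer(s, p, seed = 10))
  expect_false(identical(simulate_observer(s, p, seed = 10),
                         simulate_observer(s, p, seed = 11)))
})

test_that("a prior-blind observer produces a null context effect", {
  # w0 = w_floor = 0 with a homogeneous difficulty band: delta d' across 30
  # simulated subjects lies within 2 SE of 0. (With the full 1-30% range the
  # extreme comparison tones are also the easy trials and fall
  # preferentially in Bias- cells, so even a prior-blind observer shows a
  # negative delta d' of stimulus-composition origin; a narrow band isolates
  # the observer property from that confound.)
  p <- observer_params(sigma = 0.05, w0 = 0, w_floor = 0, tau_mem = 5)
  dd <- vapply(1:30, function(i) {
    s <- generate_random_sequence(100, df_band = c(4, 6), seed = 1000 + i)
    ch <- simulate_observer(s, p, seed = 2000 + i)
    context_effect(s, ch, min_per_label = 5)$delta_dprime[1]
  }, numeric(1))
  se <- sd(dd, na.rm = TRUE) / sqrt(sum(!is.na(dd)))
  expect_lt(abs(mean(dd, na.rm = TRUE)), 2 * se)

  # the broad-band composition artifact itself is stable and negative
  dd_broad <- vapply(1:30, function(i) {
    s <- generate_random_sequence(100, seed = 3000 + i)
    ch <- simulate_observer(s, p, seed = 4000 + i)
    context_effect(s, ch, min_per_label = 5)$delta_dprime[1]
  }, numeric(1))
  expect_lt(mean(dd_broad, na.rm = TRUE), 0)
})

test_that("longer memory never weakens the expected context effect", {
  # common random numbers: same sequences and response noise seeds
  mean_dd <- function(tau_mem) {
    p <- observer_params(sigma = 0.03, w0 = 0.4, w_floor = 0, tau_mem = tau_mem)
    mean(vapply(1:20, function(i) {
      s <- generate_random_sequence(100, iti = 4, seed = 300 + i)
      ch <- simulate_observer(s, p, seed = 400 + i)
      context_effect(s, ch, min_per_label = 5)$delta_dprime[1]
    }, numeric(1)), na.rm = TRUE)
  }
  taus <- c(1, 3, 9)
  vals <- vapply(taus, mean_dd, numeric(1))
  expect_true(all(diff(vals) > -0.05))
})

test_that("observer parameter invariants are enforced", {
  expect_error(observer_params(w0 = 1.2), class = "memdecay_config_error")
  expect_error(observer_params(w0 = 0.1, w_floor = 0.2),
               class = "memdecay_config_error")
  expect_error(observer_params(tau_mem = 0))
})

test_that("calibrated observers reproduce a planted delta d' curve", {
  map <- calibrate_ddprime_map(n_blocks = 60L)
  times <- c(1.4, 2.9, 5.9, 8.9)
  p <- observer_from_decay(0.7, 2.3, 6, times = times, map = map)
  target <- 0.7 + 2.3 * exp(-times / 6)
  measured <- sapply(seq_along(times), function(b) {
    mean(vapply(1:25, function(i) {
      s <- generate_random_sequence(100, iti = times[b], seed = 7000 + 31 * b + i)
      ch <- simulate_observer(s, p, seed = 8000 + 31 * b + i)
      context_effect(s, ch, min_per_label = 5)$delta_dprime[1]
    }, numeric(1)), na.rm = TRUE)
  })
  expect_true(all(abs(measured - target) < 0.35))
})
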