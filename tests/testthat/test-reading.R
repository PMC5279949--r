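test_that("non-words follow the disyllabic templates and stay unique", {
  toks <- generate_nonwords(4, consonants = c("b", "d"), vowels = c("a", "o"),
                            seed = 1)
  expect_length(toks, 4)
  expect_false(any(duplicated(toks)))
  # CV+CVC (CVCVC) or CVC+CV (CVCCV) over the given inventory
  pat <- "^([bd][ao][bd][ao][bd]|[bd][ao][bd][bd][ao])$"
  expect_true(all(grepl(pat, toks)))
  expect_identical(generate_nonwords(0), character(0))
  expect_error(generate_nonwords(1000, consonants = c("b", "d"),
                                 vowels = c("a", "o")),
               class = "memdecay_config_error")
  expect_error(generate_nonwords(2, consonants = character(0)),
               class = "memdecay_config_error")
})

test_that("lag plans forbid consecutive repetitions", {
  plan <- make_lag_plan(120, seed = 2)
  expect_true(all(plan$second_pos - plan$first_pos >= 2))
  bad <- data.frame(first_pos = 5L, second_pos = 6L)
  expect_error(generate_reading_session(reading_gen_params(), lag_plan = bad),
               class = "memdecay_config_error")
})

test_that("sessions are self-paced and timing is internally consistent", {
  p <- reading_gen_params(n_blocks = 1)
  s <- generate_reading_session(p, seed = 7)
  expect_equal(nrow(s), 120)
  expect_true(all(diff(s$visual_onset_ms) > 0))
  expect_true(all(s$voice_onset_ms > s$visual_onset_ms))
  expect_true(all(s$voice_offset_ms > s$voice_onset_ms))
  # next word appears 500 ms after the previous voice offset
  expect_equal(s$visual_onset_ms[-1] - s$voice_offset_ms[-nrow(s)],
               rep(500, nrow(s) - 1))
  # determinism
  expect_identical(generate_reading_session(p, seed = 7), s)
})

test_that("repetition pairing matches a brute-force duplicate scan", {
  p <- reading_gen_params(n_blocks = 2)
  s <- generate_reading_session(p, seed = 12)
  pr <- pair_repetitions(s, drop_errors = FALSE)
  brute <- sum(table(s$token) == 2L)
  expect_equal(nrow(pr), brute)
  expect_true(all(pr$n_intervening >= 1))
  expect_true(all(pr$delta_t > 0))
  # with error dropping, pairs can only be lost
  expect_lte(nrow(pair_repetitions(s)), brute)
})

test_that("positions and lags are computed per presentation order", {
  s <- data.frame(
    token = c("aa", "bb", "aa", "cc", "dd"),
    block = 1L,
    visual_onset_ms = c(0, 1500, 3000, 4500, 6000),
    voice_onset_ms = c(800, 2300, 3600, 5300, 6800),
    voice_offset_ms = c(1000, 2500, 3800, 5500, 7000),
    correct = TRUE)
  pr <- pair_repetitions(s)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$n_intervening, 1L)
  expect_equal(pr$rt_first, 800)
  expect_equal(pr$rt_second, 600)
  expect_equal(pr$delta_t, 2.0)  # 3000 ms onset - 1000 ms offset
  on <- pair_repetitions(s, lag_def = "onset_onset")
  expect_equal(on$delta_t, 3.0)
  # a token presented once yields no pair; three times errors
  expect_equal(nrow(pair_repetitions(s[1:2, ])), 0)
  s3 <- rbind(s, s[1, ])
  s3$visual_onset_ms[6] <- 9000
  expect_error(pair_repetitions(s3), class = "memdecay_config_error")
})

test_that("benefit arithmetic and scale invariance hold", {
  pr <- data.frame(token = c("x", "y"), rt_first = c(800, 700),
                   rt_second = c(600, 700), delta_t = c(1.5, 10),
                   n_intervening = c(1L, 20L))
  rb <- repetition_benefit(pr)
  expect_equal(rb$mean_benefit_pct, c(25, 0))
  expect_equal(rb$mean_benefit_ms, c(200, 0))
  # uniform slowdown leaves percentages unchanged
  pr2 <- pr
  pr2$rt_first <- pr$rt_first * 1.8
  pr2$rt_second <- pr$rt_second * 1.8
  expect_equal(repetition_benefit(pr2)$mean_benefit_pct, rb$mean_benefit_pct)
  # empty bins are flagged
  rb3 <- repetition_benefit(pr[pr$delta_t < 2, ])
  expect_true(rb3$flagged[2])
  expect_true(is.na(rb3$mean_benefit_pct[2]))
})

test_that("planted benefit decay shows up across the lag bins", {
  p <- reading_gen_params(benefit0 = 30, benefit_floor = 10, tau_read = 4)
  bins <- t(vapply(1:6, function(i) {
    s <- generate_reading_session(p, seed = 100 + i)
    rb <- repetition_benefit(pair_repetitions(s))
    c(rb$mean_benefit_pct[1], rb$mean_benefit_pct[2])
  }, numeric(2)))
  expect_gt(mean(bins[, 1], na.rm = TRUE), mean(bins[, 2], na.rm = TRUE))
})

test_that("a cohort recovers its planted bin-mean benefits", {
  p <- reading_gen_params()  # 30 -> 12%, tau 6 s
  res <- t(vapply(1:10, function(i) {
    s <- generate_reading_session(p, seed = 500 + i)
    rb <- repetition_benefit(pair_repetitions(s))
    c(short = rb$mean_benefit_pct[1], long = rb$mean_benefit_pct[2],
      lag = rb$mean_delta_t[1])
  }, numeric(3)))
  short <- mean(res[, 1], na.rm = TRUE)
  long <- mean(res[, 2], na.rm = TRUE)
  exp_short <- 12 + (30 - 12) * exp(-mean(res[, 3], na.rm = TRUE) / 6)
  expect_rel_equal(short, exp_short, 0.2)
  # the long bin sits near the floor plus a small above-floor remnant
  expect_rel_equal(long, 13, 0.2)
})

test_that("reading sessions round-trip through CSV", {
  s <- generate_reading_session(reading_gen_params(n_blocks = 1), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_reading_csv(s, path)
  back <- read_reading_csv(path)
  expect_equal(back$token, s$token)
  expect_equal(back$voice_onset_ms, s$voice_onset_ms, tolerance = 1e-9)
  expect_equal(back$correct, s$correct)
})
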