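fs <- 256

make_rec <- function(x, events = data.frame(onset_s = numeric(),
                                            kind = character())) {
  eeg_recording(x, fs, events)
}

test_that("the band-pass keeps the passband and kills line noise and DC", {
  t <- seq(0, 20, by = 1 / fs)
  sin5 <- make_rec(sin(2 * pi * 5 * t))
  out5 <- bandpass_filter(sin5)$samples
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  atten5 <- max(abs(out5[mid])) / 1
  expect_gt(atten5, 0.95)

  dc <- make_rec(rep(50, length(t)))
  expect_lt(abs(mean(bandpass_filter(dc)$samples[mid])), 0.5)

  sin60 <- make_rec(sin(2 * pi * 60 * t))
  expect_lt(max(abs(bandpass_filter(sin60)$samples[mid])), 0.1)

  expect_error(bandpass_filter(eeg_recording(rnorm(100), 50,
                                             data.frame(onset_s = 1,
                                                        kind = "tone1"))),
               class = "memdecay_config_error")
})

test_that("rule 1: an absolute excursion rejects +/-300 ms, sample-exact", {
  x <- rep(0, 10 * fs)
  hit <- 5 * fs
  x[hit] <- 120
  m <- detect_artifacts(make_rec(x))
  pad <- round(0.3 * fs)
  # the spike also fires the adjacent-step rule on the pairs (hit-1, hit)
  # and (hit, hit+1), so the union extends one sample each side
  expected <- rep(FALSE, length(x))
  expected[(hit - pad - 1L):(hit + pad + 1L)] <- TRUE
  expect_identical(m$mask, expected)
  expect_true("abs_100uV" %in% m$spans$rule)
  # rule 1 alone covers exactly +/-300 ms around the sample
  r1 <- m$spans[m$spans$rule == "abs_100uV", ]
  expect_equal(r1$start, hit - pad)
  expect_equal(r1$end, hit + pad)
})

test_that("rule 2: a fast 100 uV swing rejects +/-200 ms without rule 1", {
  # ramp rising ~110 uV over 40 ms, peak below the absolute threshold,
  # followed by a slow descent so the adjacent-step rule stays silent
  x <- rep(0, 10 * fs)
  ramp_len <- round(0.04 * fs)  # ~10 samples
  i0 <- 5 * fs
  x[i0:(i0 + ramp_len)] <- seq(-20, 90, length.out = ramp_len + 1)
  down <- seq(90, 0, length.out = 41)
  x[(i0 + ramp_len + 1):(i0 + ramp_len + 41)] <- down
  m <- detect_artifacts(make_rec(x))
  expect_false(any(abs(x) > 100))           # rule 1 cannot fire
  expect_false(any(abs(diff(x)) > 50))      # rule 3 cannot fire
  expect_true(any(m$mask))
  expect_true(all(m$spans$rule == "range_100uV_50ms"))
  # the window around the swing is rejected out to +/-200 ms of the
  # offending 50 ms windows
  w50 <- max(2L, round(0.05 * fs) + 1L)
  starts <- which(vapply(seq_len(length(x) - w50 + 1L), function(i) {
    seg <- x[i:(i + w50 - 1L)]
    max(seg) - min(seg) > 100
  }, logical(1)))
  pad <- round(0.2 * fs)
  expected <- rep(FALSE, length(x))
  for (s in starts) {
    expected[max(1, s - pad):min(length(x), s + w50 - 1L + pad)] <- TRUE
  }
  expect_identical(m$mask, expected)
})

test_that("rule 3: an adjacent-sample step rejects +/-300 ms", {
  x <- rep(0, 10 * fs)
  i0 <- 4 * fs
  x[i0:length(x)] <- 60  # single 60 uV step
  m <- detect_artifacts(make_rec(x))
  pad <- round(0.3 * fs)
  expected <- rep(FALSE, length(x))
  expected[(i0 - 1L - pad):(i0 + pad)] <- TRUE
  expect_identical(m$mask, expected)
})

test_that("adding an artifact never shrinks the rejection", {
  set.seed(3)
  x <- rnorm(10 * fs, 0, 10)
  m1 <- detect_artifacts(make_rec(x))
  x2 <- x
  x2[3 * fs] <- 150
  m2 <- detect_artifacts(make_rec(x2))
  expect_gte(sum(m2$mask), sum(m1$mask))
  expect_true(all(m2$mask[m1$mask]))
})

test_that("epochs are baseline-corrected and boundary epochs dropped", {
  n <- 10 * fs
  x <- rep(10, n)  # constant offset
  ev <- data.frame(onset_s = c(0.6, 5), kind = "tone1")
  ep <- epoch_and_baseline(make_rec(x, ev), NULL)
  # the 0.6 s event needs samples 0.5 s before onset: retained (0.1 s margin)
  expect_equal(ep$n_total, 2)
  expect_equal(ep$n_dropped, 0)
  base_idx <- ep$time_s >= -0.5 & ep$time_s <= -0.15
  expect_equal(mean(ep$epochs[2, base_idx]), 0, tolerance = 1e-12)
  # an event too close to the start is dropped
  ev2 <- data.frame(onset_s = c(0.3, 5), kind = "tone1")
  ep2 <- epoch_and_baseline(make_rec(x, ev2), NULL)
  expect_equal(ep2$n_dropped, 1)
  expect_equal(nrow(ep2$epochs), 1)
})

test_that("epoch survival matches a brute-force overlap count", {
  set.seed(11)
  n <- 60 * fs
  x <- rnorm(n, 0, 5)
  idx <- sample(n, 8)
  x[idx] <- 130
  onsets <- seq(2, 55, by = 2.5)
  rec <- make_rec(x, data.frame(onset_s = onsets, kind = "tone1"))
  m <- detect_artifacts(rec)
  ep <- epoch_and_baseline(rec, m)
  pre_n <- round(0.5 * fs)
  len <- round(2 * fs)
  brute <- sum(vapply(onsets, function(on) {
    i0 <- round(on * fs) + 1L - pre_n
    !any(m$mask[i0:(i0 + len - 1L)])
  }, logical(1)))
  expect_equal(nrow(ep$epochs), brute)
  expect_lte(nrow(ep$epochs), length(onsets))
})

test_that("component areas integrate the average over the stated windows", {
  len <- round(2 * fs)
  time_s <- (seq_len(len) - 1L - round(0.5 * fs)) / fs
  # constant +1 uV across 150-250 ms -> P2 area = 100 uV*ms (rectangle)
  y <- ifelse(time_s >= 0.150 - 1e-9 & time_s <= 0.250 + 1e-9, 1, 0)
  ep <- list(epochs = rbind(y), time_s = time_s, n_total = 1, n_dropped = 0)
  a <- average_and_area(ep, "p2", fs)
  expect_equal(a$area, 100, tolerance = 2.5)
  # constant -2 uV across 70-130 ms -> N1 area = -120 uV*ms
  y2 <- ifelse(time_s >= 0.070 - 1e-9 & time_s <= 0.130 + 1e-9, -2, 0)
  ep2 <- list(epochs = rbind(y2), time_s = time_s, n_total = 1, n_dropped = 0)
  a2 <- average_and_area(ep2, "n1", fs)
  expect_equal(a2$area, -120, tolerance = 5)
  expect_error(average_and_area(list(epochs = matrix(numeric(0), 0, len),
                                     time_s = time_s),
                                "p2", fs),
               class = "memdecay_empty_block")
})

test_that("measured areas are linear in the signal amplitude", {
  p <- erp_gen_params(noise_sd = 0, artifact_rate = 0)
  rec <- generate_eeg(block_schedule(20, 3.5), p)
  a1 <- erp_block_areas(rec)
  rec2 <- rec
  rec2$samples <- 3 * rec$samples
  a2 <- erp_block_areas(rec2)
  expect_equal(a2$area_uv_ms, 3 * a1$area_uv_ms, tolerance = 1e-8)
})
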