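# Shared test helpers: constructed sequences and an independent phi oracle.

# Build a trial sequence with explicit tone values (constant ITI).
make_seq <- function(f1, f2, iti = 1.4) {
  memdecay:::build_sequence(f1, f2, iti, "test", f_band = range(c(f1, f2)),
                            df_band = c(1, 30), tone_dur = 0.05,
                            inter_tone = 0.6)
}

# Independent phi coefficient via an explicit 2x2 contingency count.
phi_oracle <- function(a, b) {
  a <- a > 0
  b <- b > 0
  n11 <- sum(a & b)
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  n00 <- sum(!a & !b)
  num <- n11 * n00 - n10 * n01
  den <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(NA_real_)
  num / den
}

# Brute-force Mann-Whitney U (number of (x, y) pairs with x > y, + ties/2).
u_oracle <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) {
    u <- u + (xi > yi) + 0.5 * (xi == yi)
  }
  u
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
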