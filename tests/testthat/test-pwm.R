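test_that("HOCOMOCO-style parsing round-trips and rejects malformed input", {
  w <- matrix(round(rnorm(48), 4), nrow = 12, dimnames = list(NULL, BASES))
  pwm <- new_pwm("TOY_MOTIF.0.A", w,
                 thresholds = c("0.001" = 5.5, "0.0001" = 8.11))
  f <- withr::local_tempfile(fileext = ".pwm")
  write_pwm(pwm, f)
  back <- read_pwm(f)
  expect_equal(back$name, "TOY_MOTIF.0.A")
  expect_equal(back$length, 12L)
  expect_equal(back$weights, pwm$weights, tolerance = 1e-9)
  expect_equal(unname(back$thresholds), unname(pwm$thresholds))
  expect_equal(pwm_threshold(back, 1e-4), 8.11)

  bad <- withr::local_tempfile()
  writeLines(c(">X", "1 2 3"), bad)
  expect_error(read_pwm(bad), "expected 4 columns")
  writeLines(c(">X", "1 2 3 oops"), bad)
  expect_error(read_pwm(bad), "non-numeric")
  writeLines(c("1 2 3 4"), bad)
  expect_error(read_pwm(bad), "header")
})

test_that("threshold tables must be monotone and are level-addressable", {
  expect_error(new_pwm("X", matrix(0, 1, 4),
                       thresholds = c("0.001" = 2, "0.0001" = 5)), NA)
  expect_error(new_pwm("X", matrix(0, 1, 4),
                       thresholds = c("0.01" = 1, "0.0001" = 1)), NA)
  # smaller p must not have the smaller score
  expect_error(new_pwm("X", matrix(0, 1, 4),
                       thresholds = c("0.001" = 5, "0.0001" = 2)),
               "monotone")
  pwm <- new_pwm("X", matrix(0, 1, 4), thresholds = c("0.0001" = 8))
  expect_error(pwm_threshold(pwm, 0.05), "no threshold")
  expect_error(pwm_threshold(new_pwm("X", matrix(0, 1, 4)), 1e-4),
               "no threshold table")
})

test_that("window scoring matches hand enumeration on toy matrices", {
  zero <- new_pwm("ZERO", matrix(0, nrow = 4, ncol = 4))
  expect_identical(score_window(zero, "ACGT"), 0)

  w <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 2))
  toy <- new_pwm("DIMER", w)
  expect_identical(score_window(toy, "AT"), 3)
  for (b1 in BASES) for (b2 in BASES) {
    expected <- w[1, match(b1, BASES)] + w[2, match(b2, BASES)]
    expect_identical(score_window(toy, paste0(b1, b2)), expected)
  }

  # N scores the positional minimum
  wn <- rbind(c(5, -1, 2, 0), c(1, 1, 1, 1))
  expect_identical(score_window(new_pwm("N", wn), "NA"), -1 + 1)

  expect_error(score_window(toy, "ACG"), "length")
  expect_error(score_window(toy, ""), "non-empty")
})

test_that("reverse complement is an involution on the ACGTN alphabet", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("TGTTTGCACA"), "TGTGCAAACA")
  expect_identical(reverse_complement("N"), "N")
  expect_error(reverse_complement(""), "empty")
  expect_error(reverse_complement("ACGU"), "illegal")
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- random_seq(sample(1:40, 1))
      expect_identical(reverse_complement(reverse_complement(s)), s)
      expect_identical(reverse_complement(s), naive_revcomp(s))
    }
  })
})

test_that("best-strand scores equal an exhaustive naive scan", {
  withr::with_seed(202, {
    for (i in 1:200) {
      L <- sample(2:12, 1)
      w <- random_weights(L)
      pwm <- new_pwm("R", w)
      seq <- random_seq(L + sample(0:20, 1))
      got <- best_strand_scores(pwm, seq)
      want <- naive_best_scores(w, seq)
      expect_equal(got$plus$score, unname(want["plus"]), tolerance = 1e-9)
      expect_equal(got$minus$score, unname(want["minus"]), tolerance = 1e-9)
      expect_gte(got$plus$score, 0)
      expect_gte(got$minus$score, 0)
    }
  })
  pwm <- new_pwm("S", random_weights(5))
  expect_error(best_strand_scores(pwm, "ACGT"), "shorter")
})

test_that("strand symmetry: scanning a sequence equals scanning its reverse complement on the other strand", {
  withr::with_seed(303, {
    for (i in 1:20) {
      pwm <- new_pwm("R", random_weights(6))
      s <- random_seq(15)
      a <- best_strand_scores(pwm, s)
      b <- best_strand_scores(pwm, reverse_complement(s))
      expect_equal(a$plus$score, b$minus$score, tolerance = 1e-12)
      expect_equal(a$minus$score, b$plus$score, tolerance = 1e-12)
    }
  })
})

test_that("adding a constant to one position shifts every window score by that constant", {
  withr::with_seed(404, {
    pwm <- new_pwm("R", random_weights(7))
    s <- random_seq(30)
    base <- vapply(1:(30 - 7 + 1), function(st) {
      score_window(pwm, substr(s, st, st + 6))
    }, numeric(1))
    w2 <- pwm$weights
    w2[3, ] <- w2[3, ] + 1.75
    pwm2 <- new_pwm("R2", w2)
    shifted <- vapply(1:(30 - 7 + 1), function(st) {
      score_window(pwm2, substr(s, st, st + 6))
    }, numeric(1))
    expect_equal(shifted, base + 1.75, tolerance = 1e-12)
  })
})

test_that("clamping reports 0 for negative best scores but keeps the raw optimum", {
  pwm <- new_pwm("NEG", matrix(-1, nrow = 3, ncol = 4))
  r <- best_strand_scores(pwm, "ACGTACG")
  expect_identical(r$plus$score, 0)
  expect_identical(r$plus$raw, -3)
  expect_identical(r$minus$score, 0)
})

test_that("tied best windows resolve to the smallest start offset", {
  # consensus AA; sequence has equally scoring windows at offsets 1 and 3
  w <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  pwm <- new_pwm("AA", w)
  r <- best_strand_scores(pwm, "AACAA")
  expect_identical(r$plus$start_offset, 1L)
})
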