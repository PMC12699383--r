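test_that("WER matches hand-checked alignments", {
  expect_equal(compute_wer("the cat sat", "the cat sat"), 0)
  expect_equal(compute_wer("the cat sat", "the bat sat"), 1 / 3)
  ref9 <- paste(letters[1:9], collapse = " ")
  hyp8 <- paste(letters[c(1:4, 6:9)], collapse = " ")  # one word deleted
  expect_equal(compute_wer(ref9, hyp8), 1 / 9)
  expect_equal(compute_wer("a b c", ""), 1)            # empty hypothesis
  expect_error(compute_wer("", "something"), "at least one word",
               class = "lexi_validation_error")
  # tokenization folds case and punctuation
  expect_equal(compute_wer("The CAT, sat.", "the cat sat"), 0)
})

test_that("WER equals the minimal edit distance (DP oracles)", {
  # exhaustive over a 2-word alphabet, lengths 0..6, vs C Levenshtein
  alphabet <- c("cat", "dog")
  seqs <- enumerate_sequences(alphabet, 6)
  refs <- seqs[lengths(seqs) > 0L]
  got <- want <- numeric(0)
  for (a in refs) {
    for (b in seqs) {
      got <- c(got, compute_wer(a, b) * length(a))
      want <- c(want, adist_token_distance(a, b, alphabet))
    }
  }
  expect_equal(got, want)
  # spot-check against the recursive brute-force oracle, 3-word alphabet
  alpha3 <- c("cat", "dog", "sun")
  set.seed(7)
  for (i in 1:200) {
    a <- sample(alpha3, sample(1:6, 1), replace = TRUE)
    b <- sample(alpha3, sample(0:6, 1), replace = TRUE)
    expect_equal(compute_wer(a, b) * length(a), oracle_edit_distance(a, b))
  }
})

test_that("pauses keep only strictly positive gaps", {
  t <- data.frame(word = c("a", "b", "c"),
                  start = c(0.0, 0.8, 1.25), end = c(0.5, 1.2, 1.6))
  expect_equal(compute_pauses(t), c(0.3, 0.05))

  contiguous <- data.frame(word = c("a", "b"), start = c(0, 0.5),
                           end = c(0.5, 1.0))
  expect_length(compute_pauses(contiguous), 0L)

  overlap <- data.frame(word = c("a", "b"), start = c(0, 0.4),
                        end = c(0.5, 1.0))  # negative gap discarded
  expect_length(compute_pauses(overlap), 0L)

  unordered <- data.frame(word = c("a", "b"), start = c(1, 0),
                          end = c(1.5, 0.5))
  expect_error(compute_pauses(unordered), "ordered",
               class = "lexi_validation_error")
})

test_that("timing features follow the printed formulas", {
  # 20 contiguous words spanning exactly 15 s -> WPM 80
  starts <- seq(0, by = 0.75, length.out = 20)
  t <- data.frame(word = sprintf("w%d", 1:20), start = starts,
                  end = starts + 0.75)
  f <- compute_timing_features(t, wer = 0)
  expect_equal(f$wpm, 80)
  # no gaps: speech time equals total time, articulation rate = wpm / 60
  expect_equal(f$speech_time, f$total_time)
  expect_equal(f$articulation_rate, f$wpm / 60)
  expect_equal(f$pause_count, 0L)
  expect_equal(f$mean_pause, 0)

  # the 0.2 s pause cutoff is strict: 0.19 does not count, 0.21 does
  t2 <- data.frame(word = c("a", "b", "c"),
                   start = c(0, 0.69, 1.40), end = c(0.5, 1.19, 1.9))
  f2 <- compute_timing_features(t2, wer = 0)
  expect_equal(f2$pause_count, 1L)
  expect_equal(f2$pauses, c(0.19, 0.21))

  degenerate <- data.frame(word = "a", start = 1, end = 1)
  expect_error(compute_timing_features(degenerate), "degenerate",
               class = "lexi_validation_error")
})

test_that("the three-criterion rule score uses inclusive boundaries", {
  mk <- function(wer, pauses, wpm) list(wer = wer, pause_count = pauses,
                                        wpm = wpm)
  r0 <- speech_risk_score(mk(0.05, 2, 120))
  expect_equal(r0$score, 0L)
  expect_identical(r0$label, "Typical")

  # all three boundaries are inclusive
  r3 <- speech_risk_score(mk(0.15, 5, 80))
  expect_equal(r3$score, 3L)
  expect_identical(r3$label, "Likely Dyslexia")
  expect_setequal(r3$triggered_criteria, c("WER", "PAUSES", "WPM"))

  # just inside the typical side of each boundary
  expect_equal(speech_risk_score(mk(0.1499, 4, 80.01))$score, 0L)

  # one criterion alone stays Typical (decision needs >= 2)
  r1 <- speech_risk_score(mk(0.20, 0, 120))
  expect_equal(r1$score, 1L)
  expect_identical(r1$label, "Typical")
})

test_that("the rule score is monotone and covers all criterion subsets", {
  base <- list(wer = 0.05, pause_count = 0, wpm = 120)
  worst <- list(wer = 0.5, pause_count = 9, wpm = 40)
  # monotone: worsening any one feature never lowers the score
  for (feat in names(base)) {
    w <- base; w[[feat]] <- worst[[feat]]
    expect_gte(speech_risk_score(w)$score, speech_risk_score(base)$score)
  }
  # 2^3 criterion combinations; label iff >= 2 triggered
  grid <- expand.grid(wer = c(0.05, 0.5), pauses = c(0, 9),
                      wpm = c(120, 40))
  for (r in seq_len(nrow(grid))) {
    res <- speech_risk_score(list(wer = grid$wer[r],
                                  pause_count = grid$pauses[r],
                                  wpm = grid$wpm[r]))
    n_expected <- (grid$wer[r] >= 0.15) + (grid$pauses[r] >= 5) +
      (grid$wpm[r] <= 80)
    expect_equal(res$score, n_expected)
    expect_identical(res$label,
                     if (n_expected >= 2) "Likely Dyslexia" else "Typical")
  }
})

test_that("timings round-trip through JSON and drive the full screen", {
  t <- gen_word_timings(20, 70, list(n = 6, duration = 0.5), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(t, path, digits = I(12))
  t2 <- read_word_timings(path)
  expect_equal(t2$start, t$start, tolerance = 1e-9)

  res <- speech_screen("a b c d e", "a b x d e", t2)
  expect_equal(res$features$wer, 1 / 5)
  expect_s3_class(res$risk, "speech_risk")
})
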