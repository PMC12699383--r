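mk_session <- function(gaze = NULL, speech = NULL, handwriting = NULL,
                       quiz = NULL) {
  session_record(session_id = "t1", timestamp = "2026-01-01T00:00:00Z",
                 gaze = gaze, speech = speech, handwriting = handwriting,
                 quiz = quiz)
}

mk_speech <- function(score) {
  t <- gen_word_timings(20, if (score >= 1) 60 else 150,
                        list(n = 0, duration = 0), seed = 1)
  f <- compute_timing_features(t, wer = 0.01)
  list(features = f, risk = speech_risk_score(f))
}

test_that("fusion maps, weights and renormalizes over present modalities", {
  # single modality passes through unchanged
  s <- combine_scores(mk_session(gaze = list(label = "dyslexic",
                                             probability = 1.0)))
  expect_equal(s$combined$score, 1.0)
  expect_identical(s$combined$band, "High")

  q0 <- score_quiz(rep(0, 9))
  s0 <- combine_scores(mk_session(quiz = q0))
  expect_equal(s0$combined$score, 0)
  expect_identical(s0$combined$band, "Low")

  # gaze 0.8 and speech rule score 1 with equal weights
  sp <- mk_speech(1)
  expect_equal(sp$risk$score, 1L)
  s2 <- combine_scores(mk_session(
    gaze = list(label = "dyslexic", probability = 0.8), speech = sp))
  expect_equal(s2$combined$score, 0.5 * 0.8 + 0.5 * (1 / 3))

  expect_error(combine_scores(mk_session()), "no modality",
               class = "lexi_validation_error")
})

test_that("combined scores are bounded, monotone, and weight-invariant", {
  q <- score_quiz(rep(2, 9))
  hw <- handwriting_screen("big dog ran", "dig bog ran")
  base <- mk_session(gaze = list(label = "typical", probability = 0.2),
                     quiz = q, handwriting = hw)
  c_base <- combine_scores(base)$combined$score
  expect_gte(c_base, 0); expect_lte(c_base, 1)

  # monotone in the gaze probability
  higher <- base; higher$gaze$probability <- 0.9
  expect_gt(combine_scores(higher)$combined$score, c_base)

  # a zero-weight absent modality changes nothing: drop speech entirely vs
  # configure it with weight zero
  cfg0 <- lexi_config()
  cfg0$fusion$weights <- c(gaze = 1, speech = 0, handwriting = 1, quiz = 1)
  with_speech <- base
  with_speech$speech <- mk_speech(1)
  expect_equal(combine_scores(with_speech, cfg0)$combined$score,
               combine_scores(base)$combined$score)
})

test_that("reports are lossless JSON plus complete HTML", {
  t <- gen_word_timings(18, 70, list(n = 6, duration = 0.5), seed = 2)
  f <- compute_timing_features(t, wer = 0.2)
  session <- combine_scores(mk_session(
    gaze = list(label = "dyslexic", probability = 0.83),
    speech = list(features = f, risk = speech_risk_score(f)),
    handwriting = handwriting_screen("big dog", "dig bog"),
    quiz = score_quiz(c(1, 2, 0, 3, 1, 2, 0, 1, 2))))
  rep <- render_report(session)

  # JSON round-trips to an equal session record
  back <- session_from_json(rep$json)
  expect_equal(back, session, tolerance = 1e-12)

  # HTML carries every section, the diff view and the fusion config
  expect_match(rep$html, "Combined")
  expect_match(rep$html, "Character diff")
  expect_match(rep$html, "<del>")
  expect_match(rep$html, "Fusion configuration")
  expect_match(rep$html, "Behavioural quiz")

  # minimal session: absent modalities serialize as null
  minimal <- combine_scores(mk_session(quiz = score_quiz(rep(1, 9))))
  j <- jsonlite::fromJSON(render_report(minimal)$json,
                          simplifyVector = FALSE)
  expect_null(j$gaze)
  expect_null(j$handwriting)
})

test_that("the session log appends newline-delimited JSON robustly", {
  log <- withr::local_tempfile(fileext = ".ndjson")
  s1 <- combine_scores(mk_session(quiz = score_quiz(rep(1, 9))))
  s2 <- combine_scores(mk_session(quiz = score_quiz(rep(2, 9))))
  append_session_log(s1, log)
  expect_length(readLines(log), 1L)
  append_session_log(s2, log)
  lines <- readLines(log)
  expect_length(lines, 2L)

  sessions <- read_session_log(log)
  expect_length(sessions, 2L)
  expect_equal(sessions[[1]]$quiz$total, 9L)
  expect_equal(sessions[[2]]$quiz$total, 18L)

  # a corrupt line does not break appending or reading; it is flagged
  cat("{not json\n", file = log, append = TRUE)
  append_session_log(s1, log)
  sessions2 <- read_session_log(log)
  expect_length(sessions2, 3L)
  expect_equal(attr(sessions2, "bad_lines"), 3L)
})
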