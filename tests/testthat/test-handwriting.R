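seed_sentence <- "The quick brown fox jumps over the lazy dog"

test_that("normalization is NFKC + lowercase and idempotent", {
  expect_identical(normalize_text("The Quick"), "the quick")
  expect_identical(normalize_text("ＡＢＣ"), "abc")  # full-width ABC
  x <- normalize_text("already normalized text")
  expect_identical(normalize_text(x), x)
  # whitespace preserved
  expect_identical(normalize_text("a  b"), "a  b")
})

test_that("input validation enforces presence and the 500-word cap", {
  w500 <- paste(rep("word", 500), collapse = " ")
  expect_true(validate_input(w500, "something"))
  w501 <- paste(rep("word", 501), collapse = " ")
  expect_error(validate_input(w501, "something"), "exceeds 500",
               class = "lexi_too_long")
  expect_error(validate_input(NULL, "x"), class = "lexi_missing_expected")
  expect_error(validate_input("expected", ""), "no recognized text",
               class = "lexi_missing_actual")
})

test_that("alignment opcodes partition both strings deterministically", {
  ops <- align_texts("dog", "bog")
  expect_identical(ops$tag, c("replace", "equal"))
  expect_identical(ops[1, c("i1", "i2", "j1", "j2")],
                   data.frame(i1 = 1L, i2 = 1L, j1 = 1L, j2 = 1L),
                   ignore_attr = TRUE)

  ops2 <- align_texts("cat", "cart")
  expect_identical(ops2$tag, c("equal", "insert", "equal"))
  expect_identical(ops2$j1[2], 3L)
  expect_identical(ops2$j2[2], 3L)

  ident <- align_texts("same", "same")
  expect_identical(ident$tag, "equal")
  expect_identical(ident$i2, 4L)

  # opcodes partition both strings for random pairs
  set.seed(11)
  for (i in 1:50) {
    e <- random_string(sample(1:12, 1))
    a <- random_string(sample(1:12, 1))
    ops <- align_texts(e, a)
    covered_e <- sum(pmax(ops$i2 - ops$i1 + 1L, 0L))
    covered_a <- sum(pmax(ops$j2 - ops$j1 + 1L, 0L))
    expect_equal(covered_e, nchar(e))
    expect_equal(covered_a, nchar(a))
  }
})

test_that("CER uses the reference-length denominator", {
  e <- normalize_text(seed_sentence)
  expect_equal(nchar(e), 43L)
  r_ident <- compute_error_rates(e, e)
  expect_equal(r_ident$cer, 0)
  expect_equal(r_ident$wer, 0)

  # one substituted character in the printed seed sentence -> 1/43
  a <- sub("quick", "quack", e)
  r <- compute_error_rates(e, a)
  expect_equal(r$cer, 1 / 43)
  expect_equal(r$ops$substitutions, 1L)

  # complete deletion
  r_empty <- compute_error_rates(e, "")
  expect_equal(r_empty$cer, 1)
  expect_error(compute_error_rates("", "x"), class = "lexi_validation_error")
})

test_that("opcode-based CER bounds minimal-distance CER from above", {
  set.seed(13)
  for (i in 1:300) {
    e <- random_string(sample(1:12, 1))
    a <- random_string(sample(0:12, 1))
    cer_ops <- compute_error_rates(e, a)$cer
    cer_min <- compute_error_rates(e, a, minimal = TRUE)$cer
    expect_gte(cer_ops, cer_min - 1e-12)
  }
})

test_that("cer is zero exactly when the normalized strings are identical", {
  set.seed(17)
  for (i in 1:100) {
    e <- random_string(sample(1:10, 1))
    a <- if (i %% 2 == 0) e else random_string(sample(1:10, 1))
    cer <- compute_error_rates(e, a)$cer
    expect_identical(cer == 0, e == a)
  }
})

test_that("letter reversals are counted only inside replace spans", {
  expect_equal(count_reversals("pit", "qit"), 1L)
  expect_equal(count_reversals("big dog", "dig bog"), 2L)
  expect_equal(count_reversals("abc", "abc"), 0L)       # no replace opcodes
  expect_equal(count_reversals("cat", "cart"), 0L)      # insert only
  # reversal count never exceeds the substitution count
  set.seed(19)
  for (i in 1:100) {
    e <- random_string(sample(1:12, 1), alphabet = c("b", "d", "p", "q", "a"))
    a <- random_string(sample(1:12, 1), alphabet = c("b", "d", "p", "q", "a"))
    ops <- align_texts(e, a)
    expect_lte(count_reversals(e, a, ops), count_edit_ops(ops)$substitutions)
  }
})

test_that("risk scoring sums severity points and bands at 4 and 7", {
  zero <- handwriting_risk_score(0, 0, list(substitutions = 0, insertions = 0,
                                            deletions = 0), 0)
  expect_equal(zero$risk_score, 0L)
  expect_identical(zero$risk_level, "Low")

  # every feature severe: cer 2 + wer 2 + subs 2 + ins 1 + del 1 + rev 2 = 10
  severe <- handwriting_risk_score(0.5, 0.8,
                                   list(substitutions = 5, insertions = 2,
                                        deletions = 3), 2)
  expect_gte(severe$risk_score, 7L)
  expect_identical(severe$risk_level, "High")

  # one two-point feature plus one one-point feature stays just under Moderate
  mild <- handwriting_risk_score(0.30, 0, list(substitutions = 2,
                                               insertions = 0,
                                               deletions = 0), 0)
  expect_equal(mild$risk_score, 3L)
  expect_identical(mild$risk_level, "Low")

  # the bands partition all attainable scores at < 4, 4-6, >= 7
  cfg <- lexi_config()
  for (score in 0:12) {
    lvl <- if (score >= 7) "High" else if (score >= 4) "Moderate" else "Low"
    # craft inputs reaching `score` via substitutions (2), insertions (2),
    # deletions (2), reversals (2), cer (2), wer (2)
    pts <- c(min(score, 2), min(max(score - 2, 0), 2),
             min(max(score - 4, 0), 2), min(max(score - 6, 0), 2),
             min(max(score - 8, 0), 2), min(max(score - 10, 0), 2))
    val2 <- c(4, 4, 4, 2, 0.25, 0.40)
    val1 <- c(2, 2, 2, 1, 0.10, 0.15)
    vals <- ifelse(pts == 2, val2, ifelse(pts == 1, val1, 0))
    res <- handwriting_risk_score(vals[5], vals[6],
                                  list(substitutions = vals[1],
                                       insertions = vals[2],
                                       deletions = vals[3]), vals[4], cfg)
    expect_equal(res$risk_score, score)
    expect_identical(res$risk_level, lvl)
  }
})

test_that("risk score is monotone in every input", {
  base <- handwriting_risk_score(0.05, 0.05,
                                 list(substitutions = 1, insertions = 1,
                                      deletions = 1), 0)
  worse <- list(
    handwriting_risk_score(0.5, 0.05, list(substitutions = 1, insertions = 1,
                                           deletions = 1), 0),
    handwriting_risk_score(0.05, 0.5, list(substitutions = 1, insertions = 1,
                                           deletions = 1), 0),
    handwriting_risk_score(0.05, 0.05, list(substitutions = 5, insertions = 1,
                                            deletions = 1), 0),
    handwriting_risk_score(0.05, 0.05, list(substitutions = 1, insertions = 5,
                                            deletions = 1), 0),
    handwriting_risk_score(0.05, 0.05, list(substitutions = 1, insertions = 1,
                                            deletions = 5), 0),
    handwriting_risk_score(0.05, 0.05, list(substitutions = 1, insertions = 1,
                                            deletions = 1), 3))
  for (w in worse) expect_gte(w$risk_score, base$risk_score)
})

test_that("the full handwriting screen ties the pieces together", {
  hw <- handwriting_screen(seed_sentence, "The quick drown fox jumps over the lazy bog")
  expect_s3_class(hw, "handwriting_metrics")
  expect_equal(hw$substitutions, 2L)
  expect_equal(hw$reversal_count, 2L)     # b->d and d->b
  expect_equal(hw$cer, 2 / 43)
  expect_true(hw$risk_level %in% c("Low", "Moderate", "High"))
  expect_match(hw$message, "risk")
})
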