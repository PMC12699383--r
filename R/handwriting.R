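#' Normalize text for handwriting comparison
#'
#' Unicode NFKC compatibility normalization followed by lowercasing;
#' whitespace is preserved. Applied to both the expected sentence and the
#' transcribed handwriting before alignment so that full-width forms,
#' ligatures and case differences do not register as errors.
#'
#' @param text Character scalar.
#' @return Normalized string.
#' @export
#' @examples
#' normalize_text("The Quick")       # "the quick"
#' normalize_text("ＡＢＣ")  # full-width ABC -> "abc"
normalize_text <- function(text) {
  if (!is.character(text) || length(text) != 1L) {
    lexi_abort("'text' must be a single string")
  }
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(text))
}

#' Validate handwriting-screening inputs
#'
#' Errors when the expected sentence is missing/empty, when the transcribed
#' text is missing/empty (no text was recognized), or when the expected
#' sentence exceeds the word cap (default 500 words). Each failure carries a
#' distinct condition class (`lexi_missing_expected`, `lexi_missing_actual`,
#' `lexi_too_long`), all subclasses of the validation error.
#'
#' @param expected Expected sentence.
#' @param actual Transcribed handwriting string (e.g. OCR output).
#' @param config A [lexi_config()].
#' @return `TRUE` invisibly when valid.
#' @export
validate_input <- function(expected, actual, config = lexi_config()) {
  if (is.null(expected) || !is.character(expected) || length(expected) != 1L ||
      is.na(expected) || !nzchar(trimws(expected))) {
    stop(structure(
      class = c("lexi_missing_expected", "lexi_validation_error",
                "lexi_error", "error", "condition"),
      list(message = "expected sentence is missing", call = NULL)))
  }
  n_words <- length(strsplit(trimws(expected), "[[:space:]]+")[[1]])
  if (n_words > config$handwriting$max_expected_words) {
    stop(structure(
      class = c("lexi_too_long", "lexi_validation_error",
                "lexi_error", "error", "condition"),
      list(message = sprintf("expected sentence exceeds %d words (%d)",
                             config$handwriting$max_expected_words, n_words),
           call = NULL)))
  }
  if (is.null(actual) || !is.character(actual) || length(actual) != 1L ||
      is.na(actual) || !nzchar(actual)) {
    stop(structure(
      class = c("lexi_missing_actual", "lexi_validation_error",
                "lexi_error", "error", "condition"),
      list(message = "no recognized text to compare", call = NULL)))
  }
  invisible(TRUE)
}

# ---- matching-blocks sequence alignment ------------------------------------
# Ratcliff-Obershelp-style matcher: recursively take the longest common
# block (earliest in `a`, then earliest in `b`, on ties) and align the
# flanks. Mirrors the classic SequenceMatcher semantics (no junk handling).

find_longest_match <- function(a, b, alo, ahi, blo, bhi) {
  besti <- alo; bestj <- blo; bestsize <- 0L
  if (ahi < alo || bhi < blo) {
    return(c(besti, bestj, bestsize))
  }
  b2j <- split(blo:bhi, b[blo:bhi])
  j2len <- integer(0)                     # named by b-index, run length
  for (i in alo:ahi) {
    newj2len <- integer(0)
    js <- b2j[[a[i]]]
    if (!is.null(js)) {
      for (j in js) {
        k <- j2len[as.character(j - 1L)]
        k <- if (is.na(k) || length(k) == 0L) 1L else k + 1L
        newj2len[as.character(j)] <- k
        if (k > bestsize) {
          besti <- i - k + 1L
          bestj <- j - k + 1L
          bestsize <- k
        }
      }
    }
    j2len <- newj2len
  }
  c(besti, bestj, bestsize)
}

matching_blocks <- function(a, b) {
  la <- length(a); lb <- length(b)
  queue <- list(c(1L, la, 1L, lb))
  blocks <- list()
  while (length(queue)) {
    q <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    m <- find_longest_match(a, b, q[1L], q[2L], q[3L], q[4L])
    if (m[3L] > 0L) {
      blocks[[length(blocks) + 1L]] <- m
      queue[[length(queue) + 1L]] <- c(q[1L], m[1L] - 1L, q[3L], m[2L] - 1L)
      queue[[length(queue) + 1L]] <- c(m[1L] + m[3L], q[2L],
                                       m[2L] + m[3L], q[4L])
    }
  }
  if (length(blocks)) {
    ord <- order(vapply(blocks, `[`, integer(1), 1L),
                 vapply(blocks, `[`, integer(1), 2L))
    blocks <- blocks[ord]
    # merge adjacent blocks
    merged <- list(blocks[[1L]])
    for (blk in blocks[-1L]) {
      last <- merged[[length(merged)]]
      if (last[1L] + last[3L] == blk[1L] && last[2L] + last[3L] == blk[2L]) {
        merged[[length(merged)]][3L] <- last[3L] + blk[3L]
      } else {
        merged[[length(merged) + 1L]] <- blk
      }
    }
    blocks <- merged
  }
  blocks[[length(blocks) + 1L]] <- c(la + 1L, lb + 1L, 0L)  # sentinel
  blocks
}

#' Character-level alignment between expected and transcribed text
#'
#' Produces the edit-operation list that partitions both strings into
#' `equal`, `replace`, `insert` and `delete` spans, using a matching-blocks
#' (Ratcliff-Obershelp-style) matcher with deterministic tie-breaking
#' (earliest, longest common block). Note these opcodes are not guaranteed
#' to realise the *minimal* edit distance; they mirror the behaviour of
#' classic sequence-matcher diffs.
#'
#' @param expected,actual Normalized strings (see [normalize_text()]).
#' @return Data frame with columns `tag` and 1-based inclusive spans
#'   `i1,i2` (in `expected`) and `j1,j2` (in `actual`); an empty span has
#'   end = start - 1.
#' @export
#' @examples
#' align_texts("cat", "cart")
align_texts <- function(expected, actual) {
  a <- strsplit(expected, "")[[1]]
  b <- strsplit(actual, "")[[1]]
  blocks <- matching_blocks(a, b)
  tag <- character(0); i1 <- integer(0); i2 <- integer(0)
  j1 <- integer(0); j2 <- integer(0)
  i <- 1L; j <- 1L
  for (blk in blocks) {
    ai <- blk[1L]; bj <- blk[2L]; size <- blk[3L]
    t <- NULL
    if (i < ai && j < bj) t <- "replace"
    else if (i < ai) t <- "delete"
    else if (j < bj) t <- "insert"
    if (!is.null(t)) {
      tag <- c(tag, t); i1 <- c(i1, i); i2 <- c(i2, ai - 1L)
      j1 <- c(j1, j); j2 <- c(j2, bj - 1L)
    }
    i <- ai + size; j <- bj + size
    if (size > 0L) {
      tag <- c(tag, "equal"); i1 <- c(i1, ai); i2 <- c(i2, ai + size - 1L)
      j1 <- c(j1, bj); j2 <- c(j2, bj + size - 1L)
    }
  }
  data.frame(tag = tag, i1 = i1, i2 = i2, j1 = j1, j2 = j2,
             stringsAsFactors = FALSE)
}

#' Edit-operation counts from an alignment
#'
#' Tallies substitutions, insertions, deletions and matching characters
#' from the opcode table. A `replace` span of unequal lengths counts
#' position-wise substitutions up to the shorter side; the overhang counts
#' as insertions or deletions.
#'
#' @param ops Opcode data frame from [align_texts()].
#' @return List of class `edit_op_counts`: `substitutions`, `insertions`,
#'   `deletions`, `equal_chars`.
#' @export
count_edit_ops <- function(ops) {
  subs <- ins <- del <- eq <- 0L
  for (r in seq_len(nrow(ops))) {
    le <- ops$i2[r] - ops$i1[r] + 1L
    la <- ops$j2[r] - ops$j1[r] + 1L
    switch(ops$tag[r],
      equal = { eq <- eq + le },
      replace = {
        subs <- subs + min(le, la)
        if (la > le) ins <- ins + (la - le) else del <- del + (le - la)
      },
      insert = { ins <- ins + la },
      delete = { del <- del + le })
  }
  structure(list(substitutions = subs, insertions = ins, deletions = del,
                 equal_chars = eq), class = "edit_op_counts")
}

#' Character and word error rates for a handwriting sample
#'
#' CER = (substitutions + insertions + deletions) / number of characters in
#' the normalized expected sentence (spaces included in the denominator).
#' WER is the minimal word-level edit distance between the whitespace
#' tokenizations (same tokenizer as the speech module), normalized by the
#' expected word count.
#'
#' @param expected,actual Normalized strings.
#' @param ops Optional opcode table (recomputed if omitted). Set
#'   `minimal = TRUE` to base CER on the minimal Levenshtein character
#'   distance instead of the matching-blocks opcodes (sensitivity-analysis
#'   mode; matching-blocks opcodes can over-count relative to the minimum).
#' @param minimal Use minimal character edit distance for CER.
#' @return List with `cer`, `wer`, and the `edit_op_counts` used.
#' @export
compute_error_rates <- function(expected, actual, ops = NULL,
                                minimal = FALSE) {
  n_char <- nchar(expected)
  if (n_char == 0L) lexi_abort("expected sentence is empty")
  if (minimal) {
    dist <- token_edit_distance(strsplit(expected, "")[[1]],
                                strsplit(actual, "")[[1]])
    counts <- NULL
    cer <- dist / n_char
  } else {
    if (is.null(ops)) ops <- align_texts(expected, actual)
    counts <- count_edit_ops(ops)
    cer <- (counts$substitutions + counts$insertions + counts$deletions) /
      n_char
  }
  ref_words <- tokenize_words(expected)
  hyp_words <- tokenize_words(actual)
  wer <- if (length(ref_words) == 0L) {
    lexi_abort("expected sentence has no words")
  } else {
    token_edit_distance(ref_words, hyp_words) / length(ref_words)
  }
  list(cer = cer, wer = wer, ops = counts)
}

#' Count letter reversals in an alignment
#'
#' Scans `replace` spans position-wise (up to the shorter side of the span)
#' and counts aligned character pairs that match a mirror-confusion pair —
#' by default b/d and p/q in both directions, the hallmark reversals of
#' early dyslexic writing. Characters outside `replace` spans never count.
#'
#' @param expected,actual Normalized strings.
#' @param ops Opcode table from [align_texts()] (recomputed if omitted).
#' @param pairs Named character vector mapping each reversible letter to its
#'   mirror (default `c(b="d", d="b", p="q", q="p")`).
#' @return Integer reversal count.
#' @export
#' @examples
#' count_reversals("big dog", "dig bog")  # 2
count_reversals <- function(expected, actual, ops = NULL,
                            pairs = lexi_config()$handwriting$reversal_pairs) {
  if (is.null(ops)) ops <- align_texts(expected, actual)
  e <- strsplit(expected, "")[[1]]
  a <- strsplit(actual, "")[[1]]
  count <- 0L
  rep_rows <- which(ops$tag == "replace")
  for (r in rep_rows) {
    k <- min(ops$i2[r] - ops$i1[r], ops$j2[r] - ops$j1[r])
    for (off in 0:k) {
      ec <- e[ops$i1[r] + off]
      ac <- a[ops$j1[r] + off]
      if (!is.na(pairs[ec]) && identical(unname(pairs[ec]), ac)) {
        count <- count + 1L
      }
    }
  }
  count
}

#' Rule-based handwriting risk score and band
#'
#' Each of the six features — CER, WER, substitutions, insertions,
#' deletions, reversal count — contributes 0, 1 or 2 points depending on
#' severity (the per-feature thresholds live in
#' `config$handwriting$severity` and are fully overridable). The summed
#' score is banded: at or above 7 High risk ("screening recommended"), 4--6
#' Moderate ("monitor and retest"), below 4 Low ("no significant
#' indicators").
#'
#' @param cer,wer Error rates.
#' @param ops An `edit_op_counts` (or list with the three counters).
#' @param reversal_count Letter reversal count.
#' @param config A [lexi_config()].
#' @return List: `risk_score` (integer), `risk_level`
#'   (`"Low"|"Moderate"|"High"`), `points` (per-feature breakdown),
#'   `message`.
#' @export
handwriting_risk_score <- function(cer, wer, ops, reversal_count,
                                   config = lexi_config()) {
  hw <- config$handwriting
  sev <- hw$severity
  values <- c(cer = cer, wer = wer,
              substitutions = ops$substitutions,
              insertions = ops$insertions,
              deletions = ops$deletions,
              reversals = reversal_count)
  points <- vapply(seq_len(nrow(sev)), function(r) {
    v <- values[[sev$feature[r]]]
    if (v >= sev$two_point[r]) 2L else if (v >= sev$one_point[r]) 1L else 0L
  }, integer(1))
  names(points) <- sev$feature
  score <- sum(points)
  level <- if (score >= hw$high_cut) "High"
           else if (score >= hw$moderate_cut) "Moderate"
           else "Low"
  message <- switch(level,
    High = "High risk: immediate and detailed screening recommended.",
    Moderate = "Moderate risk: monitor for patterns and retest.",
    Low = "Low risk: no significant dyslexia indicators found.")
  list(risk_score = as.integer(score), risk_level = level, points = points,
       message = message)
}

#' Full handwriting screening
#'
#' End-to-end pipeline: input validation, NFKC/lowercase normalization,
#' matching-blocks alignment, edit-operation counting, CER/WER, letter
#' reversal counting, and risk banding.
#'
#' @param expected Expected sentence the child was asked to write.
#' @param actual Transcribed handwriting string (e.g. from an OCR engine;
#'   no engine is bundled — any transcriber can be plugged in upstream).
#' @param config A [lexi_config()].
#' @return List of class `handwriting_metrics` containing the normalized
#'   texts, opcode table, counts, `cer`, `wer`, `reversal_count`,
#'   `risk_score`, `risk_level` and advisory `message`.
#' @export
#' @examples
#' handwriting_screen("The quick brown fox", "The quick drown fox")
handwriting_screen <- function(expected, actual, config = lexi_config()) {
  validate_input(expected, actual, config)
  e <- normalize_text(expected)
  a <- normalize_text(actual)
  ops <- align_texts(e, a)
  rates <- compute_error_rates(e, a, ops)
  reversals <- count_reversals(e, a, ops,
                               pairs = config$handwriting$reversal_pairs)
  risk <- handwriting_risk_score(rates$cer, rates$wer, rates$ops, reversals,
                                 config)
  structure(list(
    expected = e, actual = a, opcodes = ops,
    substitutions = rates$ops$substitutions,
    insertions = rates$ops$insertions,
    deletions = rates$ops$deletions,
    equal_chars = rates$ops$equal_chars,
    cer = rates$cer, wer = rates$wer,
    reversal_count = reversals,
    risk_score = risk$risk_score,
    risk_level = risk$risk_level,
    points = risk$points,
    message = risk$message
  ), class = "handwriting_metrics")
}

#' @export
print.handwriting_metrics <- function(x, ...) {
  cat("Handwriting screening\n")
  cat(sprintf("  CER %.3f | WER %.3f | sub %d ins %d del %d | reversals %d\n",
              x$cer, x$wer, x$substitutions, x$insertions, x$deletions,
              x$reversal_count))
  cat(sprintf("  risk: %d -> %s\n  %s\n", x$risk_score, x$risk_level,
              x$message))
  invisible(x)
}
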