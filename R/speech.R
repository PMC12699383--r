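#' Word error rate between a reference and a hypothesis
#'
#' Minimal word-level edit distance (unit-cost substitutions, insertions
#' and deletions) between the reference passage and the transcript,
#' normalized by the reference word count. Both inputs are case-folded,
#' punctuation-stripped and whitespace-tokenized before alignment (pass
#' pre-tokenized character vectors to control normalization yourself).
#'
#' @param reference Reference text (string) or token vector; must be
#'   non-empty after tokenization.
#' @param hypothesis Transcript text or token vector; may be empty (WER 1).
#' @param strip_punct Passed to [tokenize_words()].
#' @return WER as a proportion `>= 0` (can exceed 1 when the hypothesis is
#'   much longer than the reference).
#' @export
#' @examples
#' compute_wer("the cat sat", "the bat sat")  # 1/3
compute_wer <- function(reference, hypothesis, strip_punct = TRUE) {
  ref <- tokenize_words(reference, strip_punct)
  hyp <- tokenize_words(hypothesis, strip_punct)
  if (length(ref) == 0L) lexi_abort("reference must contain at least one word")
  token_edit_distance(ref, hyp) / length(ref)
}

validate_word_timings <- function(timings) {
  timings <- as.data.frame(timings)
  need <- c("word", "start", "end")
  miss <- setdiff(need, names(timings))
  if (length(miss)) {
    lexi_abort(paste0("word timings need column(s): ",
                      paste(miss, collapse = ", ")),
               class = "lexi_schema_error")
  }
  if (nrow(timings) == 0L) lexi_abort("need at least one word timing")
  if (any(timings$end < timings$start)) {
    lexi_abort("each word must have end >= start")
  }
  if (is.unsorted(timings$start)) {
    lexi_abort("word timings must be ordered by start time")
  }
  timings
}

#' Inter-word pause durations
#'
#' Gaps between consecutive words (`start[i] - end[i-1]`, seconds). Only
#' strictly positive gaps are retained: contiguous words contribute nothing
#' and overlapping words (negative gaps, common in ASR output) are
#' discarded.
#'
#' @param timings Data frame (or list coercible to one) with columns
#'   `word`, `start`, `end` in seconds, ordered by start.
#' @return Numeric vector of positive pause durations (possibly empty).
#' @export
#' @examples
#' t <- data.frame(word = c("a", "b", "c"),
#'                 start = c(0, 0.8, 1.25), end = c(0.5, 1.2, 1.6))
#' compute_pauses(t)  # 0.3 0.05
compute_pauses <- function(timings) {
  timings <- validate_word_timings(timings)
  if (nrow(timings) < 2L) return(numeric(0))
  gaps <- timings$start[-1L] - timings$end[-nrow(timings)]
  gaps[gaps > 0]
}

#' Fluency features from word timings
#'
#' Computes the timing-derived fluency profile of a read-aloud attempt:
#' total time (last word end minus first word start), speech time (sum of
#' word durations), words per minute (`n / total_time * 60`), articulation
#' rate (`n / speech_time`, in words per *second* — note the unit: no x60
#' factor, measuring speed over actual speaking time with pauses excluded),
#' mean word duration, pause list, mean pause (0 when there are none) and
#' the count of pauses strictly longer than the minimum clinically relevant
#' pause (default 0.2 s).
#'
#' @param timings Word timing table (see [compute_pauses()]).
#' @param wer Word error rate for the same attempt (carried into the
#'   feature set; see [compute_wer()]).
#' @param config A [lexi_config()]; `config$speech$min_pause` sets the pause
#'   cutoff.
#' @return List of class `speech_features`.
#' @export
compute_timing_features <- function(timings, wer = NA_real_,
                                    config = lexi_config()) {
  timings <- validate_word_timings(timings)
  n <- nrow(timings)
  total_time <- timings$end[n] - timings$start[1L]
  if (total_time <= 0) {
    lexi_abort("degenerate recording: total time is zero")
  }
  durations <- timings$end - timings$start
  pauses <- compute_pauses(timings)
  structure(list(
    wer = wer,
    pauses = pauses,
    pause_count = sum(pauses > config$speech$min_pause),
    mean_word_duration = mean(durations),
    mean_pause = if (length(pauses)) mean(pauses) else 0,
    total_time = total_time,
    speech_time = sum(durations),
    wpm = n / total_time * 60,
    articulation_rate = n / sum(durations)
  ), class = "speech_features")
}

#' @export
print.speech_features <- function(x, ...) {
  cat(sprintf(
    "Speech features: WER %.3f | %.1f wpm | %d pause(s) > cutoff | total %.2f s (speech %.2f s)\n",
    x$wer, x$wpm, x$pause_count, x$total_time, x$speech_time))
  invisible(x)
}

#' Three-criterion speech fluency risk score
#'
#' One point per satisfied criterion: WER at or above the WER threshold
#' (default 0.15), pause count at or above the pause-count threshold
#' (default 5), and words-per-minute at or below the WPM threshold (default
#' 80). All three boundaries are inclusive. A total of two or more points
#' yields the label `"Likely Dyslexia"`, otherwise `"Typical"`.
#'
#' @param features A `speech_features` object (or list with `wer`,
#'   `pause_count`, `wpm`).
#' @param config A [lexi_config()] supplying the thresholds.
#' @return List of class `speech_risk`: `score` (0--3), `label`, and
#'   `triggered_criteria` (subset of `"WER"`, `"PAUSES"`, `"WPM"`).
#' @export
#' @examples
#' speech_risk_score(list(wer = 0.2, pause_count = 6, wpm = 70))
speech_risk_score <- function(features, config = lexi_config()) {
  s <- config$speech
  vals <- c(features$wer, features$pause_count, features$wpm)
  if (anyNA(vals)) lexi_abort("speech features incomplete (NA)")
  triggered <- character(0)
  if (features$wer >= s$wer_threshold) triggered <- c(triggered, "WER")
  if (features$pause_count >= s$pause_count_threshold) {
    triggered <- c(triggered, "PAUSES")
  }
  if (features$wpm <= s$wpm_threshold) triggered <- c(triggered, "WPM")
  score <- length(triggered)
  structure(list(
    score = score,
    label = if (score >= s$decision_score) "Likely Dyslexia" else "Typical",
    triggered_criteria = triggered
  ), class = "speech_risk")
}

#' @export
print.speech_risk <- function(x, ...) {
  cat(sprintf("Speech risk: score %d/3 -> %s%s\n", x$score, x$label,
              if (length(x$triggered_criteria)) {
                paste0(" [", paste(x$triggered_criteria, collapse = ", "), "]")
              } else ""))
  invisible(x)
}

#' Read word timings from JSON
#'
#' Parses the standard word-timing interchange format: a JSON array of
#' `{"word": str, "start": seconds, "end": seconds}` objects.
#'
#' @param path Path to the JSON file.
#' @return Data frame with columns `word`, `start`, `end`.
#' @export
read_word_timings <- function(path) {
  if (!file.exists(path)) {
    lexi_abort(paste0("timings file not found: ", path),
               class = "lexi_io_error")
  }
  df <- jsonlite::fromJSON(path)
  validate_word_timings(df)
}

#' Full speech screening from transcripts and timings
#'
#' Convenience wrapper: WER from reference/transcript, timing features from
#' the word timings, and the rule score, in one call.
#'
#' @param reference Reference passage text.
#' @param transcript Transcript text (e.g. ASR output).
#' @param timings Word-timing table.
#' @param config A [lexi_config()].
#' @return List with `features` (`speech_features`) and `risk`
#'   (`speech_risk`).
#' @export
speech_screen <- function(reference, transcript, timings,
                          config = lexi_config()) {
  wer <- compute_wer(reference, transcript)
  features <- compute_timing_features(timings, wer = wer, config = config)
  list(features = features, risk = speech_risk_score(features, config))
}
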