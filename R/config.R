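#' Default screening configuration
#'
#' All decision thresholds used across the screening modules, centralized in
#' one serializable object so that a single test can assert every published
#' constant. Any element can be overridden via `...` (full replacement of the
#' named top-level component).
#'
#' The defaults encode the rule-based criteria of the screening pipeline:
#'
#' * speech: a reading attempt scores one point per satisfied criterion —
#'   word error rate >= 0.15, count of pauses longer than 0.2 s >= 5, and
#'   words-per-minute <= 80 (all boundaries inclusive); two or more points
#'   yield the label "Likely Dyslexia".
#' * handwriting: per-feature severity points (one or two each) summed and
#'   banded at >= 7 (High) and 4--6 (Moderate), below 4 Low; expected
#'   sentences are capped at 500 words; reversal pairs are b/d and p/q in
#'   both directions.
#' * quiz: nine items scored 0--3 (total 0--27), banded 0--6 / 7--13 /
#'   14--20 / 21--27.
#' * reading support: passages capped at 5000 words.
#' * fusion: equal weights over present modalities, band cut points at 1/3
#'   and 2/3 of the combined score.
#'
#' @param ... Named components replacing the corresponding defaults, e.g.
#'   `fusion = list(...)`.
#' @return A list of class `"lexi_config"`.
#' @export
#' @examples
#' cfg <- lexi_config()
#' cfg$speech$wer_threshold
lexi_config <- function(...) {
  cfg <- list(
    speech = list(
      wer_threshold = 0.15,
      pause_count_threshold = 5L,
      wpm_threshold = 80,
      min_pause = 0.2,
      decision_score = 2L
    ),
    handwriting = list(
      high_cut = 7L,
      moderate_cut = 4L,
      max_expected_words = 500L,
      reversal_pairs = c(b = "d", d = "b", p = "q", q = "p"),
      severity = data.frame(
        feature = c("cer", "wer", "substitutions", "insertions",
                    "deletions", "reversals"),
        one_point = c(0.10, 0.15, 2, 2, 2, 1),
        two_point = c(0.25, 0.40, 4, 4, 4, 2),
        stringsAsFactors = FALSE
      )
    ),
    quiz = list(
      n_items = 9L,
      max_response = 3L,
      bands = data.frame(
        lo = c(0L, 7L, 14L, 21L),
        hi = c(6L, 13L, 20L, 27L),
        band = c("Unlikely dyslexia", "Mild signs",
                 "Moderate concern", "High concern"),
        message = c("No significant signs.",
                    "Monitor and support.",
                    "Consider professional screening.",
                    "Seek professional evaluation."),
        stringsAsFactors = FALSE
      )
    ),
    gaze = list(
      buffer_capacity = 100L,
      min_points = 5L,
      screen_width = 1,
      regress_threshold_frac = 0.02,
      dispersion_threshold = 50,
      min_fix_duration_ms = 40
    ),
    reading = list(
      max_words = 5000L,
      separator = "·",
      chunking = "sentence"
    ),
    fusion = list(
      weights = c(gaze = 1, speech = 1, handwriting = 1, quiz = 1),
      cuts = c(1 / 3, 2 / 3),
      bands = c("Low", "Moderate", "High")
    ),
    training = list(
      hidden = 64L,
      max_epochs = 500L,
      learn_rate = 1e-3,
      train_frac = 0.8
    )
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      lexi_abort(paste0("unknown config component(s): ",
                        paste(bad, collapse = ", ")))
    }
    for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "lexi_config")
}

# Maximum attainable handwriting risk score under a severity table.
severity_max_score <- function(severity) {
  2L * nrow(severity)
}
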