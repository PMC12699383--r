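#' Band a behavioural questionnaire total
#'
#' Maps a 0--27 total onto the four screening bands: 0--6 "Unlikely
#' dyslexia", 7--13 "Mild signs", 14--20 "Moderate concern", 21--27 "High
#' concern". The bands partition the range exactly; totals outside 0--27
#' are an error.
#'
#' @param total Integer total score.
#' @param config A [lexi_config()].
#' @return List with `band` and its advisory `message`.
#' @export
#' @examples
#' band_for_total(14)
band_for_total <- function(total, config = lexi_config()) {
  bands <- config$quiz$bands
  if (!is.numeric(total) || length(total) != 1L || is.na(total) ||
      total != round(total)) {
    lexi_abort("'total' must be a single integer")
  }
  if (total < min(bands$lo) || total > max(bands$hi)) {
    lexi_abort(sprintf("total %d outside the valid range %d-%d",
                       as.integer(total), min(bands$lo), max(bands$hi)))
  }
  r <- which(total >= bands$lo & total <= bands$hi)
  list(band = bands$band[r], message = bands$message[r])
}

#' Score the nine-item behavioural questionnaire
#'
#' Each item is answered on a 4-point Likert scale scored 0--3; the total
#' (0--27) is banded by [band_for_total()]. Exactly nine responses are
#' required; an out-of-range or missing response is rejected with an error
#' naming the offending item.
#'
#' @param responses Integer vector of length 9 with values in 0--3.
#' @param config A [lexi_config()].
#' @return List of class `quiz_result`: `total`, `band`, `message`,
#'   `per_item`.
#' @export
#' @examples
#' score_quiz(c(0, 1, 2, 3, 0, 1, 2, 3, 2))
score_quiz <- function(responses, config = lexi_config()) {
  q <- config$quiz
  if (length(responses) != q$n_items) {
    lexi_abort(sprintf("expected %d responses, got %d", q$n_items,
                       length(responses)))
  }
  responses <- suppressWarnings(as.numeric(responses))
  bad <- which(is.na(responses) | responses != round(responses) |
                 responses < 0 | responses > q$max_response)
  if (length(bad)) {
    lexi_abort(sprintf("invalid response for item %d (must be an integer 0-%d)",
                       bad[1L], q$max_response))
  }
  total <- as.integer(sum(responses))
  band <- band_for_total(total, config)
  structure(list(total = total, band = band$band, message = band$message,
                 per_item = as.integer(responses)),
            class = "quiz_result")
}

#' @export
print.quiz_result <- function(x, ...) {
  cat(sprintf("Quiz: total %d/27 -> %s (%s)\n", x$total, x$band, x$message))
  invisible(x)
}

#' Default questionnaire item bank
#'
#' Nine multiple-choice items covering commonly screened behavioural themes
#' (letter-reversal confusion, difficulty rhyming, inconsistent spelling,
#' reading avoidance, and so on), each with four frequency options scored
#' 0--3. The canonical clinical wording is not published; this bank is a
#' synthetic, clearly non-canonical stand-in shipped as editable
#' configuration (`inst/extdata/quiz_items.json`).
#'
#' @param path Optional path to an alternative item-bank JSON file.
#' @return Data frame with columns `id`, `text`, and a list column
#'   `options` (four response texts each, scored 0--3 in order).
#' @export
quiz_items <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "quiz_items.json", package = "lexiscreen")
  }
  if (!file.exists(path)) {
    lexi_abort(paste0("item bank not found: ", path), class = "lexi_io_error")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  items <- data.frame(id = unlist(raw$id), text = unlist(raw$text),
                      stringsAsFactors = FALSE)
  items$options <- lapply(raw$options, function(o) unlist(o))
  if (nrow(items) != 9L || any(lengths(items$options) != 4L)) {
    lexi_abort("item bank must contain 9 items with 4 options each",
               class = "lexi_schema_error")
  }
  items
}
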