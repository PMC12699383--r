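#' Assemble a multimodal session record
#'
#' Bundles per-modality outputs into one session. Any modality may be
#' absent (`NULL`); at least one must be present for fusion.
#'
#' @param session_id Session label; defaults to a timestamp-derived id.
#' @param timestamp ISO-8601 UTC timestamp string.
#' @param gaze List with `label` and `probability` (dyslexia probability),
#'   e.g. one row of [predict.gaze_mlp()] output, or `NULL`.
#' @param speech Output of [speech_screen()] (list with `features` and
#'   `risk`), or `NULL`.
#' @param handwriting A `handwriting_metrics` object, or `NULL`.
#' @param quiz A `quiz_result`, or `NULL`.
#' @return List of class `session_record` (without fusion; see
#'   [combine_scores()]).
#' @export
session_record <- function(session_id = NULL, timestamp = NULL,
                           gaze = NULL, speech = NULL, handwriting = NULL,
                           quiz = NULL) {
  if (is.null(timestamp)) {
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  if (is.null(session_id)) {
    session_id <- paste0("session-", gsub("[^0-9]", "", timestamp))
  }
  structure(list(
    session_id = session_id, timestamp = timestamp,
    gaze = gaze, speech = speech, handwriting = handwriting, quiz = quiz,
    combined = NULL
  ), class = "session_record")
}

# Map each present modality onto [0, 1].
modality_scores <- function(session, config) {
  max_hw <- severity_max_score(config$handwriting$severity)
  max_quiz <- max(config$quiz$bands$hi)
  scores <- c(
    gaze = if (!is.null(session$gaze)) as.numeric(session$gaze$probability)
           else NA_real_,
    speech = if (!is.null(session$speech)) session$speech$risk$score / 3
             else NA_real_,
    handwriting = if (!is.null(session$handwriting)) {
      session$handwriting$risk_score / max_hw
    } else NA_real_,
    quiz = if (!is.null(session$quiz)) session$quiz$total / max_quiz
           else NA_real_
  )
  scores[!is.na(scores)]
}

#' Fuse per-modality outputs into a combined score
#'
#' Each present modality is first mapped onto \[0, 1\] — gaze: the dyslexia
#' probability; speech: rule score / 3; handwriting: risk score / maximum
#' attainable score; quiz: total / 27 — then combined as a weighted average
#' over the *present* modalities with the weights renormalized (absent
#' modalities simply drop out, so a single present modality passes through
#' unchanged). The combined score is banded Low / Moderate / High at the
#' configurable cut points (defaults 1/3 and 2/3).
#'
#' The fusion formula is an explicit design choice of this toolkit (a
#' transparent renormalized weighted mean), not a published model; weights
#' and cut points are configurable and serialized into every report.
#'
#' @param session A [session_record()] with at least one modality present.
#' @param config A [lexi_config()]; `config$fusion` supplies weights and
#'   cut points.
#' @return The session with `combined = list(score, band, weights_used)`.
#' @export
#' @examples
#' s <- session_record(quiz = score_quiz(rep(3, 9)))
#' combine_scores(s)$combined
combine_scores <- function(session, config = lexi_config()) {
  scores <- modality_scores(session, config)
  if (length(scores) == 0L) {
    lexi_abort("no modality present: nothing to combine")
  }
  w <- config$fusion$weights[names(scores)]
  if (any(is.na(w)) || any(w < 0)) {
    lexi_abort("fusion weights must be non-negative and cover all modalities")
  }
  if (sum(w) <= 0) lexi_abort("sum of active fusion weights must be > 0")
  w <- w / sum(w)
  score <- sum(w * scores)
  cuts <- config$fusion$cuts
  bands <- config$fusion$bands
  band <- if (score < cuts[1L]) bands[1L]
          else if (score < cuts[2L]) bands[2L]
          else bands[3L]
  session$combined <- list(score = unname(score), band = band,
                           weights_used = as.list(w))
  session
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Screening session %s (%s)\n", x$session_id, x$timestamp))
  present <- c("gaze", "speech", "handwriting", "quiz")
  present <- present[!vapply(x[present], is.null, logical(1))]
  cat("  modalities:", if (length(present)) paste(present, collapse = ", ")
                       else "none", "\n")
  if (!is.null(x$combined)) {
    cat(sprintf("  combined score: %.3f -> %s\n", x$combined$score,
                x$combined$band))
  }
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

session_to_list <- function(session) {
  list(
    session_id = session$session_id,
    timestamp = session$timestamp,
    gaze = if (is.null(session$gaze)) NULL else list(
      label = as.character(session$gaze$label),
      probability = as.numeric(session$gaze$probability)),
    speech = if (is.null(session$speech)) NULL else list(
      features = unclass(session$speech$features),
      risk = unclass(session$speech$risk)),
    handwriting = if (is.null(session$handwriting)) NULL else {
      hw <- unclass(session$handwriting)
      hw$opcodes <- as.list(hw$opcodes)
      hw$points <- as.list(hw$points)
      hw
    },
    quiz = if (is.null(session$quiz)) NULL else unclass(session$quiz),
    combined = session$combined
  )
}

list_to_session <- function(x) {
  s <- session_record(
    session_id = x$session_id, timestamp = x$timestamp,
    gaze = if (is.null(x$gaze)) NULL else list(
      label = x$gaze$label, probability = x$gaze$probability),
    speech = if (is.null(x$speech)) NULL else list(
      features = structure(
        within_numeric(x$speech$features,
                       c("pauses")), class = "speech_features"),
      risk = structure(list(
        score = as.integer(x$speech$risk$score),
        label = x$speech$risk$label,
        triggered_criteria = as.character(
          unlist(x$speech$risk$triggered_criteria %||% character(0)))
      ), class = "speech_risk")),
    handwriting = if (is.null(x$handwriting)) NULL else {
      hw <- x$handwriting
      hw$opcodes <- data.frame(
        tag = as.character(unlist(hw$opcodes$tag)),
        i1 = as.integer(unlist(hw$opcodes$i1)),
        i2 = as.integer(unlist(hw$opcodes$i2)),
        j1 = as.integer(unlist(hw$opcodes$j1)),
        j2 = as.integer(unlist(hw$opcodes$j2)),
        stringsAsFactors = FALSE)
      hw$points <- stats::setNames(as.integer(unlist(hw$points)),
                                   names(hw$points))
      for (f in c("substitutions", "insertions", "deletions", "equal_chars",
                  "reversal_count", "risk_score")) {
        hw[[f]] <- as.integer(hw[[f]])
      }
      structure(hw, class = "handwriting_metrics")
    },
    quiz = if (is.null(x$quiz)) NULL else structure(list(
      total = as.integer(x$quiz$total), band = x$quiz$band,
      message = x$quiz$message,
      per_item = as.integer(unlist(x$quiz$per_item))
    ), class = "quiz_result"))
  if (!is.null(x$combined)) {
    s$combined <- list(score = as.numeric(x$combined$score),
                       band = x$combined$band,
                       weights_used = lapply(x$combined$weights_used,
                                             as.numeric))
  }
  s
}

# Coerce selected fields to plain numeric vectors after JSON parsing
# (empty JSON arrays come back as list()).
within_numeric <- function(x, vector_fields) {
  for (f in vector_fields) x[[f]] <- as.numeric(unlist(x[[f]]))
  scalar <- setdiff(names(x), vector_fields)
  for (f in scalar) {
    if (is.numeric(x[[f]]) || is.list(x[[f]])) {
      v <- unlist(x[[f]])
      if (length(v) == 0L) v <- numeric(0)
      x[[f]] <- as.numeric(v)
    }
  }
  x
}

#' Render a screening report
#'
#' Produces a machine-readable JSON document (lossless: parsing it with
#' [session_from_json()] reconstructs an equal session record) and a
#' self-contained human-readable HTML report listing every metric, the
#' handwriting character-diff, band messages and the fusion configuration
#' used.
#'
#' @param session A [session_record()] (typically after [combine_scores()]).
#' @param config The [lexi_config()] used for the session (serialized into
#'   the report for transparency).
#' @return List with elements `json` (string) and `html` (string).
#' @export
render_report <- function(session, config = lexi_config()) {
  payload <- session_to_list(session)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  list(json = as.character(json), html = render_html(session, config))
}

#' @rdname render_report
#' @param json JSON string produced by `render_report()`.
#' @export
session_from_json <- function(json) {
  list_to_session(jsonlite::fromJSON(json, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_html <- function(session, config) {
  row <- function(k, v) sprintf("<tr><th>%s</th><td>%s</td></tr>",
                                html_escape(k), html_escape(as.character(v)))
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>Screening report %s</title>",
            html_escape(session$session_id)),
    "<style>body{font-family:sans-serif;max-width:46em;margin:2em auto}",
    "table{border-collapse:collapse}th,td{border:1px solid #999;",
    "padding:0.3em 0.7em;text-align:left}del{background:#fdd}",
    "ins{background:#dfd}h2{margin-top:1.4em}</style></head><body>",
    sprintf("<h1>Dyslexia screening report</h1><p>Session <b>%s</b> at %s</p>",
            html_escape(session$session_id), html_escape(session$timestamp)))
  if (!is.null(session$combined)) {
    parts <- c(parts, "<h2>Combined</h2><table>",
               row("Combined score", sprintf("%.4f", session$combined$score)),
               row("Band", session$combined$band), "</table>")
  }
  if (!is.null(session$gaze)) {
    parts <- c(parts, "<h2>Gaze</h2><table>",
               row("Label", session$gaze$label),
               row("Dyslexia probability",
                   sprintf("%.4f", session$gaze$probability)), "</table>")
  }
  if (!is.null(session$speech)) {
    f <- session$speech$features; r <- session$speech$risk
    parts <- c(parts, "<h2>Speech</h2><table>",
               row("WER", sprintf("%.4f", f$wer)),
               row("Words per minute", sprintf("%.2f", f$wpm)),
               row("Articulation rate (words/s)",
                   sprintf("%.3f", f$articulation_rate)),
               row("Pause count (> cutoff)", f$pause_count),
               row("Mean pause (s)", sprintf("%.3f", f$mean_pause)),
               row("Rule score", sprintf("%d/3", r$score)),
               row("Label", r$label), "</table>")
  }
  if (!is.null(session$handwriting)) {
    hw <- session$handwriting
    parts <- c(parts, "<h2>Handwriting</h2><table>",
               row("Expected", hw$expected),
               row("Transcribed", hw$actual),
               row("CER", sprintf("%.4f", hw$cer)),
               row("WER", sprintf("%.4f", hw$wer)),
               row("Substitutions / insertions / deletions",
                   sprintf("%d / %d / %d", hw$substitutions, hw$insertions,
                           hw$deletions)),
               row("Letter reversals", hw$reversal_count),
               row("Risk score", hw$risk_score),
               row("Risk band", hw$risk_level),
               row("Advice", hw$message), "</table>",
               "<h3>Character diff</h3><p class='diff'>",
               diff_html(hw), "</p>")
  }
  if (!is.null(session$quiz)) {
    q <- session$quiz
    parts <- c(parts, "<h2>Behavioural quiz</h2><table>",
               row("Total", sprintf("%d/27", q$total)),
               row("Band", q$band),
               row("Advice", q$message), "</table>")
  }
  parts <- c(parts, "<h2>Fusion configuration</h2><pre>",
             html_escape(as.character(jsonlite::toJSON(
               config$fusion, auto_unbox = TRUE, digits = I(10)))),
             "</pre></body></html>")
  paste(parts, collapse = "\n")
}

# Inline diff of the handwriting alignment: deletions struck out,
# insertions highlighted.
diff_html <- function(hw) {
  out <- character(0)
  for (r in seq_len(nrow(hw$opcodes))) {
    o <- hw$opcodes[r, ]
    e_span <- if (o$i2 >= o$i1) substr(hw$expected, o$i1, o$i2) else ""
    a_span <- if (o$j2 >= o$j1) substr(hw$actual, o$j1, o$j2) else ""
    out <- c(out, switch(o$tag,
      equal = html_escape(e_span),
      replace = sprintf("<del>%s</del><ins>%s</ins>", html_escape(e_span),
                        html_escape(a_span)),
      delete = sprintf("<del>%s</del>", html_escape(e_span)),
      insert = sprintf("<ins>%s</ins>", html_escape(a_span))))
  }
  paste(out, collapse = "")
}

#' Append a session to a newline-delimited JSON log
#'
#' Each session is one compact JSON line; existing lines are never touched.
#' [read_session_log()] parses the log back, skipping (and reporting) any
#' corrupt lines rather than failing.
#'
#' @param session A [session_record()].
#' @param log Path to the log file (created if absent).
#' @return `log`, invisibly.
#' @export
append_session_log <- function(session, log) {
  line <- as.character(jsonlite::toJSON(session_to_list(session),
                                        auto_unbox = TRUE, digits = I(17),
                                        null = "null"))
  con <- file(log, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(line, con)
  invisible(log)
}

#' @rdname append_session_log
#' @return `read_session_log()` returns a list of `session_record`s with an
#'   attribute `bad_lines` giving the indices of unparseable lines.
#' @export
read_session_log <- function(log) {
  if (!file.exists(log)) {
    lexi_abort(paste0("log file not found: ", log), class = "lexi_io_error")
  }
  lines <- readLines(log, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sessions <- list()
  bad <- integer(0)
  for (i in seq_along(lines)) {
    s <- tryCatch(session_from_json(lines[i]), error = function(e) NULL)
    if (is.null(s)) bad <- c(bad, i) else sessions[[length(sessions) + 1L]] <- s
  }
  attr(sessions, "bad_lines") <- bad
  sessions
}
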