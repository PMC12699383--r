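#' Load a fixation event table from CSV
#'
#' Reads one trial's fixation events (one row per fixation) from a CSV with
#' header columns `start_ms,end_ms,duration_ms,disp_x,disp_y,aoi_line`.
#' Numeric columns are coerced; rows whose timing or displacement values do
#' not coerce are dropped. An empty result (header-only file, or all rows
#' dropped) is returned as an empty table, signalling an unusable trial, not
#' an error.
#'
#' @param path Path to a `*_fixations.csv` file.
#' @param source_id Trial/participant label; defaults to the file name with
#'   the `_fixations.csv` suffix removed.
#' @return A `fixation_table`: a data frame of fixation records with
#'   attribute `source_id`.
#' @export
load_fixation_table <- function(path, source_id = NULL) {
  if (!is.character(path) || length(path) != 1L) {
    lexi_abort("'path' must be a single file path")
  }
  if (!file.exists(path)) {
    lexi_abort(paste0("fixation file not found: ", path), class = "lexi_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("start_ms", "end_ms", "duration_ms", "disp_x", "disp_y",
                "aoi_line")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    lexi_abort(paste0("fixation CSV is missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "lexi_schema_error")
  }
  if (is.null(source_id)) {
    source_id <- sub("_fixations\\.csv$", "", basename(path))
  }
  fixation_table(df, source_id = source_id)
}

#' Construct a fixation table from a data frame
#'
#' Applies the same numeric coercion and row-dropping rules as
#' [load_fixation_table()].
#'
#' @param df Data frame with the six fixation columns.
#' @param source_id Trial/participant label.
#' @return A `fixation_table` object (possibly with zero rows).
#' @export
fixation_table <- function(df, source_id = "trial") {
  numeric_cols <- c("start_ms", "end_ms", "duration_ms", "disp_x", "disp_y")
  for (col in numeric_cols) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  keep <- rowSums(is.na(df[numeric_cols])) == 0L
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, source_id = source_id,
            class = c("fixation_table", "data.frame"))
}

#' @export
print.fixation_table <- function(x, ...) {
  cat(sprintf("Fixation table '%s': %d fixation(s)\n",
              attr(x, "source_id"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), ...)
  invisible(x)
}

#' Extract the trial-level oculomotor feature vector
#'
#' Computes the four classifier features plus one diagnostic from a fixation
#' table: fixation count (`n_fix`), mean fixation duration (`mean_fix`, ms),
#' regression ratio (`regression_ratio`, the fraction of fixations whose
#' horizontal displacement from the previous fixation is strictly negative,
#' i.e. backwards in a left-to-right script), total reading time
#' (`total_read_time = max(end_ms) - min(start_ms)`, ms), and the number of
#' distinct area-of-interest lines visited (`line_switches`, diagnostic only
#' — it is not fed to the classifier).
#'
#' @param table A `fixation_table`.
#' @return A list of class `gaze_features`, or `NULL` for an empty table
#'   (unusable trial).
#' @export
#' @examples
#' tab <- fixation_table(data.frame(
#'   start_ms = c(0, 250), end_ms = c(200, 550),
#'   duration_ms = c(200, 300), disp_x = c(5, -5),
#'   disp_y = c(0, 0), aoi_line = c(1, 1)))
#' extract_fixation_features(tab)
extract_fixation_features <- function(table) {
  if (!inherits(table, "fixation_table")) {
    lexi_abort("'table' must be a fixation_table")
  }
  if (nrow(table) == 0L) return(NULL)
  structure(list(
    n_fix = nrow(table),
    mean_fix = mean(table$duration_ms),
    regression_ratio = mean(table$disp_x < 0),
    total_read_time = max(table$end_ms) - min(table$start_ms),
    line_switches = length(unique(table$aoi_line)),
    source_id = attr(table, "source_id")
  ), class = "gaze_features")
}

#' @export
print.gaze_features <- function(x, ...) {
  cat(sprintf(
    "Gaze features [%s]: n_fix=%d mean_fix=%.1f ms regression_ratio=%.3f total_read_time=%.0f ms (lines=%d)\n",
    x$source_id %||% "?", x$n_fix, x$mean_fix, x$regression_ratio,
    x$total_read_time, x$line_switches))
  invisible(x)
}

# The four features fed to the classifier, in canonical order.
gaze_feature_order <- function() {
  c("n_fix", "mean_fix", "regression_ratio", "total_read_time")
}

#' Build a labelled feature matrix from a folder of fixation CSVs
#'
#' Scans `dir` for files matching `*_fixations.csv` (sorted by name, so row
#' order is deterministic), extracts the oculomotor feature vector from each
#' usable trial, and attaches binary labels. Labels come from a two-column
#' sidecar CSV (`source_id,label`, label in `{typical, dyslexic}`), or — as a
#' fallback when `labels` is `NULL` — from a filename-prefix convention
#' (`typical_*` / `dyslexic_*`).
#'
#' @param dir Folder containing `*_fixations.csv` files.
#' @param labels Optional path to the sidecar label CSV.
#' @return Data frame with the four feature columns, `line_switches`,
#'   `source_id`, and `label` (factor typical/dyslexic); one row per usable
#'   trial. Trials with empty tables or missing labels are dropped.
#' @export
build_feature_matrix <- function(dir, labels = NULL) {
  if (!dir.exists(dir)) {
    lexi_abort(paste0("input directory not found: ", dir),
               class = "lexi_io_error")
  }
  files <- sort(list.files(dir, pattern = "_fixations\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    lexi_abort(paste0("no data: no *_fixations.csv files in ", dir),
               class = "lexi_io_error")
  }
  label_map <- NULL
  if (!is.null(labels)) {
    if (!file.exists(labels)) {
      lexi_abort(paste0("label file not found: ", labels),
                 class = "lexi_io_error")
    }
    ldf <- utils::read.csv(labels, stringsAsFactors = FALSE)
    if (!all(c("source_id", "label") %in% names(ldf))) {
      lexi_abort("label file must have columns source_id,label",
                 class = "lexi_schema_error")
    }
    label_map <- stats::setNames(ldf$label, ldf$source_id)
  }
  rows <- list()
  for (f in files) {
    feats <- extract_fixation_features(load_fixation_table(f))
    if (is.null(feats)) next
    sid <- feats$source_id
    lab <- if (!is.null(label_map)) {
      unname(label_map[sid])
    } else if (grepl("^(typical|dyslexic)_", sid)) {
      sub("_.*$", "", sid)
    } else {
      NA_character_
    }
    if (is.na(lab)) next
    rows[[length(rows) + 1L]] <- data.frame(
      n_fix = feats$n_fix, mean_fix = feats$mean_fix,
      regression_ratio = feats$regression_ratio,
      total_read_time = feats$total_read_time,
      line_switches = feats$line_switches,
      source_id = sid, label = lab, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    lexi_abort("no data: no usable labelled trials", class = "lexi_io_error")
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = gaze_label_levels(out$label))
  rownames(out) <- NULL
  out
}

# Canonical level order: negative class first ("typical"), positive class
# ("dyslexic") last, so the positive class is consistent everywhere.
gaze_label_levels <- function(labels) {
  u <- unique(as.character(labels))
  if (setequal(u, c("typical", "dyslexic"))) c("typical", "dyslexic") else sort(u)
}

#' Write a fixation table to CSV
#'
#' Emits the standard six-column fixation CSV consumed by
#' [load_fixation_table()].
#'
#' @param table A `fixation_table`.
#' @param path Output file path (conventionally `<id>_fixations.csv`).
#' @return `path`, invisibly.
#' @export
write_fixation_csv <- function(table, path) {
  cols <- c("start_ms", "end_ms", "duration_ms", "disp_x", "disp_y",
            "aoi_line")
  utils::write.csv(as.data.frame(table)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
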