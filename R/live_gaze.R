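#' Bounded gaze-point buffer
#'
#' Holds the most recent gaze observations from a live stream. The buffer is
#' a bounded queue: once `capacity` points are held, pushing evicts the
#' oldest points first, so it always contains at most the last `capacity`
#' observations (default 100).
#'
#' @param capacity Maximum number of retained points (default 100).
#' @return An empty `gaze_buffer`.
#' @export
#' @examples
#' buf <- gaze_buffer()
#' buf <- push_gaze(buf, x = 1:150, y = rep(0, 150), t = (1:150) / 30)
#' length(buf$x)  # 100 — only the most recent points survive
gaze_buffer <- function(capacity = 100L) {
  if (capacity < 1L) lexi_abort("'capacity' must be >= 1")
  structure(list(x = numeric(0), y = numeric(0), t = numeric(0),
                 capacity = as.integer(capacity)),
            class = "gaze_buffer")
}

#' @rdname gaze_buffer
#' @param buffer A `gaze_buffer`.
#' @param x,y Gaze coordinates (screen units), equal length.
#' @param t Per-point timestamps (seconds), same length.
#' @export
push_gaze <- function(buffer, x, y, t) {
  stopifnot(inherits(buffer, "gaze_buffer"))
  if (length(x) != length(y) || length(x) != length(t)) {
    lexi_abort("x, y and t must have equal length")
  }
  buffer$x <- c(buffer$x, x)
  buffer$y <- c(buffer$y, y)
  buffer$t <- c(buffer$t, t)
  keep <- max(1L, length(buffer$x) - buffer$capacity + 1L)
  if (length(buffer$x) > buffer$capacity) {
    idx <- keep:length(buffer$x)
    buffer$x <- buffer$x[idx]
    buffer$y <- buffer$y[idx]
    buffer$t <- buffer$t[idx]
  }
  buffer
}

#' @export
print.gaze_buffer <- function(x, ...) {
  cat(sprintf("Gaze buffer: %d/%d point(s)\n", length(x$x), x$capacity))
  invisible(x)
}

#' Count fixations in a gaze stream by dispersion thresholding
#'
#' Classical dispersion-threshold (I-DT style) fixation detection: a
#' fixation is a maximal run of consecutive points whose bounding-box
#' dispersion (width + height) stays within `dispersion_threshold` and whose
#' time span is at least `min_duration_ms`.
#'
#' @param x,y Gaze coordinates (screen units).
#' @param t Timestamps in seconds, strictly non-decreasing.
#' @param dispersion_threshold Maximum bounding-box width + height for a run
#'   to count as one fixation (screen units; default 50).
#' @param min_duration_ms Minimum fixation span in milliseconds (default 40,
#'   a conventional minimum fixation duration).
#' @return Integer count of detected fixations.
#' @export
detect_fixations_dispersion <- function(x, y, t, dispersion_threshold = 50,
                                        min_duration_ms = 40) {
  n <- length(x)
  if (n < 2L) lexi_abort("need at least 2 timestamped points")
  if (length(y) != n || length(t) != n) {
    lexi_abort("x, y and t must have equal length")
  }
  if (any(diff(t) < 0)) lexi_abort("timestamps must be non-decreasing")
  min_s <- min_duration_ms / 1000
  dispersion <- function(i, j) {
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  }
  count <- 0L
  i <- 1L
  while (i <= n) {
    # smallest window starting at i that spans the minimum duration
    j <- i
    while (j < n && (t[j] - t[i]) < min_s) j <- j + 1L
    if ((t[j] - t[i]) < min_s) break      # stream exhausted
    if (dispersion(i, j) <= dispersion_threshold) {
      while (j < n && dispersion(i, j + 1L) <= dispersion_threshold) {
        j <- j + 1L
      }
      count <- count + 1L
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Extract features from a live gaze buffer
#'
#' Computes the online feature set from the buffered gaze stream: number of
#' fixations (via [detect_fixations_dispersion()]), mean gaze velocity
#' (mean consecutive-point Euclidean distance divided by the mean
#' inter-sample interval, screen units per second), count of regressive
#' (backward) saccades — consecutive-point leftward x-jumps exceeding the
#' regression threshold — and total observation duration. Fewer than
#' `min_points` buffered points is an error ("insufficient data"), mirroring
#' the live pipeline's guard.
#'
#' @param buffer A `gaze_buffer` (or list with `x`, `y`, `t`).
#' @param config A [lexi_config()]; the `gaze` component supplies
#'   `min_points`, the regression threshold (`regress_threshold_frac` of
#'   `screen_width`), and the dispersion-detector parameters.
#' @return List of class `live_gaze_features`: `n_fixations`,
#'   `mean_velocity`, `regressive_saccade_count`, `observation_duration`.
#' @export
extract_live_gaze_features <- function(buffer, config = lexi_config()) {
  g <- config$gaze
  n <- length(buffer$x)
  if (n < g$min_points) lexi_abort("insufficient data")
  dx <- diff(buffer$x)
  dy <- diff(buffer$y)
  dt <- diff(buffer$t)
  step <- sqrt(dx^2 + dy^2)
  mean_dt <- mean(dt)
  mean_velocity <- if (mean_dt > 0) mean(step) / mean_dt else 0
  regress_threshold <- g$regress_threshold_frac * g$screen_width
  regressive <- sum(dx < -regress_threshold)
  n_fix <- detect_fixations_dispersion(
    buffer$x, buffer$y, buffer$t,
    dispersion_threshold = g$dispersion_threshold,
    min_duration_ms = g$min_fix_duration_ms)
  structure(list(
    n_fixations = n_fix,
    mean_velocity = mean_velocity,
    regressive_saccade_count = as.integer(regressive),
    observation_duration = buffer$t[n] - buffer$t[1L]
  ), class = "live_gaze_features")
}

#' @export
print.live_gaze_features <- function(x, ...) {
  cat(sprintf(
    "Live gaze: %d fixation(s), mean velocity %.2f u/s, %d regressive saccade(s) over %.2f s\n",
    x$n_fixations, x$mean_velocity, x$regressive_saccade_count,
    x$observation_duration))
  invisible(x)
}
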