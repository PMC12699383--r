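test_that("the gaze buffer is a bounded queue evicting oldest first", {
  buf <- gaze_buffer()
  buf <- push_gaze(buf, x = 1:150, y = rep(0, 150), t = (1:150) / 30)
  expect_length(buf$x, 100L)
  expect_identical(buf$x, as.numeric(51:150))  # exactly the last 100
  expect_error(push_gaze(buf, 1, 2, c(1, 2)), "equal length",
               class = "lexi_validation_error")
})

test_that("live features guard against insufficient data", {
  buf <- push_gaze(gaze_buffer(), x = 1:4, y = rep(0, 4), t = (1:4) / 30)
  expect_error(extract_live_gaze_features(buf), "insufficient data",
               class = "lexi_validation_error")
})

test_that("stationary and monotone streams give zero velocity/regressions", {
  n <- 20
  still <- push_gaze(gaze_buffer(), x = rep(0.5, n), y = rep(0.5, n),
                     t = (0:(n - 1)) / 30)
  f <- extract_live_gaze_features(still)
  expect_equal(f$mean_velocity, 0)
  expect_equal(f$regressive_saccade_count, 0L)
  expect_equal(f$observation_duration, (n - 1) / 30)

  rightward <- push_gaze(gaze_buffer(), x = seq(0, 1, length.out = n),
                         y = rep(0, n), t = (0:(n - 1)) / 30)
  expect_equal(extract_live_gaze_features(rightward)$regressive_saccade_count,
               0L)

  # one large leftward jump exceeding 2% of screen width
  sweep_back <- push_gaze(gaze_buffer(),
                          x = c(seq(0, 0.5, length.out = 10),
                                seq(0.2, 0.4, length.out = 10)),
                          y = rep(0, 20), t = (0:19) / 30)
  expect_equal(extract_live_gaze_features(sweep_back)$regressive_saccade_count,
               1L)
})

test_that("dispersion-threshold detection counts spatial clusters", {
  # one stationary cluster spanning 300 ms
  t1 <- seq(0, 0.3, by = 0.02)
  expect_equal(detect_fixations_dispersion(rep(10, length(t1)),
                                           rep(10, length(t1)), t1), 1L)

  # two tight clusters separated by a large jump, each >= min duration
  n <- 10
  x <- c(rnorm(n, 100, 1), rnorm(n, 600, 1))
  y <- c(rnorm(n, 100, 1), rnorm(n, 100, 1))
  t <- (0:(2 * n - 1)) * 0.02
  expect_equal(detect_fixations_dispersion(x, y, t), 2L)

  # every dwell shorter than the minimum duration: nothing qualifies
  x3 <- seq(0, 1000, by = 200)   # large jump every sample
  t3 <- (seq_along(x3) - 1) * 0.01
  expect_equal(detect_fixations_dispersion(x3, rep(0, length(x3)), t3,
                                           dispersion_threshold = 50,
                                           min_duration_ms = 40), 0L)

  expect_error(detect_fixations_dispersion(c(1, 2, 3), c(1, 2, 3),
                                           c(0, 0.2, 0.1)),
               "non-decreasing", class = "lexi_validation_error")
  expect_error(detect_fixations_dispersion(1, 1, 0), "at least 2",
               class = "lexi_validation_error")
})

test_that("detector agrees with brute-force run enumeration on a stream", {
  # brute force: maximal qualifying runs scanned left to right
  brute <- function(x, y, t, thr, min_s) {
    n <- length(x); i <- 1L; count <- 0L
    while (i <= n) {
      best_j <- NA_integer_
      for (j in i:n) {
        disp <- (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
        if (disp > thr) break
        best_j <- j
      }
      if (!is.na(best_j) && (t[best_j] - t[i]) >= min_s) {
        count <- count + 1L
        i <- best_j + 1L
      } else {
        i <- i + 1L
      }
    }
    count
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    x <- cumsum(sample(c(0, 0, 0, 300), n, replace = TRUE)) +
      rnorm(n, 0, 2)
    y <- rnorm(n, 0, 2)
    t <- cumsum(runif(n, 0.01, 0.03))
    expect_equal(detect_fixations_dispersion(x, y, t, 50, 40),
                 brute(x, y, t, 50, 0.04))
  }
})
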