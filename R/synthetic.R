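#' Specification for a synthetic reading cohort
#'
#' Parameter sets for generating fixation tables of two cohorts — typical
#' and dyslexic readers — with controllable class separation. Defaults
#' emulate the qualitative contrasts reported for dyslexic reading (longer
#' fixations, more regressive saccades, slower overall reading) with
#' literature-plausible magnitudes; they are generator parameters, not
#' published estimates, and are recorded in generated metadata to prevent
#' misuse as ground truth.
#'
#' @param n_per_class Trials per class (>= 2).
#' @param typical,dyslexic Per-class parameter lists with elements
#'   `mean_fix` / `sd_fix` (fixation duration mean/sd, ms),
#'   `regression_prob` (probability a fixation's horizontal displacement is
#'   negative), `n_fix_range` (min/max fixation count per trial) and
#'   `gap_ms` (min/max inter-fixation gap, ms).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = 100L,
                        typical = list(mean_fix = 220, sd_fix = 30,
                                       regression_prob = 0.12,
                                       n_fix_range = c(60L, 120L),
                                       gap_ms = c(20, 120)),
                        dyslexic = list(mean_fix = 330, sd_fix = 50,
                                        regression_prob = 0.30,
                                        n_fix_range = c(90L, 170L),
                                        gap_ms = c(20, 150)),
                        seed = 1L) {
  spec <- list(n_per_class = as.integer(n_per_class),
               typical = typical, dyslexic = dyslexic,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_class < 2L) lexi_abort("n_per_class must be >= 2")
  for (cls in c("typical", "dyslexic")) {
    p <- spec[[cls]]
    need <- c("mean_fix", "sd_fix", "regression_prob", "n_fix_range",
              "gap_ms")
    miss <- setdiff(need, names(p))
    if (length(miss)) {
      lexi_abort(paste0(cls, " profile missing: ",
                        paste(miss, collapse = ", ")))
    }
    if (p$sd_fix <= 0) lexi_abort(paste0(cls, ": sd_fix must be > 0"))
    if (p$regression_prob < 0 || p$regression_prob > 1) {
      lexi_abort(paste0(cls, ": regression_prob must be in [0, 1]"))
    }
    if (length(p$n_fix_range) != 2L || any(p$n_fix_range < 1L)) {
      lexi_abort(paste0(cls, ": n_fix_range must be two counts >= 1"))
    }
  }
  invisible(TRUE)
}

#' Generate one synthetic fixation table
#'
#' Draws a trial's fixation events from the named profile of a
#' [cohort_spec()]: durations from a truncated normal, inter-fixation gaps
#' uniform within the profile range, start/end times strictly increasing,
#' horizontal displacement negative (a regression) with the profile's
#' regression probability, and an area-of-interest line label that advances
#' every few fixations. Bit-reproducible for fixed `(spec, profile, seed)`.
#'
#' @param profile `"typical"` or `"dyslexic"`.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to the spec's seed).
#' @return A `fixation_table`.
#' @export
#' @examples
#' tab <- gen_fixation_table("dyslexic", cohort_spec(), seed = 7)
#' extract_fixation_features(tab)
gen_fixation_table <- function(profile = c("typical", "dyslexic"),
                               spec = cohort_spec(), seed = spec$seed) {
  profile <- match.arg(profile)
  validate_cohort_spec(spec)
  p <- spec[[profile]]
  with_seed(seed, {
    n <- sample(p$n_fix_range[1L]:p$n_fix_range[2L], 1L)
    durations <- pmax(40, stats::rnorm(n, p$mean_fix, p$sd_fix))
    gaps <- stats::runif(n, p$gap_ms[1L], p$gap_ms[2L])
    start <- cumsum(c(0, durations[-n] + gaps[-n]))
    end <- start + durations
    regress <- stats::runif(n) < p$regression_prob
    magnitude <- abs(stats::rnorm(n, 30, 10)) + 1
    disp_x <- ifelse(regress, -magnitude, magnitude)
    disp_y <- stats::rnorm(n, 0, 5)
    aoi_line <- cumsum(c(1L, stats::runif(n - 1L) < 0.08))
    df <- data.frame(start_ms = start, end_ms = end,
                     duration_ms = durations, disp_x = disp_x,
                     disp_y = disp_y, aoi_line = as.integer(aoi_line))
    fixation_table(df, source_id = sprintf("%s_seed%d", profile,
                                           as.integer(seed)))
  })
}

#' Generate a labelled synthetic cohort feature matrix
#'
#' Generates `n_per_class` trials per class via [gen_fixation_table()]
#' (per-trial seeds derived deterministically from the spec seed), extracts
#' the oculomotor features from each, and attaches class labels — the
#' end-to-end input for [gaze_mlp()].
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with the four feature columns, `line_switches`,
#'   `source_id` and `label` (factor typical/dyslexic), balanced classes.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  validate_cohort_spec(spec)
  rows <- list()
  for (cls in c("typical", "dyslexic")) {
    for (i in seq_len(spec$n_per_class)) {
      offset <- i + (cls == "dyslexic") * spec$n_per_class
      tab <- gen_fixation_table(cls, spec,
                                seed = derive_seed(spec$seed, offset))
      f <- extract_fixation_features(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        n_fix = f$n_fix, mean_fix = f$mean_fix,
        regression_ratio = f$regression_ratio,
        total_read_time = f$total_read_time,
        line_switches = f$line_switches,
        source_id = sprintf("%s_%03d", cls, i),
        label = cls, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = c("typical", "dyslexic"))
  rownames(out) <- NULL
  out
}

#' Generate synthetic word timings
#'
#' Builds a word-timing sequence whose total span is exactly
#' `n_words / wpm_target * 60` seconds (so the recomputed words-per-minute
#' equals the target), with `pause_profile$n` pauses of
#' `pause_profile$duration` seconds inserted between words at seeded
#' positions; the remaining time is divided equally among word durations.
#'
#' @param n_words Number of words (>= 1).
#' @param wpm_target Target words-per-minute (> 0).
#' @param pause_profile List with `n` (pause count) and `duration`
#'   (seconds per pause).
#' @param seed Integer seed.
#' @return Data frame of word timings (`word`, `start`, `end`).
#' @export
#' @examples
#' t <- gen_word_timings(20, 80, list(n = 3, duration = 0.5), seed = 1)
#' compute_timing_features(t)$wpm  # 80
gen_word_timings <- function(n_words, wpm_target,
                             pause_profile = list(n = 0L, duration = 0.5),
                             seed = 1L) {
  if (n_words < 1L) lexi_abort("n_words must be >= 1")
  if (wpm_target <= 0) lexi_abort("wpm_target must be > 0")
  n_pauses <- min(pause_profile$n %||% 0L, n_words - 1L)
  total <- n_words / wpm_target * 60
  pause_dur <- if (n_pauses > 0L) pause_profile$duration else 0
  speech_time <- total - n_pauses * pause_dur
  if (speech_time <= 0) {
    lexi_abort("pause profile leaves no speaking time at this WPM target")
  }
  word_dur <- speech_time / n_words
  with_seed(seed, {
    pause_after <- if (n_pauses > 0L) {
      sort(sample(seq_len(n_words - 1L), n_pauses))
    } else integer(0)
    gap <- numeric(n_words - 1L)
    gap[pause_after] <- pause_dur
    start <- cumsum(c(0, word_dur + gap))
    data.frame(word = sprintf("w%03d", seq_len(n_words)),
               start = start, end = start + word_dur,
               stringsAsFactors = FALSE)
  })
}

#' Inject controlled errors into a text
#'
#' Corrupts a clean string the way early dyslexic writing (and imperfect
#' transcription) does, with ground truth attached: mirror-letter reversals
#' applied only to characters in b/d/p/q with probability `reversal_rate`;
#' uniform random letter substitutions, insertions and deletions at the
#' given per-character rates. Deterministic under `seed`; returns the
#' injected-error counts alongside the corrupted string so recovery can be
#' asserted downstream.
#'
#' @param text Input string.
#' @param sub_rate,ins_rate,del_rate,reversal_rate Per-character rates in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `text` (corrupted), `injected` (list of counts:
#'   `reversals`, `substitutions`, `insertions`, `deletions`).
#' @export
#' @examples
#' corrupt_text("bad pup", reversal_rate = 1, seed = 1)
corrupt_text <- function(text, sub_rate = 0, ins_rate = 0, del_rate = 0,
                         reversal_rate = 0, seed = 1L) {
  rates <- c(sub_rate, ins_rate, del_rate, reversal_rate)
  if (any(rates < 0 | rates > 1)) lexi_abort("rates must be in [0, 1]")
  pairs <- c(b = "d", d = "b", p = "q", q = "p")
  chars <- strsplit(text, "")[[1]]
  letters_pool <- letters
  with_seed(seed, {
    out <- character(0)
    inj <- c(reversals = 0L, substitutions = 0L, insertions = 0L,
             deletions = 0L)
    for (ch in chars) {
      emitted <- ch
      if (!is.na(pairs[ch]) && stats::runif(1) < reversal_rate) {
        emitted <- unname(pairs[ch])
        inj["reversals"] <- inj["reversals"] + 1L
      } else if (grepl("[a-z]", ch) && stats::runif(1) < sub_rate) {
        emitted <- sample(setdiff(letters_pool, ch), 1L)
        inj["substitutions"] <- inj["substitutions"] + 1L
      } else if (grepl("[a-z]", ch) && stats::runif(1) < del_rate) {
        emitted <- NULL
        inj["deletions"] <- inj["deletions"] + 1L
      }
      out <- c(out, emitted)
      if (stats::runif(1) < ins_rate) {
        out <- c(out, sample(letters_pool, 1L))
        inj["insertions"] <- inj["insertions"] + 1L
      }
    }
    list(text = paste(out, collapse = ""), injected = as.list(inj))
  })
}
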