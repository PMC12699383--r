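#' Split a word into syllable-like units
#'
#' Rule-based English syllabification designed for reading support:
#' vowel-nucleus grouping with classic division rules (VC-CV between two
#' consonants, V-CV before a single consonant), protection of common
#' digraphs (ch, sh, th, ph, wh, ck, qu, gh), silent final e, the
#' consonant-le ending, and the -ing suffix. The segmentation approximates
#' phonological syllables the way hyphenation dictionaries do; its hard
#' guarantee is the reconstruction invariant: concatenating the returned
#' segments always reproduces the input word exactly.
#'
#' @param word Non-empty string without internal whitespace.
#' @param lang Language code; currently `"en"`, `"en_US"`, `"en_GB"`.
#' @return Character vector of syllables whose concatenation equals `word`.
#' @export
#' @examples
#' syllabify_word("reading")  # "read" "ing"
#' syllabify_word("window")   # "win" "dow"
syllabify_word <- function(word, lang = "en") {
  supported <- c("en", "en_us", "en_gb")
  if (!tolower(lang) %in% supported) {
    lexi_abort(paste0("unsupported language code '", lang,
                      "'; supported: ", paste(supported, collapse = ", ")))
  }
  if (!is.character(word) || length(word) != 1L || !nzchar(word)) {
    lexi_abort("'word' must be a single non-empty string")
  }
  if (grepl("[[:space:]]", word)) {
    lexi_abort("'word' must not contain whitespace")
  }
  syllable_splits(word)
}

digraphs <- c("ch", "sh", "th", "ph", "wh", "ck", "qu", "gh")

# Returns the syllable segments of one word (original casing preserved).
syllable_splits <- function(word) {
  low <- tolower(word)
  chars <- strsplit(low, "")[[1]]
  n <- length(chars)
  if (n <= 3L || !grepl("^[a-z]+$", low)) return(word)

  # -ing suffix: syllabify the stem, append "ing" (so "reading" -> read|ing)
  if (endsWith(low, "ing") && n > 4L) {
    stem <- substr(word, 1L, n - 3L)
    if (grepl("[aeiouy]", tolower(stem))) {
      return(c(syllable_splits(stem), substr(word, n - 2L, n)))
    }
  }

  is_vowel <- chars %in% c("a", "e", "i", "o", "u") |
    (chars == "y" & seq_len(n) > 1L)

  # nucleus groups: maximal runs of vowels
  r <- rle(is_vowel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  groups <- cbind(starts[r$values], ends[r$values])
  if (is.null(nrow(groups)) || nrow(groups) <= 1L) return(word)

  # consonant-le ending: final syllable is C + "le"
  le_tail <- NULL
  if (endsWith(low, "le") && n >= 4L && !is_vowel[n - 2L]) {
    le_tail <- substr(word, n - 2L, n)
    return(c(syllable_splits(substr(word, 1L, n - 3L)), le_tail))
  }

  # silent final e: a lone final "e" after a consonant is not a nucleus
  g_last <- nrow(groups)
  if (groups[g_last, 1L] == n && chars[n] == "e" && !is_vowel[n - 1L]) {
    groups <- groups[-g_last, , drop = FALSE]
    if (nrow(groups) <= 1L) return(word)
  }

  # split between consecutive nuclei
  cut_points <- integer(0)            # split AFTER these positions
  for (g in seq_len(nrow(groups) - 1L)) {
    c_start <- groups[g, 2L] + 1L     # consonant span between nuclei
    c_end <- groups[g + 1L, 1L] - 1L
    k <- c_end - c_start + 1L
    if (k <= 0L) next
    cut <- if (k == 1L) {
      c_start - 1L                    # V|CV
    } else {
      first_two <- paste0(chars[c_start], chars[c_start + 1L])
      if (first_two %in% digraphs) c_start - 1L   # V|CCV, keep digraph
      else c_start                    # VC|CV
    }
    cut_points <- c(cut_points, cut)
  }
  if (length(cut_points) == 0L) return(word)
  bounds <- c(0L, cut_points, n)
  vapply(seq_len(length(bounds) - 1L), function(i) {
    substr(word, bounds[i] + 1L, bounds[i + 1L])
  }, character(1))
}

#' Syllabify a passage for dyslexia-friendly display
#'
#' Tokenizes a passage preserving all punctuation and whitespace verbatim,
#' syllabifies each alphabetic token, and produces (1) the display text
#' with syllables joined by a separator and (2) line chunks for
#' line-by-line highlighting. Passages are capped at 5000 words.
#'
#' @param text Passage text.
#' @param lang Language code (see [syllabify_word()]).
#' @param separator Display delimiter between syllables (default `"·"`).
#' @param chunking `"sentence"` (default) chunks at sentence boundaries;
#'   `"width"` wraps at `width` characters.
#' @param width Line width for `chunking = "width"`.
#' @param config A [lexi_config()] (supplies the word cap).
#' @return List of class `syllabified_text`: `text` (the input), `words`
#'   (data frame of alphabetic tokens with a `syllables` list column),
#'   `separator`, `display` (syllabified passage), `line_chunks`
#'   (character vector), `n_words`.
#' @export
#' @examples
#' syllabify_passage("Reading is fun. Keep reading!")
syllabify_passage <- function(text, lang = "en", separator = NULL,
                              chunking = NULL, width = 60L,
                              config = lexi_config()) {
  if (!is.character(text) || length(text) != 1L) {
    lexi_abort("'text' must be a single string")
  }
  separator <- separator %||% config$reading$separator
  chunking <- chunking %||% config$reading$chunking
  tokens <- regmatches(text,
                       gregexpr("[[:alpha:]]+|[^[:alpha:]]+", text))[[1]]
  is_word <- grepl("^[[:alpha:]]+$", tokens)
  n_words <- sum(is_word)
  if (n_words > config$reading$max_words) {
    lexi_abort(sprintf("passage exceeds %d words (%d)",
                       config$reading$max_words, n_words))
  }
  syl <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    syl[[i]] <- if (is_word[i]) syllabify_word(tokens[i], lang)
                else tokens[i]
  }
  display_tokens <- vapply(seq_along(tokens), function(i) {
    if (is_word[i]) paste(syl[[i]], collapse = separator) else tokens[i]
  }, character(1))
  display <- paste(display_tokens, collapse = "")
  words <- data.frame(word = tokens[is_word], stringsAsFactors = FALSE)
  words$syllables <- syl[is_word]
  chunks <- if (identical(chunking, "sentence")) {
    split_sentences(text)
  } else {
    strwrap(text, width = width)
  }
  structure(list(text = text, words = words, separator = separator,
                 display = display, line_chunks = chunks,
                 n_words = n_words),
            class = "syllabified_text")
}

split_sentences <- function(text) {
  out <- strsplit(text, "(?<=[.!?])[[:space:]]+", perl = TRUE)[[1]]
  out[nzchar(trimws(out))]
}

#' @export
print.syllabified_text <- function(x, ...) {
  cat(sprintf("Syllabified passage: %d word(s), %d line chunk(s)\n",
              x$n_words, length(x$line_chunks)))
  cat(substr(x$display, 1L, 200L), "\n")
  invisible(x)
}
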