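# Independent oracles and small fixture builders, kept deliberately separate
# from the implementation paths they check.

# Brute-force minimal edit distance by plain recursion with memoisation:
# min over delete / insert / substitute at every position.
oracle_edit_distance <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1L)
    if (j > length(b)) return(length(a) - i + 1L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- min(
      rec(i + 1L, j) + 1L,
      rec(i, j + 1L) + 1L,
      rec(i + 1L, j + 1L) + (a[i] != b[j])
    )
    memo[[key]] <- res
    res
  }
  rec(1L, 1L)
}

# All token sequences of length 0..max_len over `alphabet`, as a list of
# character vectors.
enumerate_sequences <- function(alphabet, max_len) {
  out <- list(character(0))
  frontier <- list(character(0))
  for (l in seq_len(max_len)) {
    nxt <- list()
    for (s in frontier) {
      for (tok in alphabet) nxt[[length(nxt) + 1L]] <- c(s, tok)
    }
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# adist-based minimal distance between token sequences: map each distinct
# token to one character and use the C Levenshtein implementation.
adist_token_distance <- function(a, b, alphabet) {
  code <- stats::setNames(letters[seq_along(alphabet)], alphabet)
  sa <- paste(code[a], collapse = "")
  sb <- paste(code[b], collapse = "")
  as.integer(utils::adist(sa, sb))
}

# Write a fixation CSV fixture and return its path.
write_fix_fixture <- function(dir, name, df) {
  path <- file.path(dir, paste0(name, "_fixations.csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

basic_fix_df <- function() {
  data.frame(start_ms = c(0, 250), end_ms = c(200, 550),
             duration_ms = c(200, 300), disp_x = c(5, -5),
             disp_y = c(0, 0), aoi_line = c(1, 1))
}

random_string <- function(n, alphabet = c(letters[1:4], " ")) {
  chars <- sample(alphabet, n, replace = TRUE)
  # guarantee at least one letter so word-level rates stay defined
  if (n > 0L && !any(grepl("[[:alpha:]]", chars))) {
    chars[1L] <- sample(grep("[[:alpha:]]", alphabet, value = TRUE), 1L)
  }
  paste(chars, collapse = "")
}
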