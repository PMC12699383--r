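#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd predict coef
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions: validation / schema / io errors are user-input problems
# (CLI exit code 2); anything else is internal (exit code 1).
lexi_abort <- function(msg, class = "lexi_validation_error") {
  stop(structure(
    class = c(class, "lexi_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_lexi_user_error <- function(cond) {
  inherits(cond, c("lexi_validation_error", "lexi_schema_error", "lexi_io_error"))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards: generators are pure functions of (args, seed) and never
# leak into or depend on global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    lexi_abort("'seed' must be a single non-missing number")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a stream seed from a base seed; kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + as.double(offset)) %% 2147483647)
}

#' Normalize free text into word tokens
#'
#' Lowercases, strips punctuation, and splits on whitespace. This is the
#' tokenizer shared by the speech and handwriting word-error-rate routines so
#' the two modalities count word errors identically.
#'
#' @param text Character scalar (or an already-tokenized character vector,
#'   returned lowercased).
#' @param strip_punct Drop punctuation characters before splitting
#'   (default `TRUE`).
#' @return Character vector of tokens; zero-length for empty input.
#' @export
#' @examples
#' tokenize_words("The quick, brown fox!")
tokenize_words <- function(text, strip_punct = TRUE) {
  if (length(text) == 0L) return(character(0))
  if (length(text) > 1L) return(tolower(text))
  x <- tolower(text)
  if (strip_punct) x <- gsub("[[:punct:]]", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Minimal edit distance (unit-cost substitution/insertion/deletion) between
# two token sequences; classic two-row Levenshtein DP.
token_edit_distance <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    ai <- a[i]
    for (j in seq_len(m)) {
      cost <- if (ai == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j] + cost, prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1L]
}
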