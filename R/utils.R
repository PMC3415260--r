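# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Strip leading/trailing punctuation from a token, keeping internal characters
# ("Smith." -> "Smith", "(Toronto)" -> "Toronto", "O'Brien," -> "O'Brien").
token_core <- function(x) {
  gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", x)
}

# A token counts as capitalized when its punctuation-trimmed core starts with
# an uppercase letter and contains only word-internal characters.
is_capitalized <- function(core) {
  nzchar(core) & grepl("^[[:upper:]][[:alpha:]'.-]*$", core)
}

# Case-fold and collapse runs of whitespace; used for titles and keyword terms.
squash_ws <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}

# Locale-independent sort.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Empty match table shared by the PII and health detectors. Spans are 0-based
# half-open token offsets.
empty_matches <- function(extra = character()) {
  cols <- c("category", "subcategory", "start", "end", "text")
  out <- data.frame(
    category = character(), subcategory = character(),
    start = integer(), end = integer(), text = character(),
    stringsAsFactors = FALSE
  )
  out
}
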