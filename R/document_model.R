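#' Load a file of unknown type
#'
#' Reads a file as raw bytes and records the metadata used by the shallow
#' triage stages: size in whole kilobytes (rounded up), the lowercased
#' extension, and the title (the file name without directory or extension).
#'
#' @param path Path to an existing, readable file.
#' @return An object of class `raw_file` with fields `path`, `size_kb`,
#'   `raw_bytes`, `extension`, and `title`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("hello", f)
#' load_file(f)$extension
#' @export
load_file <- function(path) {
  if (length(path) != 1L || !file.exists(path) || dir.exists(path)) {
    stop("cannot read file: ", path)
  }
  n <- file.info(path)$size
  raw <- readBin(path, what = "raw", n = n)
  title <- tools::file_path_sans_ext(basename(path))
  if (!nzchar(title)) title <- basename(path)
  structure(
    list(
      path = path,
      size_kb = as.integer(ceiling(length(raw) / 1024)),
      raw_bytes = raw,
      extension = tolower(tools::file_ext(path)),
      title = title
    ),
    class = "raw_file"
  )
}

#' @export
print.raw_file <- function(x, ...) {
  cat(sprintf(
    "<raw_file> %s (%d KB, .%s)\n", x$title, x$size_kb,
    if (nzchar(x$extension)) x$extension else "?"
  ))
  invisible(x)
}

# ---- byte decoding -----------------------------------------------------------

# Decode raw bytes to a UTF-8 string: NUL bytes are dropped, valid UTF-8 is
# kept as-is, anything else falls back to Latin-1 so that no byte sequence is
# undecodable. Files arrive "as is" with no normalization.
decode_bytes <- function(raw) {
  raw <- raw[raw != as.raw(0L)]
  if (length(raw) == 0L) return("")
  s <- rawToChar(raw)
  if (isTRUE(validUTF8(s))) {
    Encoding(s) <- "UTF-8"
    s
  } else {
    iconv(s, from = "latin1", to = "UTF-8")
  }
}

# Proportion of characters that are printable text; used to classify decoded
# output as corrupted.
printable_ratio <- function(text) {
  if (!nchar(text)) return(0)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  mean(grepl("[[:print:][:space:]]", chars))
}

# ---- extractors --------------------------------------------------------------

extract_plain <- function(raw) {
  decode_bytes(raw)
}

extract_markup <- function(raw) {
  text <- decode_bytes(raw)
  doc <- xml2::read_html(text)
  for (node in xml2::xml_find_all(doc, "//script | //style")) {
    xml2::xml_remove(node)
  }
  xml2::xml_text(doc)
}

# Minimal RTF-to-text conversion: resolves \'hh escapes, turns paragraph
# marks into newlines, skips destination groups (font tables etc.), and drops
# remaining control words and braces.
extract_rtf <- function(raw) {
  text <- decode_bytes(raw)
  if (!grepl("^\\s*\\{\\\\rtf", text)) stop("not an RTF document")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  destinations <- c(
    "fonttbl", "colortbl", "stylesheet", "info", "pict", "header", "footer",
    "generator", "themedata"
  )
  i <- 1L
  skip_depth <- 0L   # brace depth at which a skipped destination group started
  depth <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "{") {
      depth <- depth + 1L
      i <- i + 1L
    } else if (ch == "}") {
      if (skip_depth > 0L && depth == skip_depth) skip_depth <- 0L
      depth <- depth - 1L
      i <- i + 1L
    } else if (ch == "\\") {
      nxt <- if (i < n) chars[i + 1L] else ""
      if (nxt %in% c("\\", "{", "}")) {
        if (skip_depth == 0L) out <- c(out, nxt)
        i <- i + 2L
      } else if (nxt == "'") {
        hex <- paste0(chars[i + 2L], chars[i + 3L])
        if (skip_depth == 0L) {
          out <- c(out, iconv(rawToChar(as.raw(strtoi(hex, 16L))), "latin1", "UTF-8"))
        }
        i <- i + 4L
      } else if (nxt == "*") {
        if (skip_depth == 0L) skip_depth <- depth
        i <- i + 2L
      } else {
        j <- i + 1L
        while (j <= n && grepl("[a-zA-Z]", chars[j])) j <- j + 1L
        word <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
        while (j <= n && grepl("[-0-9]", chars[j])) j <- j + 1L
        if (j <= n && chars[j] == " ") j <- j + 1L
        if (word %in% destinations) {
          if (skip_depth == 0L) skip_depth <- depth
        } else if (skip_depth == 0L && word %in% c("par", "line", "sect", "page")) {
          out <- c(out, "\n")
        } else if (skip_depth == 0L && word == "tab") {
          out <- c(out, " ")
        }
        i <- j
      }
    } else {
      if (skip_depth == 0L && !ch %in% c("\r", "\n")) out <- c(out, ch)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Built-in text extractor registry
#'
#' Maps file extensions to extraction functions taking a raw vector and
#' returning decoded plain text. Built-ins cover plain text (`txt`, `text`,
#' `log`, `csv`), HTML/XML, and RTF. Additional formats (for example PDF or
#' word-processor files) can be supported by registering a function under the
#' corresponding extension; extensions without an entry are treated as
#' non-text and discarded.
#'
#' @return Named list of extractor functions.
#' @export
default_extractors <- function() {
  list(
    txt = extract_plain,
    text = extract_plain,
    log = extract_plain,
    csv = extract_plain,
    html = extract_markup,
    htm = extract_markup,
    xml = extract_markup,
    rtf = extract_rtf
  )
}

# ---- segmentation ------------------------------------------------------------

#' Segment text into tokens and sentences
#'
#' Tokens are maximal runs of non-whitespace characters. Sentences are split
#' after terminal punctuation (`.`, `!`, `?`) followed by whitespace; text
#' without terminal punctuation forms a single sentence. Empty text yields
#' empty token and sentence lists.
#'
#' @param text A decoded character scalar.
#' @return A list with components `tokens` and `sentences`.
#' @examples
#' segment("A b. C d!")$sentences
#' @export
segment <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(list(tokens = character(0), sentences = character(0)))
  }
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  sentences <- strsplit(trimws(text), "(?<=[.!?])[[:space:]]+", perl = TRUE)[[1]]
  sentences <- gsub("[[:space:]]+", " ", trimws(sentences))
  sentences <- sentences[nzchar(sentences)]
  list(tokens = tokens, sentences = sentences)
}

# ---- extraction entry point --------------------------------------------------

# Terminal disposition for one file.
disposition <- function(stage, outcome, reason) {
  structure(list(stage = stage, outcome = outcome, reason = reason),
            class = "disposition")
}

is_disposition <- function(x) inherits(x, "disposition")

#' Extract plain text from a loaded file
#'
#' Applies the extractor registered for the file's extension. On success
#' returns an `extracted_doc` carrying the decoded, markup-free text together
#' with its whitespace tokens and sentences. Files with no registered
#' extractor (non-text formats such as media files), extractor failures of
#' any kind, and decoded output with under 1% printable characters
#' (corrupted files) all yield a discard disposition at stage
#' `"text_extractor"`; extraction never raises for any input bytes.
#'
#' @param file A `raw_file` from [load_file()].
#' @param registry Named list mapping extensions to extractor functions;
#'   defaults to [default_extractors()].
#' @return An `extracted_doc` (fields `source`, `text`, `tokens`,
#'   `sentences`) or a discard `disposition`.
#' @export
extract_text <- function(file, registry = default_extractors()) {
  stopifnot(inherits(file, "raw_file"))
  fun <- registry[[file$extension]]
  if (is.null(fun)) {
    return(disposition(
      "text_extractor", "discarded",
      sprintf("no text extractor for extension '%s'", file$extension)
    ))
  }
  text <- tryCatch(fun(file$raw_bytes), error = function(e) e)
  if (inherits(text, "error")) {
    return(disposition(
      "text_extractor", "discarded",
      sprintf("extraction failed: %s", conditionMessage(text))
    ))
  }
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    return(disposition("text_extractor", "discarded", "extractor returned no text"))
  }
  if (nzchar(text) && printable_ratio(text) < 0.01) {
    return(disposition("text_extractor", "discarded", "corrupted: under 1% printable"))
  }
  seg <- segment(text)
  structure(
    list(source = file, text = text, tokens = seg$tokens, sentences = seg$sentences),
    class = "extracted_doc"
  )
}

# Build an extracted_doc directly from text, for detector-level use where no
# file is involved (tests, single-document screening).
#' Wrap plain text as an extracted document
#'
#' Convenience constructor used to run the PII and health detectors on text
#' that did not come from a file on disk.
#'
#' @param text Character scalar.
#' @param title Optional title; defaults to `"<text>"`.
#' @return An `extracted_doc`.
#' @export
as_extracted_doc <- function(text, title = "<text>") {
  seg <- segment(text)
  structure(
    list(source = list(title = title, path = NA_character_),
         text = text, tokens = seg$tokens, sentences = seg$sentences),
    class = "extracted_doc"
  )
}

#' @export
print.extracted_doc <- function(x, ...) {
  cat(sprintf("<extracted_doc> %d tokens, %d sentences\n",
              length(x$tokens), length(x$sentences)))
  invisible(x)
}
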