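# Shallow triage stages: duplicate removal, published-title lookup, and
# publishable-content keyword triage. (Language identification lives in
# language.R.)

# ---- duplicate removal -------------------------------------------------------

# Hex rendering of the first / last `n` raw bytes; used as content
# fingerprints for duplicate grouping. This stage runs before text
# extraction, so fingerprints are taken on raw bytes rather than sentences.
byte_fingerprint <- function(raw, n = 256L, from_end = FALSE) {
  if (length(raw) == 0L) return("")
  piece <- if (from_end) utils::tail(raw, n) else utils::head(raw, n)
  paste(as.character(piece), collapse = "")
}

#' Remove duplicate files
#'
#' Two files are duplicates when all four parameters agree: size in
#' kilobytes, normalized title (case-folded, whitespace collapsed), and the
#' fingerprints of their first and last 256 bytes. Within each duplicate
#' group the file with the lexicographically smallest path is retained and
#' the rest are discarded at stage `"duplicate_removal"`.
#'
#' @param files List of `raw_file` objects.
#' @return List with `retained` (a list of `raw_file`) and `dispositions`
#'   (named by path, discard dispositions for the removed copies).
#' @export
remove_duplicates <- function(files) {
  if (length(files) == 0L) return(list(retained = list(), dispositions = list()))
  paths <- vapply(files, `[[`, "", "path")
  keys <- vapply(files, function(f) {
    paste(
      f$size_kb,
      squash_ws(f$title),
      byte_fingerprint(f$raw_bytes),
      byte_fingerprint(f$raw_bytes, from_end = TRUE),
      sep = "\r"
    )
  }, character(1))
  ord <- order(paths, method = "radix")
  retained <- list()
  dispositions <- list()
  seen <- new.env(parent = emptyenv())
  for (i in ord) {
    key <- keys[[i]]
    first <- get0(key, envir = seen)
    if (is.null(first)) {
      assign(key, paths[[i]], envir = seen)
      retained[[length(retained) + 1L]] <- files[[i]]
    } else {
      dispositions[[paths[[i]]]] <- disposition(
        "duplicate_removal", "discarded",
        sprintf("duplicate of %s", first)
      )
    }
  }
  list(retained = retained, dispositions = dispositions)
}

# ---- published-title lookup --------------------------------------------------

#' Published-title database
#'
#' A set of known publication titles (books, music, films). Files whose
#' normalized title exactly matches a database entry are assumed to carry
#' already-public content and are discarded -- unless the title contains one
#' of the exemption words (terms like "discharge" or "lab" that flag
#' potentially personal documents), in which case the file is kept for
#' deeper analysis.
#'
#' @param titles Character vector of titles.
#' @param exemption_words Lowercase words that exempt a title from discard.
#' @return A `title_database`.
#' @export
title_database <- function(titles,
                           exemption_words = c("notification", "affidavit",
                                               "justice", "discharge", "lab")) {
  structure(
    list(titles = unique(squash_ws(titles)),
         exemption_words = tolower(exemption_words)),
    class = "title_database"
  )
}

#' @param path Plain-text file, one title per line, UTF-8.
#' @rdname title_database
#' @export
read_title_database <- function(path, exemption_words = c("notification",
                                                          "affidavit", "justice",
                                                          "discharge", "lab")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  title_database(lines[nzchar(trimws(lines))], exemption_words)
}

#' Filter a file by published-title lookup
#'
#' @param file A `raw_file`.
#' @param db A `title_database`.
#' @return `TRUE` to keep the file, `FALSE` to discard it (exact title match
#'   with no exemption word).
#' @export
filter_published_title <- function(file, db) {
  stopifnot(inherits(db, "title_database"))
  norm <- squash_ws(file$title)
  if (!norm %in% db$titles) return(TRUE)
  words <- strsplit(norm, "[^[:alnum:]]+")[[1]]
  any(words %in% db$exemption_words)
}

# ---- publishable-content keywords --------------------------------------------

#' Read a publishable-content keyword set
#'
#' One `category<TAB>term` per line, UTF-8. Categories cover indicators of
#' published or otherwise non-personal material: Books, Education, Retail,
#' Periodical, Fictional, Politics.
#'
#' @param path Keyword file path.
#' @return Data frame with columns `category` and `term`.
#' @export
read_content_keywords <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("category", "term"),
                          stringsAsFactors = FALSE, quote = "", comment.char = "#",
                          fileEncoding = "UTF-8")
  df$term <- squash_ws(df$term)
  df
}

# Simple singular/plural variants of the final word of a term.
term_variants <- function(term) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  last <- words[length(words)]
  vars <- c(last, paste0(last, "s"), paste0(last, "es"))
  if (grepl("y$", last)) vars <- c(vars, sub("y$", "ies", last))
  if (grepl("ies$", last)) vars <- c(vars, sub("ies$", "y", last))
  if (grepl("s$", last)) vars <- c(vars, sub("s$", "", last))
  vapply(unique(vars), function(v) {
    paste(c(words[-length(words)], v), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Detect publishable-content keywords in a document prefix
#'
#' Case-insensitive whole-word search for each keyword term (and its simple
#' plural/singular variants) within the first `prefix_len` whitespace tokens
#' of the document. Terms that appear in the front matter of published and
#' educational material make the file an unlikely PHI leak, so any hit
#' discards it.
#'
#' @param doc An `extracted_doc`.
#' @param keywords Data frame from [read_content_keywords()].
#' @param prefix_len Number of leading tokens searched (default 200).
#' @return `NULL` to keep, or a list with `category`, `term`, and `span`
#'   (0-based half-open token offsets) for the first hit.
#' @export
detect_publishable_content <- function(doc, keywords, prefix_len = 200L) {
  toks <- utils::head(doc$tokens, prefix_len)
  norm <- tolower(token_core(toks))
  if (length(norm) == 0L) return(NULL)
  expanded <- do.call(rbind, lapply(seq_len(nrow(keywords)), function(i) {
    data.frame(category = keywords$category[i], base = keywords$term[i],
               variant = term_variants(keywords$term[i]),
               stringsAsFactors = FALSE)
  }))
  expanded$nwords <- lengths(strsplit(expanded$variant, " ", fixed = TRUE))
  max_w <- max(expanded$nwords)
  for (i in seq_along(norm)) {
    for (w in seq(min(max_w, length(norm) - i + 1L), 1L)) {
      window <- paste(norm[i:(i + w - 1L)], collapse = " ")
      hit <- which(expanded$variant == window & expanded$nwords == w)
      if (length(hit)) {
        hit <- hit[1]
        return(list(category = expanded$category[hit], term = expanded$base[hit],
                    span = c(i - 1L, i - 1L + w)))
      }
    }
  }
  NULL
}
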