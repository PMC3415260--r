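# Patient-oriented health information: lexicon construction, term matching,
# and the final PHI decision.

#' Read the packaged stop-word list
#'
#' A fixed list of common English function words removed from multiword
#' lexicon terms and from the document stream before health-term matching.
#'
#' @param path Plain-text file, one word per line.
#' @return Character vector of lowercase stop words.
#' @export
read_stop_words <- function(path = system.file("extdata", "stopwords.txt",
                                               package = "phitriage")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tolower(trimws(x[nzchar(trimws(x))]))
}

# Normalize one string the way lexicon terms are stored: lowercase,
# punctuation and digits replaced by spaces, stop words dropped. Returns a
# character vector of remaining words (possibly empty).
normalize_health_words <- function(x, stop_words) {
  x <- tolower(x)
  x <- gsub("[^a-z]+", " ", x)
  words <- strsplit(trimws(x), " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  words[!words %in% stop_words]
}

#' Build the health-term lexicon
#'
#' Raw term lists (packaged stand-ins for disease classifications, adverse
#' event dictionaries, drug databases, and manual dictionary additions such
#' as acronyms and provider specialties) are preprocessed into a matching
#' lexicon: terms are lowercased, punctuation and digits removed, stop words
#' eliminated, empty results dropped; the first category wins for duplicate
#' terms. Categories for animal diseases and animal drugs are excluded from
#' the packaged sources.
#'
#' @param sources Either a data frame with columns `term` and `category`, or
#'   a named list of character vectors (names are the categories, one of
#'   disease, symptom, procedure, drug_generic, drug_trade, acronym,
#'   specialty, condition).
#' @param stop_words Stop-word vector (default: packaged list).
#' @return A `health_lexicon`: named character vector mapping normalized
#'   term to category, plus the stop-word list used.
#' @export
build_health_lexicon <- function(sources, stop_words = read_stop_words()) {
  if (is.data.frame(sources)) {
    terms <- sources$term
    cats <- sources$category
  } else if (is.list(sources) && length(sources)) {
    terms <- unlist(sources, use.names = FALSE)
    cats <- rep(names(sources), lengths(sources))
  } else {
    stop("no lexicon sources")
  }
  if (length(terms) == 0L) stop("no lexicon sources")
  norm <- vapply(terms, function(t) {
    paste(normalize_health_words(t, stop_words), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  keep <- nzchar(norm)
  norm <- norm[keep]
  cats <- cats[keep]
  first <- !duplicated(norm)
  structure(
    list(terms = stats::setNames(cats[first], norm[first]),
         stop_words = stop_words),
    class = "health_lexicon"
  )
}

#' Read packaged health-term sources
#'
#' One `term<TAB>category` per line, UTF-8.
#'
#' @param path Source file; defaults to the packaged stand-in list.
#' @return Data frame with columns `term` and `category`.
#' @export
read_health_sources <- function(path = system.file("extdata", "health_terms.tsv",
                                                   package = "phitriage")) {
  utils::read.delim(path, header = FALSE, col.names = c("term", "category"),
                    stringsAsFactors = FALSE, quote = "", comment.char = "#",
                    fileEncoding = "UTF-8")
}

#' @export
print.health_lexicon <- function(x, ...) {
  cat(sprintf("<health_lexicon> %d terms in %d categories\n",
              length(x$terms), length(unique(x$terms))))
  invisible(x)
}

#' Detect health terms in a document
#'
#' The document's tokens are normalized exactly as the lexicon terms were
#' (lowercase, punctuation/digits removed, stop words dropped), then scanned
#' longest-match-first for whole-word lexicon hits; shorter matches
#' overlapped by a longer one are suppressed ("chest pain" beats "pain").
#'
#' @param doc An `extracted_doc`.
#' @param lexicon A `health_lexicon`.
#' @return Data frame with columns `term` (normalized lexicon term),
#'   `category`, and 0-based half-open `start`/`end` offsets into the
#'   original token stream.
#' @export
detect_health_terms <- function(doc, lexicon) {
  empty <- data.frame(term = character(), category = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (length(doc$tokens) == 0L || length(lexicon$terms) == 0L) return(empty)
  # normalized word stream with a map back to original token indices
  words <- character(0)
  orig <- integer(0)
  for (i in seq_along(doc$tokens)) {
    w <- normalize_health_words(doc$tokens[i], lexicon$stop_words)
    words <- c(words, w)
    orig <- c(orig, rep(i, length(w)))
  }
  if (length(words) == 0L) return(empty)
  term_names <- names(lexicon$terms)
  max_w <- max(lengths(strsplit(term_names, " ", fixed = TRUE)))
  rows <- list()
  i <- 1L
  n <- length(words)
  while (i <= n) {
    matched <- FALSE
    for (w in seq(min(max_w, n - i + 1L), 1L)) {
      key <- paste(words[i:(i + w - 1L)], collapse = " ")
      cat <- unname(lexicon$terms[key])
      if (!is.na(cat)) {
        rows[[length(rows) + 1L]] <- data.frame(
          term = key, category = cat,
          start = orig[i] - 1L, end = orig[i + w - 1L],
          stringsAsFactors = FALSE
        )
        i <- i + w
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Final PHI decision
#'
#' A document is flagged as PHI when it both carries PII (per
#' [evaluate_pii_rule()]) and mentions at least `min_health_terms` distinct
#' health-lexicon terms: identity plus health specifics. "John Smith caught
#' a cold" style statements with identifiers but no lexicon hit are
#' rejected, as are documents with health terms but no PII.
#'
#' @param pii A `pii_result`.
#' @param health Data frame from [detect_health_terms()].
#' @param min_health_terms Minimum distinct health terms (default 1; the
#'   recall-maximizing choice, configurable upward to suppress pseudo-PHI).
#' @return A `phi_decision` with `pii`, `health_matches`, and `phi_flag`.
#' @export
evaluate_phi <- function(pii, health, min_health_terms = 1L) {
  stopifnot(inherits(pii, "pii_result"))
  structure(
    list(
      pii = pii,
      health_matches = health,
      n_health_terms = length(unique(health$term)),
      phi_flag = isTRUE(pii$pii_flag) &&
        length(unique(health$term)) >= min_health_terms
    ),
    class = "phi_decision"
  )
}

#' @export
print.phi_decision <- function(x, ...) {
  cat(sprintf("<phi_decision> phi=%s (pii=%s, %d distinct health terms)\n",
              x$phi_flag, x$pii$pii_flag, x$n_health_terms))
  invisible(x)
}
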