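# Independent brute-force oracles used to cross-check the detectors, plus a
# seeded random-document factory. The oracles deliberately re-derive every
# step (offset scanning, span mapping, overlap suppression) with different
# algorithms from the implementation.

# All matches of one regex in `text`, found by testing every character
# offset as a potential match start (regexpr on each suffix, accepting only
# position-1 hits). Returns char start/end pairs.
scan_all_offsets <- function(text, rx) {
  out <- list()
  n <- nchar(text)
  for (s in seq_len(n)) {
    # keep one character of left context so \b anchors see the real
    # preceding character, then accept only matches at the probed offset
    from <- max(s - 1L, 1L)
    want <- s - from + 1L
    m <- regexpr(rx, substr(text, from, n), perl = TRUE)
    if (m == want) {
      out[[length(out) + 1L]] <- c(s, s + attr(m, "match.length") - 1L)
    }
  }
  out
}

# Brute-force structured-identifier scan: every pattern applied at every
# offset of the space-joined tokens, spans mapped to token offsets by
# counting spaces, maximal character spans kept via pairwise comparison.
oracle_structured <- function(doc, health_cards = read_health_card_patterns()) {
  tokens <- doc$tokens
  joined <- paste(tokens, collapse = " ")
  # char position -> token index, by walking the joined string
  tok_of <- integer(nchar(joined))
  t <- 1L
  for (i in seq_len(nchar(joined))) {
    tok_of[i] <- t
    if (substr(joined, i, i) == " ") t <- t + 1L
  }
  ok_year <- function(s) {
    if (!grepl("\\d{3,4}$", s)) return(TRUE)
    grepl("^(19|20)\\d{2}$", sub(".*?(\\d{3,4})$", "\\1", s))
  }
  months <- paste0("(january|february|march|april|may|june|july|august|",
                   "september|october|november|december|jan|feb|mar|apr|jun|",
                   "jul|aug|sept|sep|oct|nov|dec)")
  spec <- list(
    list(sub = "phone", cat = "structured", chk = NULL, rx = c(
      "\\(\\d{3}\\) ?\\d{3}[ .-]?\\d{4}\\b",
      "\\b\\d{3}[ .-]\\d{3}[ .-]\\d{4}\\b",
      "\\b\\d{3}[.-]\\d{4}\\b")),
    list(sub = "health_insurance", cat = "structured", chk = NULL,
         rx = unname(health_cards)),
    list(sub = "date", cat = "structured", chk = ok_year, rx = c(
      paste0("(?i)\\b", months, "\\.?,? [0-3]?\\d(st|nd|rd|th)?(,? \\d{3,4})?\\b"),
      paste0("(?i)\\b[0-3]?\\d(st|nd|rd|th)?( of)? ", months, "\\.?(,? \\d{3,4})?\\b"),
      "\\b[0-3]?\\d[/-][0-3]?\\d[/-](\\d{4}|\\d{2})\\b")),
    list(sub = "email", cat = "structured", chk = NULL, rx = c(
      "\\b[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}\\b",
      "\\b[A-Za-z0-9._-]+ AT [A-Za-z0-9._-]+( DOT [A-Za-z0-9_-]+)+\\b")),
    list(sub = "postal_code", cat = "geographic", chk = NULL, rx = c(
      "\\b[A-Z]\\d[A-Z] ?\\d[A-Z]\\d\\b",
      "\\b\\d{5}(-\\d{4})?\\b"))
  )
  rows <- list()
  for (p in spec) {
    for (rx in p$rx) {
      for (span in scan_all_offsets(joined, rx)) {
        txt <- substr(joined, span[1], span[2])
        if (!is.null(p$chk) && !p$chk(txt)) next
        rows[[length(rows) + 1L]] <- data.frame(
          category = p$cat, subcategory = p$sub,
          start = tok_of[span[1]] - 1L, end = tok_of[span[2]],
          text = txt, cs = span[1], ce = span[2], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(category = character(), subcategory = character(),
                      start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, rows))
  # pairwise maximal-span suppression
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || !keep[i]) next
      wider <- df$cs[j] <= df$cs[i] && df$ce[j] >= df$ce[i] &&
        (df$ce[j] - df$cs[j]) > (df$ce[i] - df$cs[i])
      if (wider && keep[j]) keep[i] <- FALSE
    }
  }
  # equal spans across subcategories: keep only the first in precedence order
  df <- df[keep, , drop = FALSE]
  prec <- c(phone = 1, health_insurance = 2, date = 3, email = 4, postal_code = 5)
  df <- df[order(df$cs, prec[df$subcategory]), , drop = FALSE]
  dup <- duplicated(df[, c("cs", "ce")])
  df <- df[!dup, c("category", "subcategory", "start", "end", "text")]
  df <- df[order(df$start, df$subcategory, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Brute-force health scan: enumerate every whole-word window of the
# normalized stream that is a lexicon term, then select greedily from the
# left preferring the longest match at each position.
oracle_health <- function(doc, lexicon) {
  stops <- lexicon$stop_words
  words <- character(0)
  orig <- integer(0)
  for (i in seq_along(doc$tokens)) {
    t <- gsub("[^a-z]+", " ", tolower(doc$tokens[i]))
    ws <- strsplit(trimws(t), " ", fixed = TRUE)[[1]]
    ws <- ws[nzchar(ws) & !ws %in% stops]
    words <- c(words, ws)
    orig <- c(orig, rep(i, length(ws)))
  }
  terms <- names(lexicon$terms)
  max_len <- if (length(terms)) max(lengths(strsplit(terms, " "))) else 1L
  cands <- list()
  for (i in seq_along(words)) {
    for (len in seq_len(min(max_len, length(words) - i + 1L))) {
      key <- paste(words[i:(i + len - 1L)], collapse = " ")
      if (key %in% terms) {
        cands[[length(cands) + 1L]] <- list(i = i, len = len, key = key)
      }
    }
  }
  taken <- rep(FALSE, length(words))
  rows <- list()
  if (length(cands)) {
    ord <- order(vapply(cands, `[[`, 0L, "i"), -vapply(cands, `[[`, 0L, "len"))
    for (c_ in cands[ord]) {
      idx <- c_$i:(c_$i + c_$len - 1L)
      if (any(taken[idx])) next
      taken[idx] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        term = c_$key, category = unname(lexicon$terms[c_$key]),
        start = orig[c_$i] - 1L, end = orig[c_$i + c_$len - 1L],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(term = character(), category = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force out-of-place ranking: linear search for each document n-gram
# in each profile, explicit loop accumulation, insertion-order sort.
oracle_language <- function(doc, profiles, profile_length = 400L) {
  dp <- build_language_profile(doc$text, "doc", profile_length = profile_length)
  dist <- numeric(length(profiles))
  for (k in seq_along(profiles)) {
    total <- 0
    ranked <- profiles[[k]]$ranked_ngrams
    for (r in seq_along(dp$ranked_ngrams)) {
      g <- dp$ranked_ngrams[r]
      pos <- 0L
      for (q in seq_along(ranked)) {
        if (ranked[q] == g) {
          pos <- q
          break
        }
      }
      total <- total + if (pos == 0L) profile_length else abs(r - pos)
    }
    dist[k] <- total
  }
  langs <- unname(vapply(profiles, `[[`, "", "language_code"))
  best <- langs[order(dist, langs, method = "radix")][1]
  list(language = best, is_english = best == "en", distance = dist)
}

# ---- random document factory -------------------------------------------------

filler_words <- c(
  "the", "quick", "brown", "fox", "jumped", "over", "a", "lazy", "dog",
  "while", "rain", "fell", "softly", "on", "rooftops", "and", "gardens",
  "nearby", "children", "played", "until", "dusk", "settled", "in"
)

planted_fragments <- function() {
  c("March 9th, 1999", "613-555-1234", "jane@example.ca",
    "john AT Canada DOT ca", "K1A 0B1", "90210", "12/31/1999",
    "(416) 555-0188", "555-0199", "4321-987-654", "chest pain", "arthritis",
    "blood pressure", "tylenol", "Toronto", "France", "William", "Smith")
}

random_doc <- function(max_tokens = 100L) {
  n <- sample(5:max_tokens, 1)
  words <- sample(filler_words, n, replace = TRUE)
  n_plant <- sample(0:3, 1)
  if (n_plant > 0) {
    for (frag in sample(planted_fragments(), n_plant)) {
      pos <- sample(seq_along(words), 1)
      words <- append(words, strsplit(frag, " ")[[1]], after = pos)
    }
  }
  as_extracted_doc(paste(words, collapse = " "))
}
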