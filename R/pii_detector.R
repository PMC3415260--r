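# Personally identifiable information (PII) detection: person identifiers,
# structured identifiers (soft regular expressions), geographic identifiers,
# organizations, and the PII decision rule.

# ---- resource readers --------------------------------------------------------

#' Read the personal-name lexicon
#'
#' Three plain-text lists (one name per line, UTF-8): female first names,
#' male first names, and last names. Lists include informal forms and common
#' misspellings. Lookup is case-insensitive, but only capitalized document
#' tokens are candidates.
#'
#' @param female,male,last Paths to the three name lists.
#' @return A `name_lexicon` with lowercase sets `female_first`, `male_first`,
#'   and `last`.
#' @export
read_name_lexicon <- function(female, male, last) {
  rd <- function(p) {
    x <- readLines(p, encoding = "UTF-8", warn = FALSE)
    unique(tolower(trimws(x[nzchar(trimws(x))])))
  }
  structure(
    list(female_first = rd(female), male_first = rd(male), last = rd(last)),
    class = "name_lexicon"
  )
}

#' Read trigger patterns for name harvesting
#'
#' One `pattern<TAB>direction<TAB>kind` per line. `direction` says on which
#' side of the pattern capitalized words are captured (`preceding` or
#' `following`); `kind` is one of `relation`, `self_id`, `life_event`.
#'
#' @param path Pattern file path.
#' @return Data frame with columns `pattern`, `direction`, `kind`.
#' @export
read_trigger_patterns <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("pattern", "direction", "kind"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  stopifnot(all(df$direction %in% c("preceding", "following")))
  df$pattern <- squash_ws(df$pattern)
  df
}

#' Read the geographic gazetteer
#'
#' One `entry<TAB>tier` per line. Tiers record granularity: `country` and
#' `capital` (UN-recognized countries, their capitals, self-proclaimed
#' entities), `us_place` (state, state capital, largest city), `ca_place`
#' (province/territory, capital, largest cities, tourist attractions), and
#' `world_city` (major non-capital cities elsewhere).
#'
#' @param path Gazetteer file path.
#' @return Data frame with columns `entry`, `tier`, `subcategory` (`country`
#'   for country/capital tiers, `place` otherwise).
#' @export
read_gazetteer <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("entry", "tier"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  df$entry <- gsub("\\s+", " ", trimws(df$entry))
  df$subcategory <- ifelse(df$tier %in% c("country", "capital"), "country", "place")
  df
}

#' Read organization patterns
#'
#' One `kind<TAB>term` per line with kinds `language_pattern` (e.g. "lived
#' in"), `org_type` (schools, churches, military units, care homes, ...) and
#' `target_population` (youth, women, seniors, ...).
#'
#' @param path Pattern file path.
#' @return List with character vectors `language_patterns`, `org_types`,
#'   `target_populations`.
#' @export
read_org_patterns <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("kind", "term"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  list(
    language_patterns = squash_ws(df$term[df$kind == "language_pattern"]),
    org_types = squash_ws(df$term[df$kind == "org_type"]),
    target_populations = squash_ws(df$term[df$kind == "target_population"])
  )
}

#' Read provincial health-card number patterns
#'
#' One `province<TAB>regex` per line; regexes are applied to the
#' space-joined token stream. The defaults cover Ontario (10 digits with
#' optional two-letter version code), Quebec (four letters + eight digits)
#' and BC-style ten-digit personal health numbers, and are user-replaceable.
#'
#' @param path Pattern file; defaults to the packaged set.
#' @return Named character vector of regular expressions.
#' @export
read_health_card_patterns <- function(path = system.file("extdata",
                                                         "health_cards.tsv",
                                                         package = "phitriage")) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("province", "regex"),
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", fileEncoding = "UTF-8")
  stats::setNames(df$regex, df$province)
}

# ---- candidate-name harvesting -----------------------------------------------

# Token spans (1-based inclusive) at which any of `terms` (lowercase,
# possibly multiword) occurs in the normalized token vector `norm`.
find_term_spans <- function(norm, terms) {
  if (length(terms) == 0L || length(norm) == 0L) {
    return(data.frame(from = integer(), to = integer(), term = character(),
                      stringsAsFactors = FALSE))
  }
  split_terms <- strsplit(terms, " ", fixed = TRUE)
  out <- list()
  for (t in seq_along(terms)) {
    words <- split_terms[[t]]
    w <- length(words)
    if (w > length(norm)) next
    for (i in seq_len(length(norm) - w + 1L)) {
      if (all(norm[i:(i + w - 1L)] == words)) {
        out[[length(out) + 1L]] <- data.frame(
          from = i, to = i + w - 1L, term = terms[[t]], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(from = integer(), to = integer(), term = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Harvest candidate person names near trigger patterns
#'
#' Person-name lookup is expensive, so the document is first scanned for
#' family-relation, self-identification, and life-event trigger patterns;
#' for each occurrence, up to `capture_window` capitalized tokens on the
#' pattern's declared side are stored in the file's name list. Tokens on the
#' name list are later accepted as person names regardless of the lexicon.
#'
#' @param doc An `extracted_doc`.
#' @param patterns Data frame from [read_trigger_patterns()].
#' @param capture_window Maximum capitalized tokens captured per trigger
#'   occurrence (default 2, enough for "First Last").
#' @return Character vector of unique candidate names (original casing).
#' @export
harvest_candidate_names <- function(doc, patterns, capture_window = 2L) {
  cores <- token_core(doc$tokens)
  norm <- tolower(cores)
  caps <- is_capitalized(cores)
  found <- character(0)
  for (p in seq_len(nrow(patterns))) {
    spans <- find_term_spans(norm, patterns$pattern[p])
    for (s in seq_len(nrow(spans))) {
      if (patterns$direction[p] == "following") {
        k <- spans$to[s] + 1L
        taken <- 0L
        while (k <= length(cores) && taken < capture_window && caps[k]) {
          found <- c(found, cores[k])
          taken <- taken + 1L
          k <- k + 1L
        }
      } else {
        k <- spans$from[s] - 1L
        grabbed <- character(0)
        while (k >= 1L && length(grabbed) < capture_window && caps[k]) {
          grabbed <- c(cores[k], grabbed)
          k <- k - 1L
        }
        found <- c(found, grabbed)
      }
    }
  }
  unique(found)
}

# ---- person names ------------------------------------------------------------

#' Detect person names
#'
#' Capitalized tokens are checked first against the file's harvested name
#' list (accepted regardless of the lexicon), then against the female-first,
#' male-first, and last-name lists. Lookup is case-insensitive; lowercase
#' tokens are never candidates, so sentence-initial capitalized words that
#' match no list produce no match.
#'
#' @param doc An `extracted_doc`.
#' @param lexicon A `name_lexicon`.
#' @param names Character vector from [harvest_candidate_names()].
#' @return Match data frame (`category` = "person"; `subcategory` one of
#'   `first_name`, `last_name`, `relation_name`; 0-based half-open `start`,
#'   `end` token offsets; `text`).
#' @export
detect_person_names <- function(doc, lexicon, names = character()) {
  cores <- token_core(doc$tokens)
  caps <- which(is_capitalized(cores))
  names_low <- tolower(names)
  rows <- list()
  for (i in caps) {
    low <- tolower(cores[i])
    in_first <- low %in% lexicon$female_first || low %in% lexicon$male_first
    in_last <- low %in% lexicon$last
    sub <- if (low %in% names_low) {
      if (in_first) "first_name" else if (in_last) "last_name" else "relation_name"
    } else if (in_first) {
      "first_name"
    } else if (in_last) {
      "last_name"
    } else {
      NA_character_
    }
    if (!is.na(sub)) {
      rows[[length(rows) + 1L]] <- data.frame(
        category = "person", subcategory = sub,
        start = i - 1L, end = i, text = cores[i], stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  do.call(rbind, rows)
}

# ---- structured identifiers --------------------------------------------------

# Character-offset bookkeeping for the space-joined token stream.
token_char_map <- function(tokens) {
  starts <- cumsum(c(1L, nchar(tokens) + 1L))[seq_along(tokens)]
  list(joined = paste(tokens, collapse = " "), starts = starts)
}

char_to_token_span <- function(map, s, e) {
  t0 <- findInterval(s, map$starts)
  t1 <- findInterval(e, map$starts)
  c(t0 - 1L, t1)
}

month_regex <- paste0(
  "(january|february|march|april|may|june|july|august|september|october|",
  "november|december|jan|feb|mar|apr|jun|jul|aug|sept|sep|oct|nov|dec)"
)

# A date is "specific" only with a day; dates are restricted to the 20th and
# 21st centuries (earlier dates are unlikely to concern a living person), so
# a trailing 3- or 4-digit year outside 1900-2099 invalidates the match.
validate_date_year <- function(text) {
  if (!grepl("\\d{3,4}$", text)) return(TRUE)
  year <- sub(".*?(\\d{3,4})$", "\\1", text)
  grepl("^(19|20)\\d{2}$", year)
}

structured_id_patterns <- function(health_card_patterns) {
  pats <- list(
    list(subcategory = "phone", category = "structured", validate = NULL,
         regex = c(
           "\\(\\d{3}\\) ?\\d{3}[ .-]?\\d{4}\\b",    # (613) 555-1234
           "\\b\\d{3}[ .-]\\d{3}[ .-]\\d{4}\\b",     # 613-555-1234 / 613 555 1234
           "\\b\\d{3}[.-]\\d{4}\\b"                  # incomplete local: 555-1234
         )),
    list(subcategory = "health_insurance", category = "structured",
         validate = NULL, regex = unname(health_card_patterns)),
    list(subcategory = "date", category = "structured",
         validate = validate_date_year,
         regex = c(
           paste0("(?i)\\b", month_regex,
                  "\\.?,? [0-3]?\\d(st|nd|rd|th)?(,? \\d{3,4})?\\b"),
           paste0("(?i)\\b[0-3]?\\d(st|nd|rd|th)?( of)? ", month_regex,
                  "\\.?(,? \\d{3,4})?\\b"),
           "\\b[0-3]?\\d[/-][0-3]?\\d[/-](\\d{4}|\\d{2})\\b"
         )),
    list(subcategory = "email", category = "structured", validate = NULL,
         regex = c(
           "\\b[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}\\b",
           "\\b[A-Za-z0-9._-]+ AT [A-Za-z0-9._-]+( DOT [A-Za-z0-9_-]+)+\\b"
         )),
    # Postal and ZIP codes locate a person, so they sit in the geographic
    # category for the PII rule.
    list(subcategory = "postal_code", category = "geographic", validate = NULL,
         regex = c(
           "\\b[A-Z]\\d[A-Z] ?\\d[A-Z]\\d\\b",       # Canadian postal code
           "\\b\\d{5}(-\\d{4})?\\b"                  # US ZIP / ZIP+4
         ))
  )
  pats
}

#' Detect structured identifiers
#'
#' Deliberately permissive ("soft") regular expressions over the
#' space-joined token stream detect: North American telephone numbers in
#' complete and incomplete formats; provincial health insurance numbers;
#' specific dates (a day is required, and years are restricted to
#' 1900-2099); email addresses, including obfuscated `AT`/`DOT` forms; and
#' Canadian postal codes / US ZIP codes. Matches whose character span is
#' contained within another match are suppressed.
#'
#' @param doc An `extracted_doc`.
#' @param health_card_patterns Named regex vector from
#'   [read_health_card_patterns()].
#' @return Match data frame (columns `category`, `subcategory`, `start`,
#'   `end`, `text`); postal/ZIP codes carry category "geographic", the rest
#'   "structured".
#' @export
detect_structured_ids <- function(doc,
                                  health_card_patterns = read_health_card_patterns()) {
  if (length(doc$tokens) == 0L) return(empty_matches())
  map <- token_char_map(doc$tokens)
  rows <- list()
  pats <- structured_id_patterns(health_card_patterns)
  for (prec in seq_along(pats)) {
    p <- pats[[prec]]
    for (rx in p$regex) {
      m <- gregexpr(rx, map$joined, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      starts <- as.integer(m)
      lens <- attr(m, "match.length")
      for (k in seq_along(starts)) {
        s <- starts[k]
        e <- s + lens[k] - 1L
        txt <- substr(map$joined, s, e)
        if (!is.null(p$validate) && !p$validate(txt)) next
        sp <- char_to_token_span(map, s, e)
        rows[[length(rows) + 1L]] <- data.frame(
          category = p$category, subcategory = p$subcategory,
          start = sp[1], end = sp[2], text = txt,
          cstart = s, cend = e, prec = prec, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_matches())
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("subcategory", "cstart", "cend")]), , drop = FALSE]
  df <- df[order(df$cstart, -(df$cend - df$cstart), df$prec), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    contained <- df$cstart >= df$cstart[i] & df$cend <= df$cend[i] &
      seq_len(nrow(df)) != i & keep
    # strict containment or same span at lower precedence
    contained <- contained & !(df$cstart == df$cstart[i] & df$cend == df$cend[i] &
                                 seq_len(nrow(df)) < i)
    keep[contained] <- FALSE
  }
  df <- df[keep, c("category", "subcategory", "start", "end", "text"), drop = FALSE]
  df <- df[order(df$start, df$subcategory, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- geographic identifiers --------------------------------------------------

#' Detect geographic identifiers
#'
#' Case-sensitive whole-phrase matching of gazetteer entries against the
#' punctuation-trimmed token stream, longest match first (so "New York"
#' beats "York"). Lowercase occurrences ("turkey dinner") never match.
#'
#' @param doc An `extracted_doc`.
#' @param gazetteer Data frame from [read_gazetteer()].
#' @return Match data frame with `category` "geographic" and `subcategory`
#'   `country` or `place`; the matched tier is in column `tier`.
#' @export
detect_geographic <- function(doc, gazetteer) {
  cores <- token_core(doc$tokens)
  n <- length(cores)
  if (n == 0L || nrow(gazetteer) == 0L) return(empty_matches())
  words <- strsplit(gazetteer$entry, " ", fixed = TRUE)
  nw <- lengths(words)
  max_w <- max(nw)
  rows <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (w in seq(min(max_w, n - i + 1L), 1L)) {
      cand <- which(nw == w)
      phrase <- cores[i:(i + w - 1L)]
      for (g in cand) {
        if (all(phrase == words[[g]])) {
          rows[[length(rows) + 1L]] <- data.frame(
            category = "geographic", subcategory = gazetteer$subcategory[g],
            start = i - 1L, end = i - 1L + w,
            text = paste(phrase, collapse = " "),
            tier = gazetteer$tier[g], stringsAsFactors = FALSE
          )
          i <- i + w
          matched <- TRUE
          break
        }
      }
      if (matched) break
    }
    if (!matched) i <- i + 1L
  }
  if (length(rows) == 0L) return(empty_matches())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- organizations -----------------------------------------------------------

#' Detect organization mentions
#'
#' Organizations (schools, churches, care homes, support centers, military
#' units, ...) identify where a person lives, studies, or receives care. An
#' organization-type term is reported when a language pattern ("lived in",
#' "come from") or a target-population term (youth, women, seniors) occurs
#' within `window` tokens of it; the match covers the span from trigger to
#' organization type.
#'
#' @param doc An `extracted_doc`.
#' @param org List from [read_org_patterns()].
#' @param window Token co-occurrence window (default 10).
#' @return Match data frame with `category` "geographic", `subcategory`
#'   "organization".
#' @export
detect_organizations <- function(doc, org, window = 10L) {
  cores <- token_core(doc$tokens)
  norm <- sub("['’]s$", "", tolower(cores))
  with_plurals <- function(terms) {
    unique(unlist(lapply(terms, term_variants)))
  }
  types <- find_term_spans(norm, with_plurals(org$org_types))
  if (nrow(types) == 0L) return(empty_matches())
  triggers <- rbind(
    find_term_spans(norm, org$language_patterns),
    find_term_spans(norm, with_plurals(org$target_populations))
  )
  if (nrow(triggers) == 0L) return(empty_matches())
  rows <- list()
  for (t in seq_len(nrow(types))) {
    near <- which(triggers$from <= types$to[t] + window &
                    triggers$to >= types$from[t] - window)
    if (length(near) == 0L) next
    k <- near[which.min(pmax(abs(triggers$from[near] - types$to[t]),
                             abs(types$from[t] - triggers$to[near])))]
    from <- min(types$from[t], triggers$from[k])
    to <- max(types$to[t], triggers$to[k])
    rows[[length(rows) + 1L]] <- data.frame(
      category = "geographic", subcategory = "organization",
      start = from - 1L, end = to,
      text = paste(doc$tokens[from:to], collapse = " "),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty_matches())
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# ---- decision rule -----------------------------------------------------------

#' Apply the PII decision rule
#'
#' A document carries PII when it contains at least one geographic
#' identifier (place, country, postal/ZIP code, or organization) and at
#' least two other personal identifiers -- distinct (subcategory, text)
#' pairs from the person or structured categories, so the same string
#' matched twice counts once. Typical qualifying pairs: first + last name,
#' or first name + date of birth.
#'
#' @param matches Match data frame (rows from the four detectors combined).
#' @return A `pii_result` with `matches`, counts, and logical `pii_flag`.
#' @export
evaluate_pii_rule <- function(matches) {
  geo <- matches[matches$category == "geographic", , drop = FALSE]
  oth <- matches[matches$category %in% c("person", "structured"), , drop = FALSE]
  ids <- unique(data.frame(subcategory = oth$subcategory,
                           text = tolower(oth$text), stringsAsFactors = FALSE))
  structure(
    list(matches = matches, n_geographic = nrow(geo),
         n_identifiers = nrow(ids),
         pii_flag = nrow(geo) >= 1L && nrow(ids) >= 2L),
    class = "pii_result"
  )
}

#' @export
print.pii_result <- function(x, ...) {
  cat(sprintf("<pii_result> flag=%s (%d geographic, %d distinct identifiers)\n",
              x$pii_flag, x$n_geographic, x$n_identifiers))
  invisible(x)
}

#' Run the full PII detector on one document
#'
#' Harvests candidate names, runs the person, structured, geographic, and
#' organization detectors, and applies the PII rule.
#'
#' @param doc An `extracted_doc`.
#' @param resources Resource list from [load_resources()].
#' @return A `pii_result`.
#' @export
run_pii_detector <- function(doc, resources) {
  cand <- harvest_candidate_names(doc, resources$triggers,
                                  resources$config$capture_window)
  matches <- rbind(
    detect_person_names(doc, resources$name_lexicon, cand),
    detect_structured_ids(doc, resources$health_cards),
    detect_geographic(doc, resources$gazetteer)[, c("category", "subcategory",
                                                    "start", "end", "text")],
    detect_organizations(doc, resources$org_patterns,
                         resources$config$org_window)
  )
  evaluate_pii_rule(matches)
}
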