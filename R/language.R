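# Character n-gram language identification (Cavnar-Trenkle out-of-place
# rank distance, the algorithm behind the classic TextCat guesser).

# All character n-grams (n in n_range) of the letter-only, lowercased,
# underscore-padded words of `text`.
char_ngrams <- function(text, n_range = 1:5) {
  words <- strsplit(gsub("[^[:alpha:]]+", " ", tolower(text)), " ", fixed = TRUE)[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0L) return(character(0))
  padded <- paste0("_", words, "_")
  grams <- vector("list", length(padded))
  for (k in seq_along(padded)) {
    w <- padded[[k]]
    nc <- nchar(w)
    pieces <- lapply(n_range[n_range <= nc], function(n) {
      substring(w, 1:(nc - n + 1L), n:nc)
    })
    grams[[k]] <- unlist(pieces, use.names = FALSE)
  }
  unlist(grams, use.names = FALSE)
}

#' Build a character n-gram language profile
#'
#' Counts the character n-grams (word-boundary padded, letters only,
#' lowercased) of a training text and ranks them by descending frequency,
#' breaking ties lexicographically (byte order), truncated to
#' `profile_length` entries.
#'
#' @param training_text Nonempty character scalar of text in one language.
#' @param language_code Short code stored with the profile (e.g. `"en"`).
#' @param n_range Integer vector of n-gram sizes (default 1 to 5).
#' @param profile_length Maximum number of ranked n-grams kept (default 400).
#' @return A `language_profile` with fields `language_code`, `ranked_ngrams`,
#'   and `profile_length`.
#' @export
build_language_profile <- function(training_text, language_code = "??",
                                   n_range = 1:5, profile_length = 400L) {
  stopifnot(is.character(training_text), length(training_text) == 1L)
  grams <- char_ngrams(training_text, n_range)
  if (length(grams) == 0L) stop("cannot profile empty text")
  tab <- table(grams)
  ng <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, ng, method = "radix")
  structure(
    list(
      language_code = language_code,
      ranked_ngrams = utils::head(ng[ord], profile_length),
      profile_length = as.integer(profile_length)
    ),
    class = "language_profile"
  )
}

#' @export
print.language_profile <- function(x, ...) {
  cat(sprintf("<language_profile> %s: %d n-grams (top: %s)\n",
              x$language_code, length(x$ranked_ngrams),
              paste(utils::head(x$ranked_ngrams, 5), collapse = " ")))
  invisible(x)
}

#' Read / write language profiles
#'
#' Profile files hold one n-gram per line in rank order; the file name (minus
#' extension) is the language code.
#'
#' @param path Profile file path.
#' @param profile A `language_profile`.
#' @return `read_language_profile` returns a `language_profile`.
#' @export
read_language_profile <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  structure(
    list(
      language_code = tools::file_path_sans_ext(basename(path)),
      ranked_ngrams = lines,
      profile_length = length(lines)
    ),
    class = "language_profile"
  )
}

#' @rdname read_language_profile
#' @export
write_language_profile <- function(profile, path) {
  writeLines(profile$ranked_ngrams, path, useBytes = TRUE)
  invisible(path)
}

#' Bundled language profiles
#'
#' Loads the packaged profiles (English, French, Spanish, German), built from
#' the bundled training paragraphs with the default parameters.
#'
#' @param dir Directory of `.profile` files; defaults to the packaged set.
#' @return Named list of `language_profile` objects.
#' @export
default_language_profiles <- function(dir = system.file("extdata", "lang",
                                                        package = "phitriage")) {
  paths <- sort_c(list.files(dir, pattern = "\\.profile$", full.names = TRUE))
  profiles <- lapply(paths, read_language_profile)
  names(profiles) <- vapply(profiles, `[[`, "", "language_code")
  profiles
}

# Out-of-place distance between a ranked document profile and a ranked
# language profile: sum over document n-grams of |rank difference|, with a
# fixed penalty of `profile_length` for n-grams absent from the language
# profile.
out_of_place_distance <- function(doc_ngrams, profile_ngrams, profile_length) {
  if (length(doc_ngrams) == 0L) return(Inf)
  pos <- match(doc_ngrams, profile_ngrams)
  pen <- abs(seq_along(doc_ngrams) - pos)
  pen[is.na(pos)] <- profile_length
  sum(as.numeric(pen))
}

#' Identify the language of a document
#'
#' Builds an n-gram profile of the document and ranks the candidate language
#' profiles by ascending out-of-place distance (ties broken by language
#' code). The document is accepted as English only when `"en"` ranks first.
#' Documents shorter than `min_tokens` whitespace tokens are classified
#' `"unknown"` (rank distances are meaningless on tiny inputs) and treated as
#' non-English.
#'
#' @param doc An `extracted_doc`.
#' @param profiles List of `language_profile`s, at least two, including `"en"`.
#' @param n_range,profile_length Profile parameters; must match those used to
#'   build `profiles`.
#' @param min_tokens Minimum token count for classification (default 10).
#' @return List with `ranking` (data frame of `language`, `distance`),
#'   `language` (top-ranked code or `"unknown"`), and `is_english`.
#' @export
identify_language <- function(doc, profiles, n_range = 1:5,
                              profile_length = 400L, min_tokens = 10L) {
  stopifnot(length(profiles) >= 2L,
            "en" %in% vapply(profiles, `[[`, "", "language_code"))
  if (length(doc$tokens) < min_tokens) {
    return(list(
      ranking = data.frame(language = character(), distance = numeric(),
                           stringsAsFactors = FALSE),
      language = "unknown", is_english = FALSE
    ))
  }
  dp <- build_language_profile(doc$text, "doc", n_range = n_range,
                               profile_length = profile_length)
  langs <- vapply(profiles, `[[`, "", "language_code")
  dist <- vapply(profiles, function(p) {
    out_of_place_distance(dp$ranked_ngrams, p$ranked_ngrams, profile_length)
  }, numeric(1))
  ord <- order(dist, langs, method = "radix")
  ranking <- data.frame(language = langs[ord], distance = dist[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  list(ranking = ranking, language = ranking$language[1],
       is_english = identical(ranking$language[1], "en"))
}
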