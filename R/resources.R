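# Configuration and resource loading. Every lexicon, gazetteer, pattern
# file, and profile directory is a plain-text resource resolvable through
# the config, so users can substitute larger or localized resources.

#' Default pipeline configuration
#'
#' Returns the resolved configuration used by [run_pipeline()]: paths to the
#' packaged resources and the tunable parameters (all user-overridable via a
#' YAML config, see [load_config()]).
#'
#' Parameters: `prefix_len` -- tokens searched by the publishable-content
#' stage (200); `min_health_terms` -- distinct health terms required for a
#' PHI flag (1); `min_tokens_language` -- shortest document the language
#' identifier will classify (10 tokens, shorter is "unknown" and discarded);
#' `profile_length` (400) and `ngram_min`/`ngram_max` (1/5) -- language
#' profile shape; `capture_window` -- capitalized tokens captured per name
#' trigger (2); `org_window` -- organization co-occurrence window (10);
#' `disabled_stages` -- stage names to skip (empty by default; the
#' false-negative audit mode disables `"duplicate_removal"`).
#'
#' @return Named list of class `phitriage_config`.
#' @export
default_config <- function() {
  ext <- function(...) system.file("extdata", ..., package = "phitriage")
  structure(list(
    resources = list(
      titles = ext("titles.txt"),
      content_keywords = ext("content_keywords.tsv"),
      profiles_dir = ext("lang"),
      female_first = ext("female_first.txt"),
      male_first = ext("male_first.txt"),
      last_names = ext("last_names.txt"),
      triggers = ext("trigger_patterns.tsv"),
      gazetteer = ext("gazetteer.tsv"),
      org_patterns = ext("org_patterns.tsv"),
      health_terms = ext("health_terms.tsv"),
      stop_words = ext("stopwords.txt"),
      health_cards = ext("health_cards.tsv")
    ),
    exemption_words = c("notification", "affidavit", "justice", "discharge", "lab"),
    prefix_len = 200L,
    min_health_terms = 1L,
    min_tokens_language = 10L,
    profile_length = 400L,
    ngram_min = 1L,
    ngram_max = 5L,
    capture_window = 2L,
    org_window = 10L,
    disabled_stages = character(0)
  ), class = "phitriage_config")
}

#' Load a YAML configuration
#'
#' Reads a YAML file and merges it over [default_config()]; only the keys
#' present in the file are overridden (nested under `resources:` for
#' resource paths).
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A `phitriage_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (!is.null(user$resources)) {
    cfg$resources <- utils::modifyList(cfg$resources, user$resources)
    user$resources <- NULL
  }
  out <- utils::modifyList(unclass(cfg), user)
  for (k in c("prefix_len", "min_health_terms", "min_tokens_language",
              "profile_length", "ngram_min", "ngram_max", "capture_window",
              "org_window")) {
    out[[k]] <- as.integer(out[[k]])
  }
  structure(out, class = "phitriage_config")
}

#' Load all pipeline resources
#'
#' Resolves and reads every resource referenced by the configuration,
#' failing at startup with the offending path if one is missing.
#'
#' @param config A `phitriage_config`.
#' @return List with the loaded `title_db`, `keywords`, `profiles`,
#'   `name_lexicon`, `triggers`, `gazetteer`, `org_patterns`,
#'   `health_lexicon`, `health_cards`, and the `config` itself.
#' @export
load_resources <- function(config = default_config()) {
  r <- config$resources
  missing <- names(r)[!vapply(r, function(p) nzchar(p) && file.exists(p), logical(1))]
  if (length(missing)) {
    stop("missing resource file(s): ",
         paste(sprintf("%s (%s)", missing, unlist(r[missing])), collapse = ", "))
  }
  stop_words <- read_stop_words(r$stop_words)
  list(
    title_db = read_title_database(r$titles, config$exemption_words),
    keywords = read_content_keywords(r$content_keywords),
    profiles = default_language_profiles(r$profiles_dir),
    name_lexicon = read_name_lexicon(r$female_first, r$male_first, r$last_names),
    triggers = read_trigger_patterns(r$triggers),
    gazetteer = read_gazetteer(r$gazetteer),
    org_patterns = read_org_patterns(r$org_patterns),
    health_lexicon = build_health_lexicon(read_health_sources(r$health_terms),
                                          stop_words),
    health_cards = read_health_card_patterns(r$health_cards),
    config = config
  )
}
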