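# Seeded synthetic corpus generator. Emulates the document classes observed
# on file-sharing networks -- PHI letters, pseudo-PHI forms/CVs/essays,
# published and keyword-bearing texts, non-English texts, byte-identical
# duplicates, and binary junk -- so every pipeline stage has ground truth by
# construction. Class construction draws only on the packaged lexicons and
# gazetteers, so the intended outcome of every file is decidable without
# running the pipeline.

#' Specify a synthetic corpus
#'
#' Counts per document class. `true_phi` documents contain, by
#' construction, a gazetteer place, at least two person/structured
#' identifiers, and health-lexicon terms; `pseudo_phi` documents (blank
#' insurance forms, medical CVs, student essays) also satisfy both
#' detectors and are flagged -- separating them from true PHI is a manual
#' review step, not an algorithmic one. `benign_personal` documents satisfy
#' the PII rule but contain no health term; `health_only` documents contain
#' health terms but at most one non-geographic identifier. `published`
#' files either bear a known publication title or carry publishable-content
#' keywords in their first words; `duplicates` are byte-identical copies
#' (same file name, different directory) of other generated files;
#' `binary_junk` files are random bytes under media extensions.
#'
#' @param true_phi,pseudo_phi,published,non_english,duplicates,binary_junk,benign_personal,health_only
#'   Non-negative class counts. Defaults give a 520-file corpus dominated
#'   by benign material, mirroring the observation that most shared files
#'   leak nothing.
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return A `corpus_spec`.
#' @export
corpus_spec <- function(true_phi = 40L, pseudo_phi = 40L, published = 80L,
                        non_english = 80L, duplicates = 40L, binary_junk = 40L,
                        benign_personal = 100L, health_only = 100L, seed = 1L) {
  counts <- c(true_phi = true_phi, pseudo_phi = pseudo_phi,
              published = published, non_english = non_english,
              duplicates = duplicates, binary_junk = binary_junk,
              benign_personal = benign_personal, health_only = health_only)
  stopifnot(all(counts >= 0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(c(as.list(counts), list(seed = as.integer(seed))),
            class = "corpus_spec")
}

# ---- slot pools --------------------------------------------------------------

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# Curated slot pools, filtered against the other packaged resources so that
# a slot value can only trigger the detector it is meant for.
fixture_pools <- function(res) {
  gaz_words <- tolower(unlist(strsplit(res$gazetteer$entry, " ", fixed = TRUE)))
  health_words <- unlist(strsplit(names(res$health_lexicon$terms), " ", fixed = TRUE))
  kw_words <- unlist(strsplit(res$keywords$term, " ", fixed = TRUE))
  all_names <- c(res$name_lexicon$female_first, res$name_lexicon$male_first,
                 res$name_lexicon$last)
  blocked <- c(gaz_words, health_words, kw_words)

  firsts <- setdiff(c(res$name_lexicon$female_first, res$name_lexicon$male_first),
                    blocked)
  firsts <- sort_c(firsts[grepl("^[a-z]{4,}$", firsts)])
  lasts <- setdiff(res$name_lexicon$last, c(blocked, firsts))
  lasts <- sort_c(lasts[grepl("^[a-z]{4,}$", lasts)])

  entry_words <- strsplit(res$gazetteer$entry, " ", fixed = TRUE)
  safe_place <- vapply(entry_words, function(ws) {
    all(!tolower(ws) %in% c(all_names, health_words, kw_words))
  }, logical(1))
  places <- sort_c(unique(res$gazetteer$entry[safe_place]))

  hterms <- names(res$health_lexicon$terms)
  hcats <- unname(res$health_lexicon$terms)
  safe_h <- vapply(strsplit(hterms, " ", fixed = TRUE), function(ws) {
    length(ws) <= 2L && all(nchar(ws) >= 3L) &&
      all(!ws %in% c(all_names, gaz_words, kw_words))
  }, logical(1))
  health <- function(cats) sort_c(hterms[safe_h & hcats %in% cats])

  list(
    firsts = cap1(firsts), lasts = cap1(lasts), places = places,
    diseases = health("disease"), symptoms = health(c("symptom", "condition")),
    procedures = health("procedure"),
    drugs = health(c("drug_generic", "drug_trade")),
    specialties = health("specialty")
  )
}

pick <- function(pool, n = 1L) pool[sample.int(length(pool), n)]

rand_phone <- function() {
  sprintf("%d%d%d-%d%d%d-%d%d%d%d",
          sample(2:9, 1), sample(0:9, 1), sample(0:9, 1),
          sample(2:9, 1), sample(0:9, 1), sample(0:9, 1),
          sample(0:9, 1), sample(0:9, 1), sample(0:9, 1), sample(0:9, 1))
}

rand_date <- function() {
  m <- pick(c("January", "February", "March", "April", "June", "July",
              "August", "September", "October", "November", "December"))
  d <- sample(1:28, 1)
  suf <- c("st", "nd", "rd", rep("th", 17), "st", "nd", "rd", rep("th", 5))[d]
  sprintf("%s %d%s, %d", m, d, suf, sample(1950:2009, 1))
}

rand_health_card <- function() {
  sprintf("%04d-%03d-%03d", sample(1000:9999, 1), sample(100:999, 1),
          sample(100:999, 1))
}

rand_email <- function(first, last, obfuscated = runif(1) < 0.3) {
  user <- tolower(paste0(substr(first, 1, 1), last))
  if (obfuscated) paste(user, "AT", "example", "DOT", "ca")
  else paste0(user, "@example.ca")
}

# ---- document templates ------------------------------------------------------

gen_true_phi <- function(p) {
  first <- pick(p$firsts)
  last <- pick(p$lasts)
  first2 <- pick(setdiff(p$firsts, first))
  last2 <- pick(setdiff(p$lasts, last))
  place <- pick(p$places)
  if (runif(1) < 0.5) {
    paste0(
      "Dear ", pick(c("Mrs", "Mr")), " ", last2, ",\n\n",
      "I will be away until ", rand_date(), " and my daughter ", first, " ",
      last, " will stay with you. She was born on ", rand_date(),
      " and has ", pick(p$diseases), ". She takes ", pick(p$drugs),
      " every morning, and if her ", pick(p$symptoms),
      " returns please call the number below. We live near ", place,
      " and can be reached at ", rand_phone(), ".\n\nSincerely,\n",
      first2, " ", last, "\n"
    )
  } else {
    paste0(
      "To whom it may concern,\n\n",
      "This letter confirms that my client ", first, " ", last, " of ", place,
      " attended the appointment on ", rand_date(), ". Following the ",
      pick(p$procedures), ", my client requires rest and continues treatment for ",
      pick(p$diseases), ". Questions can be sent to ",
      rand_email(first, tolower(last)), " or left at ", rand_phone(),
      ".\n\nRegards,\n", first2, " ", last2, "\n"
    )
  }
}

gen_pseudo_phi <- function(p) {
  first <- pick(p$firsts)
  last <- pick(p$lasts)
  place <- pick(p$places)
  kind <- sample(3L, 1)
  if (kind == 1L) {
    paste0(
      "Extended health insurance claim\n\n",
      "Patient name: ", first, " ", last, "\n",
      "Date of birth: ", rand_date(), "\n",
      "Health card number: ", rand_health_card(), "\n",
      "Town of residence: ", place, "\n",
      "Condition treated: ", pick(p$diseases), "\n",
      "Prescribed drug: ", pick(p$drugs), "\n",
      "Daytime telephone: ", rand_phone(), "\n\n",
      "Signature: ____________\n"
    )
  } else if (kind == 2L) {
    paste0(
      "Professional profile of ", first, " ", last, ", a registered ",
      pick(p$specialties), " based in ", place,
      ". Experience includes ", pick(p$procedures),
      " support and daily care for patients with ", pick(p$diseases),
      ". Reach me by email at ", rand_email(first, tolower(last)),
      " or by telephone at ", rand_phone(), ". References available on request.\n"
    )
  } else {
    first2 <- pick(setdiff(p$firsts, first))
    paste0(
      "When I was four, I ended up in the hospital for playing with medicine. ",
      "The nurses treated my ", pick(p$symptoms), " and my mother ", first,
      " stayed overnight. My sister ", first2,
      " brought games, and our whole family drove back home to ", place,
      " the next weekend. I still remember the visit every ",
      pick(c("summer", "winter")), ".\n"
    )
  }
}

benign_filler <- c(
  "Thanks again for the lovely visit last month.",
  "We spent the weekend repainting the back fence.",
  "Your garden looked wonderful in the photos.",
  "Travel went smoothly and the roads were quiet.",
  "Everyone here sends warm wishes for the new year.",
  "Our neighbours helped us move the old piano.",
  "Dinner was delicious and the music carried on late.",
  "We hope the renovations are finished before winter."
)

gen_benign_personal <- function(p) {
  first <- pick(p$firsts)
  last <- pick(p$lasts)
  first2 <- pick(setdiff(p$firsts, first))
  place <- pick(p$places)
  paste0(
    "Hi ", first2, ",\n\n",
    paste(pick(benign_filler, sample(3:5, 1)), collapse = " "), " ",
    "We are planning to visit ", place, " again on ", rand_date(),
    ", and you can reach us at ", rand_phone(), " once we arrive. ",
    paste(pick(benign_filler, 2), collapse = " "), "\n\nSincerely,\n",
    first, " ", last, "\n"
  )
}

health_only_filler <- c(
  "Routine and patience make a real difference over time.",
  "A pharmacist can explain how doses interact before changes are made.",
  "Plain-language pamphlets from the local clinic describe what to expect.",
  "Gentle daily walks are often suggested as a starting point.",
  "Keeping a simple diary of meals and sleep can reveal patterns."
)

gen_health_only <- function(p) {
  hs <- pick(sort_c(unique(c(p$diseases, p$symptoms))), 3)
  paste0(
    "Living well with ", hs[1], " takes planning. ",
    pick(health_only_filler), " Many people find that ", hs[2],
    " improves with rest, while persistent ", hs[3],
    " deserves a conversation with a ", pick(p$specialties), ". ",
    paste(pick(health_only_filler, 2), collapse = " "), "\n"
  )
}

published_paragraphs <- c(
  "The narrative opens on a quiet coastal town where the seasons turn slowly and the harbour lights flicker against the evening tide.",
  "Critics praised the sweeping descriptions of landscape and the patient pacing of the middle chapters.",
  "In this volume the narrator revisits familiar streets, tracing how the town changed while its stories stayed the same.",
  "The collected chapters bring together material first drafted over a decade of quiet observation.",
  "Readers follow the slow unraveling of an old promise, told through letters found in an attic trunk."
)

gen_published_keyword <- function(res) {
  kw <- res$keywords
  row <- kw[sample.int(nrow(kw), 1), ]
  lead <- switch(
    row$category,
    Books = sprintf("This %s edition was prepared for wide distribution.", row$term),
    Education = sprintf("Submitted as a graduate %s in partial fulfilment of course requirements.", row$term),
    Retail = sprintf("Weekly flyer for %s locations across the region.", cap1(row$term)),
    Periodical = sprintf("Reprinted from a monthly %s with permission of the editors.", row$term),
    Fictional = sprintf("An appreciation of %s and the stories that made the character famous.", cap1(row$term)),
    Politics = sprintf("A commentary on speeches given by %s during the campaign season.", cap1(row$term)),
    sprintf("This %s edition was prepared for wide distribution.", row$term)
  )
  paste0(lead, " ", paste(pick(published_paragraphs, 3), collapse = " "), "\n")
}

# sentences of the bundled non-English training texts, cached per call
training_sentences <- function(lang_dir, code) {
  text <- paste(readLines(file.path(lang_dir, paste0(code, ".txt")),
                          encoding = "UTF-8", warn = FALSE), collapse = " ")
  segment(text)$sentences
}

# ---- file writers ------------------------------------------------------------

write_text_bytes <- function(path, text) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
}

rtf_escape <- function(text) {
  text <- gsub("\\\\", "\\\\\\\\", text)
  text <- gsub("\\{", "\\\\{", text)
  gsub("\\}", "\\\\}", text)
}

as_rtf <- function(text) {
  body <- paste(rtf_escape(strsplit(text, "\n", fixed = TRUE)[[1]]),
                collapse = "\\par ")
  paste0("{\\rtf1\\ansi\\deff0 {\\fonttbl{\\f0 Times New Roman;}} ", body, "}")
}

as_html <- function(text) {
  paras <- strsplit(text, "\n", fixed = TRUE)[[1]]
  paras <- paras[nzchar(paras)]
  paste0("<html><head><title>letter</title></head><body>",
         paste0("<p>", paras, "</p>", collapse = ""), "</body></html>")
}

# ---- generator ---------------------------------------------------------------

#' Generate a synthetic corpus
#'
#' Writes the files described by a [corpus_spec()] into `out_dir` and
#' returns the ground-truth manifest. Generation is deterministic: the same
#' spec and seed produce byte-identical corpora. Duplicate copies are
#' placed in a `zz/` subdirectory under their source file's name, so the
#' original (lexicographically first) copy is the one the pipeline retains.
#'
#' @param spec A `corpus_spec`.
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest: `path` (relative to `out_dir`), `class`,
#'   `intended_stage`, `intended_outcome` -- the terminal disposition the
#'   pipeline is expected to assign.
#' @export
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  cfg <- default_config()
  res <- load_resources(cfg)
  pools <- fixture_pools(res)
  titles <- readLines(cfg$resources$titles, encoding = "UTF-8", warn = FALSE)
  titles <- titles[nzchar(trimws(titles))]
  fr <- training_sentences(cfg$resources$profiles_dir, "fr")
  es <- training_sentences(cfg$resources$profiles_dir, "es")

  rows <- list()
  emit <- function(rel, class, stage, outcome, bytes = NULL, text = NULL) {
    path <- file.path(out_dir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    if (is.null(bytes)) write_text_bytes(path, text)
    else writeBin(bytes, path)
    rows[[length(rows) + 1L]] <<- data.frame(
      path = rel, class = class, intended_stage = stage,
      intended_outcome = outcome, stringsAsFactors = FALSE
    )
  }

  with_rng(spec$seed, {
    for (i in seq_len(spec$true_phi)) {
      emit(sprintf("phi_letter_%03d.txt", i), "true_phi",
           "health_detector", "phi_flagged", text = gen_true_phi(pools))
    }
    for (i in seq_len(spec$pseudo_phi)) {
      emit(sprintf("pseudo_doc_%03d.txt", i), "pseudo_phi",
           "health_detector", "phi_flagged", text = gen_pseudo_phi(pools))
    }
    n_title <- spec$published %/% 2L
    for (i in seq_len(n_title)) {
      title <- titles[((i - 1L) %% length(titles)) + 1L]
      rel <- sprintf("%s.txt", title)
      if (i > length(titles)) rel <- toupper(rel)  # same normalized title, new name
      emit(rel, "published", "title_filter", "discarded",
           text = paste(pick(published_paragraphs, 3), collapse = " "))
    }
    for (i in seq_len(spec$published - n_title)) {
      ext <- if (i %% 4L == 0L) "html" else "txt"
      body <- gen_published_keyword(res)
      if (ext == "html") body <- as_html(body)
      emit(sprintf("pub_front_%03d.%s", i, ext), "published",
           "content_filter", "discarded", text = body)
    }
    for (i in seq_len(spec$non_english)) {
      pool <- if (i %% 2L == 0L) fr else es
      emit(sprintf("lang_doc_%03d.txt", i), "non_english",
           "language_id", "discarded",
           text = paste(pick(pool, min(6L, length(pool))), collapse = " "))
    }
    for (i in seq_len(spec$binary_junk)) {
      ext <- if (i %% 3L == 0L) "rm" else "mp3"
      emit(sprintf("junk_media_%03d.%s", i, ext), "binary_junk",
           "text_extractor", "discarded",
           bytes = as.raw(sample(0:255, 512 + sample.int(1024, 1), replace = TRUE)))
    }
    for (i in seq_len(spec$benign_personal)) {
      text <- gen_benign_personal(pools)
      if (i %% 10L == 0L) {
        emit(sprintf("note_letter_%03d.rtf", i), "benign_personal",
             "health_detector", "discarded", text = as_rtf(text))
      } else if (i %% 10L == 5L) {
        emit(sprintf("note_letter_%03d.html", i), "benign_personal",
             "health_detector", "discarded", text = as_html(text))
      } else {
        emit(sprintf("note_letter_%03d.txt", i), "benign_personal",
             "health_detector", "discarded", text = text)
      }
    }
    for (i in seq_len(spec$health_only)) {
      emit(sprintf("info_sheet_%03d.txt", i), "health_only",
           "pii_detector", "discarded", text = gen_health_only(pools))
    }
    # byte-identical copies of already-generated files, same base name,
    # under zz/ so the original sorts (and is retained) first
    if (spec$duplicates > 0L) {
      manifest_so_far <- do.call(rbind, rows)
      sources <- if (is.null(manifest_so_far)) character(0) else manifest_so_far$path
      if (spec$duplicates > length(sources)) {
        stop("more duplicates requested than source files available")
      }
      dup_src <- pick(sources, spec$duplicates)
      for (s in dup_src) {
        raw <- readBin(file.path(out_dir, s), "raw",
                       n = file.info(file.path(out_dir, s))$size)
        emit(file.path("zz", basename(s)), "duplicates",
             "duplicate_removal", "discarded", bytes = raw)
      }
    }
  })

  if (length(rows) == 0L) {
    return(data.frame(path = character(), class = character(),
                      intended_stage = character(),
                      intended_outcome = character(), stringsAsFactors = FALSE))
  }
  manifest <- do.call(rbind, rows)
  manifest[order(manifest$path, method = "radix"), , drop = FALSE] ->
    manifest
  rownames(manifest) <- NULL
  manifest
}
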