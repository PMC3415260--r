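make_files <- function(dir, specs) {
  lapply(names(specs), function(nm) {
    load_file(write_fixture_file(dir, nm, specs[[nm]]))
  })
}

test_that("remove_duplicates requires agreement on size, title, and both fingerprints", {
  dir <- withr::local_tempdir()

  # byte-identical copies under different directories, same filename
  files <- make_files(dir, list("a/doc.txt" = "same content here",
                                "b/doc.txt" = "same content here"))
  res <- remove_duplicates(files)
  expect_length(res$retained, 1)
  expect_length(res$dispositions, 1)
  expect_identical(res$dispositions[[1]]$stage, "duplicate_removal")
  # lexicographically first path is the representative
  expect_identical(res$retained[[1]]$path, files[[1]]$path)

  # same title and size but different content fingerprints: both retained
  files2 <- make_files(dir, list("c/doc.txt" = strrep("x", 100),
                                 "d/doc.txt" = strrep("y", 100)))
  res2 <- remove_duplicates(files2)
  expect_length(res2$retained, 2)
  expect_length(res2$dispositions, 0)

  # singleton passes through
  res3 <- remove_duplicates(files2[1])
  expect_length(res3$retained, 1)
  expect_length(res3$dispositions, 0)

  # idempotence: a second pass discards nothing
  res4 <- remove_duplicates(res$retained)
  expect_length(res4$dispositions, 0)
  expect_length(res4$retained, length(res$retained))
})

test_that("published titles are discarded unless an exemption word intervenes", {
  dir <- withr::local_tempdir()
  db <- title_database(c("The Abominable Snowman", "hospital discharge summary",
                         "lab results 2007"))

  f <- load_file(write_fixture_file(dir, "The Abominable Snowman.txt", "story"))
  expect_false(filter_published_title(f, db))

  # normalization: case and whitespace do not defeat the exact match
  f2 <- load_file(write_fixture_file(dir, "the  ABOMINABLE   snowman.txt", "story"))
  expect_false(filter_published_title(f2, db))

  f3 <- load_file(write_fixture_file(dir, "hospital discharge summary.txt", "x"))
  expect_true(filter_published_title(f3, db))

  f4 <- load_file(write_fixture_file(dir, "unlisted memoir.txt", "x"))
  expect_true(filter_published_title(f4, db))

  # property: a title containing an exemption word is never discarded
  for (w in db$exemption_words) {
    t <- load_file(write_fixture_file(dir, sprintf("lab results 2007 %s.txt", w), "x"))
    expect_true(filter_published_title(t, title_database(
      c(db$titles, sprintf("lab results 2007 %s", w)))))
  }
})

test_that("language profiles rank n-grams by frequency with lexicographic tie-break", {
  p <- build_language_profile("aaa", "t", n_range = 1L)
  expect_identical(p$ranked_ngrams[1], "a")   # 3 occurrences beat the 2 pads

  # determinism: identical text gives identical profiles
  expect_identical(build_language_profile("the cat sat", "t")$ranked_ngrams,
                   build_language_profile("the cat sat", "t")$ranked_ngrams)

  # tie between "a" and "b" at equal counts: "a" first
  p2 <- build_language_profile("ab", "t", n_range = 1L)
  expect_identical(p2$ranked_ngrams, c("_", "a", "b"))

  expect_error(build_language_profile("", "t"), "empty")
  expect_error(build_language_profile("1234 !!", "t"), "empty")
})

test_that("identify_language accepts English only when it ranks first", {
  res <- test_resources()
  en_doc <- as_extracted_doc(paste(
    "The committee met on a rainy afternoon to discuss the plans for the",
    "new library, and everyone agreed that the reading room should keep",
    "its old wooden shelves."))
  lid <- identify_language(en_doc, res$profiles)
  expect_true(lid$is_english)
  expect_identical(lid$language, "en")

  # the French training text ranks fr first (self-match minimizes distance)
  fr_text <- paste(readLines(file.path(default_config()$resources$profiles_dir,
                                       "fr.txt"), encoding = "UTF-8"),
                   collapse = " ")
  lid_fr <- identify_language(as_extracted_doc(fr_text), res$profiles)
  expect_identical(lid_fr$language, "fr")
  expect_false(lid_fr$is_english)

  # short or empty documents are unknown, treated as non-English
  expect_identical(identify_language(as_extracted_doc(""), res$profiles)$language,
                   "unknown")
  short <- as_extracted_doc("only five words right here")
  expect_false(identify_language(short, res$profiles)$is_english)
})

test_that("identify_language agrees with the brute-force out-of-place oracle", {
  res <- test_resources()
  langs <- c("en", "fr", "es", "de")
  texts <- lapply(langs, function(code) {
    paste(readLines(file.path(default_config()$resources$profiles_dir,
                              paste0(code, ".txt")), encoding = "UTF-8"),
          collapse = " ")
  })
  words <- lapply(texts, function(t) segment(t)$tokens)
  set.seed(404)
  for (k in 1:25) {
    src <- sample(4, 1)
    n <- sample(10:50, 1)
    doc <- as_extracted_doc(paste(sample(words[[src]], n, replace = TRUE),
                                  collapse = " "))
    got <- identify_language(doc, res$profiles)
    want <- oracle_language(doc, res$profiles)
    expect_identical(got$language, want$language)
    expect_identical(got$is_english, want$is_english)
  }
})

test_that("publishable-content keywords are only found in the 200-token prefix", {
  res <- test_resources()
  pad <- function(n) paste(rep("word", n), collapse = " ")

  doc <- as_extracted_doc("Complete text includes ISBN and index pages.")
  hit <- detect_publishable_content(doc, res$keywords)
  expect_identical(hit$category, "Books")
  expect_identical(hit$term, "isbn")

  doc2 <- as_extracted_doc(paste(pad(149), "thesis", pad(30)))
  hit2 <- detect_publishable_content(doc2, res$keywords)
  expect_identical(hit2$category, "Education")

  doc3 <- as_extracted_doc(paste(pad(249), "thesis"))
  expect_null(detect_publishable_content(doc3, res$keywords))

  # simple plural variants match the singular entry
  doc4 <- as_extracted_doc("Back issues of the magazines are archived.")
  expect_identical(detect_publishable_content(doc4, res$keywords)$category,
                   "Periodical")

  # multiword celebrity/retail terms match case-insensitively
  doc5 <- as_extracted_doc("A tribute to Bart Simpson episodes of note.")
  expect_identical(detect_publishable_content(doc5, res$keywords)$category,
                   "Fictional")
})
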