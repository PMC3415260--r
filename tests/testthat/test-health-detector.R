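test_that("lexicon preprocessing lowercases, strips punctuation/digits, drops stop words", {
  lex <- build_health_lexicon(data.frame(
    term = c("Arthritis, rheumatoid (ICD)", "Vitamin B-12", "of",
             "Shortness of Breath", "chest pain", "chest pain"),
    category = c("disease", "drug_generic", "symptom", "symptom",
                 "symptom", "condition"),
    stringsAsFactors = FALSE
  ))
  terms <- lex$terms
  expect_identical(unname(terms["arthritis rheumatoid icd"]), "disease")
  expect_identical(unname(terms["vitamin b"]), "drug_generic")
  expect_false("of" %in% names(terms))                 # pure stop word dropped
  expect_identical(unname(terms["shortness breath"]), "symptom")
  expect_identical(unname(terms["chest pain"]), "symptom")  # first category wins
  expect_true(all(!grepl("[^a-z ]", names(terms))))

  expect_error(build_health_lexicon(list()), "no lexicon sources")

  # idempotence: rebuilding from the processed terms changes nothing
  again <- build_health_lexicon(data.frame(term = names(terms),
                                           category = unname(terms)))
  expect_identical(again$terms, terms)
})

test_that("health terms match whole words, longest first", {
  res <- test_resources()
  lex <- res$health_lexicon

  m <- detect_health_terms(as_extracted_doc("diagnosed with mumps last week"), lex)
  expect_identical(m$term, "mumps")
  expect_identical(m$category, "disease")

  m2 <- detect_health_terms(as_extracted_doc("admitted to the ICU overnight"), lex)
  expect_identical(m2$term, "icu")
  expect_identical(m2$category, "acronym")

  expect_identical(
    nrow(detect_health_terms(as_extracted_doc("painting the fence all day"), lex)),
    0L)

  # longest match suppresses the overlapped shorter one
  lex2 <- build_health_lexicon(data.frame(
    term = c("chest pain", "pain"), category = c("symptom", "symptom")))
  m3 <- detect_health_terms(as_extracted_doc("sudden chest pain at night"), lex2)
  expect_identical(m3$term, "chest pain")

  # normalization bridges punctuation and stop words in the document
  m4 <- detect_health_terms(
    as_extracted_doc("reported shortness of breath while walking"), lex)
  expect_true("shortness breath" %in% m4$term)
})

test_that("health matching agrees with the brute-force substring oracle", {
  res <- test_resources()
  set.seed(31)
  for (k in 1:60) {
    doc <- random_doc(100)
    got <- detect_health_terms(doc, res$health_lexicon)
    want <- oracle_health(doc, res$health_lexicon)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("PHI requires both the PII flag and a health term", {
  geo_first_last <- data.frame(
    category = c("geographic", "person", "person"),
    subcategory = c("place", "first_name", "last_name"),
    start = 0:2, end = 1:3, text = c("Toronto", "John", "Smith"),
    stringsAsFactors = FALSE)
  pii_yes <- evaluate_pii_rule(geo_first_last)
  pii_no <- evaluate_pii_rule(geo_first_last[1, ])
  one_term <- data.frame(term = "arthritis", category = "disease",
                         start = 5L, end = 6L, stringsAsFactors = FALSE)
  none <- one_term[0, ]

  expect_true(evaluate_phi(pii_yes, one_term, 1L)$phi_flag)
  expect_false(evaluate_phi(pii_no, rbind(one_term, one_term), 1L)$phi_flag)
  expect_false(evaluate_phi(pii_yes, none, 1L)$phi_flag)

  # threshold counts distinct terms
  two <- rbind(one_term,
               data.frame(term = "insulin", category = "drug_generic",
                          start = 9L, end = 10L))
  expect_false(evaluate_phi(pii_yes, one_term, 2L)$phi_flag)
  expect_true(evaluate_phi(pii_yes, two, 2L)$phi_flag)
})
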