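test_that("trigger patterns harvest adjacent capitalized tokens only", {
  res <- test_resources()

  expect_identical(
    harvest_candidate_names(as_extracted_doc("my daughter Emily went home"),
                            res$triggers),
    "Emily")
  expect_identical(
    harvest_candidate_names(as_extracted_doc("Sincerely, John Smith"),
                            res$triggers),
    c("John", "Smith"))
  # life-event triggers capture on the preceding side
  expect_identical(
    harvest_candidate_names(as_extracted_doc("Anna Petrov was born in winter"),
                            res$triggers),
    c("Anna", "Petrov"))
  expect_identical(
    harvest_candidate_names(as_extracted_doc("nothing to see in this text"),
                            res$triggers),
    character(0))

  # capture window: at most two tokens, stopping at the first lowercase one
  got <- harvest_candidate_names(
    as_extracted_doc("my daughter Mary Ann Louise stayed"), res$triggers)
  expect_identical(got, c("Mary", "Ann"))

  # property: harvested candidates are always capitalized document tokens
  set.seed(21)
  for (k in 1:20) {
    doc <- random_doc(60)
    cand <- harvest_candidate_names(doc, res$triggers)
    cores <- phitriage:::token_core(doc$tokens)
    caps <- cores[phitriage:::is_capitalized(cores)]
    expect_true(all(cand %in% caps))
  }
})

test_that("person names require capitalization and list membership", {
  res <- test_resources()
  lex <- res$name_lexicon

  m <- detect_person_names(as_extracted_doc("Please ask William about it"), lex)
  expect_identical(m$subcategory, "first_name")
  expect_identical(m$text, "William")

  # common misspellings ship with the lexicon
  m2 <- detect_person_names(as_extracted_doc("signed by Bll yesterday"), lex)
  expect_identical(m2$subcategory, "first_name")

  # lowercase occurrences are never candidates
  expect_identical(
    nrow(detect_person_names(as_extracted_doc("ask william about it"), lex)), 0L)

  # file name list accepts tokens missing from the lexicon
  m3 <- detect_person_names(as_extracted_doc("call Zyxzy tomorrow"), lex,
                            names = "Zyxzy")
  expect_identical(m3$subcategory, "relation_name")

  # sentence-initial capitalized non-names do not match
  expect_identical(
    nrow(detect_person_names(as_extracted_doc("Yesterday it rained. Today too."),
                             lex)), 0L)
})

test_that("structured identifiers follow the worked examples", {
  date_subs <- function(text) {
    m <- detect_structured_ids(as_extracted_doc(text))
    m$subcategory
  }
  expect_true("date" %in% date_subs("We met on March 9th, 1999 in the park"))
  expect_false("date" %in% date_subs("March was chilly this year"))
  # 20th/21st century restriction
  expect_false("date" %in% date_subs("He wrote this March 9th, 1899 at home"))
  expect_true("date" %in% date_subs("delivered 12/31/1999 by post"))

  m <- detect_structured_ids(as_extracted_doc("write to john AT Canada DOT ca now"))
  expect_identical(m$subcategory, "email")
  expect_identical(m$text, "john AT Canada DOT ca")
  expect_true("email" %in% date_subs("send it to john@canada.ca please"))

  expect_true("phone" %in% date_subs("call (613) 555-1234 today"))
  expect_true("phone" %in% date_subs("the incomplete 555-1234 also counts"))
  expect_true("health_insurance" %in% date_subs("card 4321-987-654 on file"))

  pc <- detect_structured_ids(as_extracted_doc("mail to K1A 0B1 or 90210"))
  expect_identical(sort(pc$subcategory), c("postal_code", "postal_code"))
  expect_identical(unique(pc$category), "geographic")
})

test_that("structured detection agrees with the per-offset brute-force oracle", {
  set.seed(77)
  for (k in 1:60) {
    doc <- random_doc(100)
    got <- detect_structured_ids(doc)
    want <- oracle_structured(doc)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("match spans stay in bounds and cover the matched text", {
  set.seed(99)
  for (k in 1:25) {
    doc <- random_doc(80)
    m <- detect_structured_ids(doc)
    if (nrow(m) == 0) next
    expect_true(all(m$start >= 0 & m$end <= length(doc$tokens) & m$start < m$end))
    for (i in seq_len(nrow(m))) {
      window <- paste(doc$tokens[(m$start[i] + 1):m$end[i]], collapse = " ")
      expect_true(grepl(m$text[i], window, fixed = TRUE))
    }
  }
})

test_that("gazetteer matching is case-sensitive, whole-phrase, longest-first", {
  res <- test_resources()
  gaz <- res$gazetteer

  m <- detect_geographic(as_extracted_doc("We hiked near Banff last fall"), gaz)
  expect_identical(m$subcategory, "place")
  expect_identical(m$tier, "ca_place")

  m2 <- detect_geographic(as_extracted_doc("Moved from Springfield years ago"), gaz)
  expect_identical(m2$tier, "us_place")

  expect_identical(
    nrow(detect_geographic(as_extracted_doc("we ate turkey dinner at six"), gaz)),
    0L)

  # multiword entries win over their single-word suffixes
  m3 <- detect_geographic(as_extracted_doc("Flights to New York leave hourly"), gaz)
  expect_identical(m3$text, "New York")
  expect_identical(nrow(m3), 1L)

  m4 <- detect_geographic(as_extracted_doc("Paris and France both matched"), gaz)
  expect_identical(m4$subcategory, c("country", "country"))
})

test_that("organizations need an org type near a pattern or population term", {
  res <- test_resources()
  org <- res$org_patterns

  m <- detect_organizations(
    as_extracted_doc("she lived in St. Mary's foster home for a year"), org)
  expect_identical(m$subcategory, "organization")
  expect_identical(m$category, "geographic")

  expect_identical(
    nrow(detect_organizations(as_extracted_doc("the school was closed"), org)),
    0L)

  m2 <- detect_organizations(
    as_extracted_doc("the seniors support center on the corner"), org)
  expect_identical(nrow(m2), 1L)

  # beyond the 10-token window there is no co-occurrence
  far <- paste("lived in", paste(rep("plain", 12), collapse = " "), "school")
  expect_identical(nrow(detect_organizations(as_extracted_doc(far), org)), 0L)
})

test_that("the PII rule needs one geographic plus two distinct identifiers", {
  mk <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r) {
      data.frame(category = r[1], subcategory = r[2], start = 0L, end = 1L,
                 text = r[3], stringsAsFactors = FALSE)
    }))
  }
  geo <- c("geographic", "place", "Toronto")
  first <- c("person", "first_name", "John")
  last <- c("person", "last_name", "Smith")
  date <- c("structured", "date", "March 9th, 1999")

  expect_true(evaluate_pii_rule(mk(geo, first, last))$pii_flag)
  expect_false(evaluate_pii_rule(mk(geo))$pii_flag)
  # geographic identifier is mandatory
  expect_false(evaluate_pii_rule(mk(first, date))$pii_flag)
  # repeated mentions of the same identifier count once
  expect_false(evaluate_pii_rule(mk(geo, first, first))$pii_flag)
  expect_true(evaluate_pii_rule(mk(geo, first, date))$pii_flag)

  # monotone: adding matches never flips TRUE to FALSE
  set.seed(5)
  pool <- list(geo, first, last, date,
               c("structured", "phone", "613-555-0000"),
               c("geographic", "postal_code", "K1A 0B1"))
  for (k in 1:30) {
    base <- mk(geo, first, last)
    extra <- pool[sample(length(pool), sample(3, 1))]
    expect_true(evaluate_pii_rule(do.call(mk, c(list(geo, first, last),
                                                extra)))$pii_flag)
    expect_true(evaluate_pii_rule(base)$pii_flag)
  }
})
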