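test_that("load_file records size, extension, and title", {
  dir <- withr::local_tempdir()

  empty <- write_fixture_file(dir, "empty.txt", "")
  f <- load_file(empty)
  expect_s3_class(f, "raw_file")
  expect_identical(f$size_kb, 0L)
  expect_identical(length(f$raw_bytes), 0L)

  onek <- write_fixture_file(dir, "onek.bin", raw = as.raw(rep(65L, 1024)))
  expect_identical(load_file(onek)$size_kb, 1L)
  over <- write_fixture_file(dir, "over.bin", raw = as.raw(rep(65L, 1025)))
  expect_identical(load_file(over)$size_kb, 2L)

  doc <- write_fixture_file(dir, "report.DOC", "x")
  f <- load_file(doc)
  expect_identical(f$extension, "doc")
  expect_identical(f$title, "report")

  expect_error(load_file(file.path(dir, "missing.txt")), "missing.txt")
})

test_that("extract_text strips markup and decodes plain text verbatim", {
  dir <- withr::local_tempdir()

  html <- load_file(write_fixture_file(dir, "a.html", "<html><b>hello</b></html>"))
  doc <- extract_text(html)
  expect_s3_class(doc, "extracted_doc")
  expect_identical(trimws(doc$text), "hello")

  txt <- "Plain text, kept exactly as written.\nSecond line."
  plain <- load_file(write_fixture_file(dir, "b.txt", txt))
  expect_identical(extract_text(plain)$text, txt)

  rtf <- load_file(write_fixture_file(
    dir, "c.rtf",
    "{\\rtf1\\ansi\\deff0 {\\fonttbl{\\f0 Arial;}} hello \\b bold\\b0 world\\par done}"
  ))
  out <- extract_text(rtf)
  expect_match(out$text, "hello")
  expect_match(out$text, "world")
  expect_false(grepl("fonttbl|Arial|rtf1", out$text))
})

test_that("non-text and failing inputs become text_extractor discards, never errors", {
  dir <- withr::local_tempdir()

  set.seed(11)
  mp3 <- load_file(write_fixture_file(
    dir, "song.mp3", raw = as.raw(sample(0:255, 1024, replace = TRUE))))
  d <- extract_text(mp3)
  expect_s3_class(d, "disposition")
  expect_identical(d$stage, "text_extractor")
  expect_identical(d$outcome, "discarded")

  # fuzz: random bytes under every registered extension never raise
  for (s in 1:15) {
    set.seed(s)
    ext <- sample(c("txt", "html", "xml", "rtf", "mp3"), 1)
    f <- load_file(write_fixture_file(
      dir, sprintf("fuzz%d.%s", s, ext),
      raw = as.raw(sample(0:255, sample(1:2048, 1), replace = TRUE))))
    expect_no_error(extract_text(f))
  }

  # an extractor that throws is converted to a discard
  reg <- c(default_extractors(), list(bad = function(raw) stop("boom")))
  f <- load_file(write_fixture_file(dir, "x.bad", "content"))
  d <- extract_text(f, registry = reg)
  expect_s3_class(d, "disposition")
  expect_match(d$reason, "boom")
})

test_that("extraction of extraction output is idempotent", {
  dir <- withr::local_tempdir()
  src <- "<html><p>One paragraph.</p><p>And another, with <i>markup</i>.</p></html>"
  first <- extract_text(load_file(write_fixture_file(dir, "p.html", src)))
  second <- extract_text(load_file(write_fixture_file(dir, "p.txt", first$text)))
  expect_identical(second$text, first$text)
})

test_that("segment splits tokens on whitespace and sentences on terminal punctuation", {
  expect_identical(segment("A b. C d!")$sentences, c("A b.", "C d!"))
  expect_identical(segment("no punctuation here")$sentences, "no punctuation here")
  expect_identical(segment("  a   b  ")$tokens, c("a", "b"))
  expect_identical(segment("")$tokens, character(0))
  expect_identical(segment("")$sentences, character(0))

  # 200-word prefix has exactly min(200, n) tokens
  for (n in c(3L, 200L, 450L)) {
    toks <- segment(paste(rep("w", n), collapse = " "))$tokens
    expect_identical(length(utils::head(toks, 200L)), min(200L, n))
  }
})
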