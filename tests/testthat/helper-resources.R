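# Shared resources, loaded once per test run.
test_resources <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_resources(default_config())
    cache
  }
})

write_fixture_file <- function(dir, name, content, raw = NULL) {
  path <- file.path(dir, name)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.null(raw)) {
    con <- file(path, open = "wb")
    writeBin(charToRaw(enc2utf8(content)), con)
    close(con)
  } else {
    writeBin(raw, path)
  }
  path
}
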