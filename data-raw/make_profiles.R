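# Builds the packaged language profiles (inst/extdata/lang/*.profile) from
# the bundled training paragraphs with the default parameters (n = 1..5,
# profile length 400). Run from the package root:
#   Rscript data-raw/make_profiles.R

pkgload::load_all(".", quiet = TRUE)

dir <- "inst/extdata/lang"
for (txt in list.files(dir, pattern = "\\.txt$", full.names = TRUE)) {
  code <- tools::file_path_sans_ext(basename(txt))
  text <- paste(readLines(txt, encoding = "UTF-8", warn = FALSE), collapse = " ")
  profile <- build_language_profile(text, code)
  write_language_profile(profile, file.path(dir, paste0(code, ".profile")))
  cat(code, length(profile$ranked_ngrams), "n-grams\n")
}
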