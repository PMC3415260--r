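---
title: "Detecting personal health information leaks in heterogeneous files"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting personal health information leaks in heterogeneous files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phitriage)
```

## The problem

A document leaks personal health information (PHI) when it both identifies
a unique individual and reveals specifics of that individual's health — a
diagnosis, a prescription, a procedure. "John Smith caught a cold" does
not qualify; a letter giving John Smith's town, date of birth, and his
medication does. Directories harvested from file-sharing networks (or any
bulk store of user files) are dominated by material that cannot leak PHI:
published books and music, duplicates, binary media, non-English text,
and assorted forms and homework. Reading everything deeply is infeasible,
so `phitriage` triages: cheap, shallow filters discard files *guaranteed*
not to contain PHI, and only the small remainder receives full lexical
analysis. The design preference throughout is recall over precision —
a discarded PHI file is the costly error, a flagged non-PHI file is merely
reviewer time.

## Shallow stages and their assumptions

**Duplicate removal** treats two files as copies when four parameters all
agree: size in whole kilobytes, normalized title (case-folded, whitespace
collapsed), and the first and last 256 raw bytes. This stage runs before
text extraction, so the fingerprints are taken on bytes, not sentences;
byte-level agreement on both ends plus size and title makes a false
duplicate collapse vanishingly unlikely while staying O(1) per file.

**Published-title lookup** assumes anything already published leaks
nothing. Matching is exact on the normalized title; fuzzy matching is
deliberately avoided because a near-miss ("discharge summary" vs a song
title) must not discard a personal document. Titles containing an
exemption word — *notification*, *affidavit*, *justice*, *discharge*,
*lab* — are always retained, since those words mark exactly the documents
most likely to be personal. The packaged title list is a small stand-in;
deployments should point `titles` in the configuration at a real
publication database export.

**Text extraction** recovers markup-free text from plain text, HTML/XML
(via `xml2`, scripts and styles removed), and RTF (a minimal control-word
parser). Encoding is detected byte-wise: valid UTF-8 is kept, anything
else falls back to Latin-1, so no file is undecodable — inputs are
processed as-is with no normalization. Corruption is defined
operationally: an extractor exception, or decoded output under 1%
printable characters, discards the file. Extraction is wrapped so that no
input bytes can crash a run; formats such as PDF or word-processor files
are supported by registering an extractor function for their extension.

**Language identification** is the classic character n-gram rank
classifier: n-grams (n = 1..5) of letter-only, underscore-padded words are
ranked by frequency (ties broken lexicographically for determinism) and
truncated to a 400-entry profile; a document is compared to each language
profile by the out-of-place distance, with a fixed penalty of 400 for
absent n-grams. A file survives only when English ranks strictly first.
Documents under 10 tokens are classified "unknown" and discarded: rank
distances on a handful of n-grams are noise, and a ten-token fragment
cannot satisfy the PII rule anyway. Profiles for en/fr/es/de are bundled,
built from the included training paragraphs; additional languages are a
profile file away.

**Publishable-content keywords** catch published material that title
lookup missed, by searching the first 200 words — where front matter
lives — for category terms (Books, Education, Retail, Periodical,
Fictional, Politics) as whole words, case-insensitively, with simple
singular/plural variants. The fictional/celebrity/politician names fold
into the Fictional and Politics categories on the theory that public
figures' health is already public; the shipped lists are stand-ins and
user-replaceable.

## The PII detector

Person-name lookup against large name lists is the expensive step, so the
document is first scanned for trigger patterns — family relations ("my
daughter"), self-identification ("my name is", "sincerely"), life events
("was born") — and up to two capitalized tokens on the declared side of
each trigger are harvested into the file's name list. Harvested tokens
are accepted as person names regardless of the lexicon (they are, after
all, introduced as people); other capitalized tokens must appear in the
female-first, male-first, or last-name lists. Only capitalized tokens are
candidates, which is what makes sentence-initial ordinary words safe. The
capture window of two covers "First Last" after a closing "Sincerely,"
without runaway capture.

Structured identifiers use deliberately permissive regular expressions
over the space-joined token stream: North American phone numbers in
complete and incomplete forms; provincial health-card numbers
(configurable per-province patterns — Ontario-style 10 digits with
optional version code, Quebec-style four letters + eight digits, BC-style
personal health numbers); dates, which must be *specific* (a day is
required — "March 9th, 1999" matches, "March was chilly" does not) and
are restricted to 1900–2099 since earlier dates cannot concern a living
patient; emails including obfuscated `john AT Canada DOT ca` forms; and
Canadian postal / US ZIP codes. Matches contained inside a longer match
are suppressed. Postal codes are categorized as geographic (they locate a
person); phone numbers stay structured — each identifier is counted in
exactly one category to avoid double-counting under the decision rule.

Geographic matching is case-sensitive whole-phrase gazetteer lookup,
longest match first, across four granularity tiers: countries and
capitals, US state/capital/largest-city, Canadian
province/capital/largest-cities/tourist-attractions, and major world
cities. Case sensitivity is what keeps "turkey dinner" from matching
Turkey. Organization mentions (schools, churches, care homes, support
centers …) are reported only when an organization type co-occurs within
ten tokens of a residence pattern ("lived in") or a target population
("seniors"), and count as geographic identifiers.

**The decision rule:** a file carries PII iff it contains at least one
geographic identifier and at least two other personal identifiers. "Two
other" counts distinct (subcategory, text) pairs from the person and
structured categories, so a name mentioned five times is one identifier,
while a first name + last name, or a first name + birth date, qualify.
Whether the two identifiers must come from different subcategories is
genuinely open; counting distinct pairs (two different first names count)
is the recall-preserving reading and the one implemented.

## The health detector

Term lists for diseases, symptoms, procedures, generic and trade drug
names, acronyms (ICU, MRI), provider specialties (therapist, surgeon),
and condition phrases (blood pressure, tube fed) are preprocessed into a
single lexicon: lowercased, punctuation and digits removed, stop words
(a fixed packaged list of ~120 function words) eliminated, first category
kept for duplicates. Documents are normalized identically and scanned
longest-match-first, so "chest pain" suppresses "pain" and substrings
never match ("painting" is not "pain"). The packaged lists are small
stand-ins for full ICD/MedDRA/drug-database extracts, with animal
diseases and drugs excluded; the `lexicon-build` CLI rebuilds the lexicon
from any `term<TAB>category` file.

A file is flagged as PHI when the PII rule holds **and** at least
`min_health_terms` distinct lexicon terms occur. The default is 1: the
threshold is not fixed by any published criterion, recall is the
priority, and raising it is the user's lever against pseudo-PHI noise.
Pseudo-PHI — blank insurance forms, medical CVs, student essays that
contain both PII and health terms yet disclose nothing private — is *not*
separated algorithmically: the flagged-file report carries every match
span as evidence precisely so that a human reviewer can make that call.
Negation and context analysis are out of scope.

## Auditing the discards

The false-negative question — did the pipeline throw away PHI? — is
answered by sampling. Modelling each discarded file as containing PHI
independently with probability θ, the chance that a sample of n files
contains at least one PHI file is P = 1 − (1 − θ)ⁿ; inverting gives the
minimal n = ⌈log(1 − P)/log(1 − θ)⌉. At θ = 0.01 (the rate prior studies
of shared files suggest) and P = 0.95 this is 299 files — commonly
rounded up to 300, which `sample_size(round_up_to = 100)` reproduces
while the default returns the exact minimum. Discards are stratified
into three groups mirroring the architecture — shallow discards (title,
extraction, language), content-filter discards, and deep discards (PII +
health) — and sampled without replacement, seeded, per stratum. The audit
is run with duplicate removal disabled (`disabled_stages =
"duplicate_removal"`) so that every distinct file reaches a substantive
stage. Sampling without replacement makes the binomial P a lower bound on
the actual detection probability.

```{r sampling}
sample_size(0.01, 0.95)
100 * detection_probability(300, 0.01)
```

## The synthetic corpus: what it shows and what it does not

`generate_corpus()` writes a seeded corpus across eight classes — true-PHI
letters (guardian and lawyer notes), pseudo-PHI (insurance claim forms,
medical CVs, childhood-hospital essays), published texts (title matches
and keyword-bearing front matter), non-English texts (sampled from the
bundled French/Spanish training paragraphs, guaranteeing the language
stage is the one that discards them), byte-identical duplicates (same
name, `zz/` subdirectory, so the original sorts first and is retained),
binary junk under media extensions, benign-personal letters (full PII, no
health terms), and health-only information sheets (health terms, at most
one non-geographic identifier). Slot values are drawn only from the
packaged lexicons and gazetteers, filtered so that a value can trigger
only the detector it is meant for; every file's intended terminal stage
is therefore decidable at generation time and recorded in the manifest.

The default specification (520 files, mostly benign) is the corpus the
acceptance tests run: the pipeline must reproduce the manifest for 100%
of files — in particular, zero true-PHI files discarded and zero
benign/health-only files flagged. This mirrors, by construction, the
zero-false-negative outcome a manual audit of a real deployment is meant
to confirm; it demonstrates the *machinery* (stage ordering, rule logic,
conservation, determinism), not performance on real-world text, whose
spelling noise, OCR artifacts, name/word ambiguity, and adversarial
formats the generator deliberately does not model. Real-data recall
depends on resource coverage (names, places, terms), which is exactly
what the substitution hooks are for.

Numerical and tie-break choices, for the record: n-gram ties are broken
lexicographically in byte order; language ranking ties break
alphabetically by language code; equal-span structured matches keep the
highest-precedence subcategory (phone, health-card, date, email, postal);
duplicate groups retain the lexicographically smallest path; files are
processed in sorted path order, making reports byte-identical across runs
(timings aside). Problem sizes used by the test suite — a 520-file
corpus, 200 random documents per oracle-equivalence check, 200 seeded
repetitions of the 300-of-1000 sampling experiment — were chosen to make
the checks statistically meaningful at desk scale.

## Known limitations

Detection is English-only; coreference resolution and person-vs-place
disambiguation beyond list membership are not attempted; the packaged
resources are intentionally small stand-ins; pseudo-PHI separation is
manual by design. The per-stage timings in every report echo the
efficiency concern that motivates the shallow-first architecture but are
hardware-dependent and never asserted.
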