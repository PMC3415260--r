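# phitriage

Staged triage of heterogeneous files for personal health information (PHI)
leaks.

People who share folders on peer-to-peer networks (or any shared storage)
sometimes expose documents that both identify an individual and reveal
specifics of that individual's health — a letter naming a child, her date of
birth, her diagnosis and prescription. `phitriage` is for privacy teams and
researchers who need to scan large directories of files of unknown type and
surface exactly those documents, while discarding the overwhelming majority
of files that cannot leak PHI, cheaply and early.

## The pipeline

Files pass through seven stages; each stage either discards a file with a
recorded reason or hands it on:

1. **Duplicate removal** — files agreeing on size (KB), normalized title,
   and fingerprints of their first and last 256 bytes are collapsed to one
   representative.
2. **Published-title filter** — exact (case-folded) title match against a
   publication-title database discards already-public content, unless the
   title contains an exemption word (*notification*, *affidavit*, *justice*,
   *discharge*, *lab*).
3. **Text extraction** — markup-free text is recovered from txt/HTML/XML/RTF
   (pluggable registry for other formats); non-text and corrupted files are
   discarded. Extraction never crashes on any input bytes.
4. **Language identification** — a character n-gram classifier
   (Cavnar–Trenkle out-of-place rank distance, n = 1..5, profile length 400)
   keeps a file only when English ranks first.
5. **Publishable-content filter** — case-insensitive keyword search (Books,
   Education, Retail, Periodical, Fictional, Politics) in the first 200
   words.
6. **PII detector** — person names (lexicon lookup accelerated by
   trigger-pattern harvesting of capitalized neighbours), structured
   identifiers via soft regular expressions (phones, provincial health-card
   numbers, specific dates restricted to 1900–2099, emails including
   obfuscated `AT`/`DOT` forms, postal/ZIP codes), gazetteer places, and
   organization mentions. A file carries PII iff it has **one geographic
   identifier and two other distinct personal identifiers**.
7. **Health detector** — a preprocessed medical-term lexicon (diseases,
   symptoms, procedures, drugs, acronyms, specialties, conditions) is
   matched longest-first over the normalized token stream. PII plus at least
   one distinct health term ⇒ the file is flagged as PHI.

The package also implements the binomial audit used to bound the
false-negative rate of the discards. With θ the assumed PHI rate and n the
sample size, the probability of catching at least one PHI file is

    P = 1 − (1 − θ)^n        (so n = ⌈ log(1 − P) / log(1 − θ) ⌉)

and `draw_stratified_sample()` draws seeded, reproducible per-stratum
samples of discarded files for manual review. A seeded corpus generator
(`generate_corpus()`) produces synthetic corpora — PHI letters, pseudo-PHI
forms/CVs/essays, published texts, non-English texts, duplicates, binary
junk — with a ground-truth manifest, so the whole pipeline is testable
without any real harvested data.

## Worked example

```r
library(phitriage)

dir <- tempfile()
manifest <- generate_corpus(corpus_spec(seed = 5), dir)  # 520 files
report <- run_pipeline(dir)
report
#> <scan_report> 520 files from /tmp/.../corpus
#>              stage n_in n_discarded enabled
#>  duplicate_removal  520          40    TRUE
#>       title_filter  480          40    TRUE
#>     text_extractor  440          40    TRUE
#>        language_id  400          80    TRUE
#>     content_filter  320          40    TRUE
#>       pii_detector  280         100    TRUE
#>    health_detector  180         100    TRUE
#> phi_flagged: 80, retained: 0
```

Each row chains into the next (480 = 520 − 40, …) and the 80 flagged files
are exactly the generator's 40 true-PHI letters plus 40 pseudo-PHI
forms/CVs/essays — documents that genuinely contain both PII and health
terms; separating pseudo-PHI from true PHI is a manual review step, and the
report retains every PII and health match span as evidence to support it.
Auditing the discards:

```r
sample_size(theta = 0.01, power = 0.95)
#> [1] 299
100 * detection_probability(300, 0.01)
#> [1] 95.0959
plan <- sampling_plan(theta = 0.01, power = 0.95, seed = 7)
samples <- draw_stratified_sample(report, plan)
lengths(samples)
#> shallow content    deep
#>     160      40     200
```

(Strata smaller than the 299-file target are sampled exhaustively.)

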