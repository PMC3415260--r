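# Pipeline orchestration: seven stages applied in fixed order, one terminal
# disposition per file, per-stage counts, and report serialization.

PIPELINE_STAGES <- c(
  "duplicate_removal", "title_filter", "text_extractor", "language_id",
  "content_filter", "pii_detector", "health_detector"
)

#' Run the triage pipeline on a directory
#'
#' Applies the seven stages in order -- duplicate removal, published-title
#' filter, text extraction, language identification, publishable-content
#' filter, PII detection, health-term detection -- to every file under
#' `input_dir` (recursively, in sorted path order). Every file receives
#' exactly one terminal disposition: discarded at some stage, flagged as
#' PHI, or retained (only possible when late stages are disabled).
#' Per-file failures never abort the run.
#'
#' @param input_dir Directory of input files.
#' @param config A `phitriage_config`; stages named in
#'   `config$disabled_stages` are skipped, passing their files through.
#' @param resources Optional pre-loaded resource list (from
#'   [load_resources()]); loaded from `config` when `NULL`.
#' @return A `scan_report`: `per_file` data frame (path, stage, outcome,
#'   reason), `evidence` (PII and health matches for flagged files),
#'   `stage_counts` (input and discarded counts per stage), `config_echo`,
#'   and per-stage `timings` in seconds.
#' @export
run_pipeline <- function(input_dir, config = default_config(), resources = NULL) {
  if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
  if (is.null(resources)) resources <- load_resources(config)
  cfg <- resources$config
  enabled <- !(PIPELINE_STAGES %in% cfg$disabled_stages)
  names(enabled) <- PIPELINE_STAGES

  rel <- sort(list.files(input_dir, recursive = TRUE, all.files = FALSE),
              method = "radix")
  n <- length(rel)
  files <- lapply(file.path(input_dir, rel), load_file)
  state <- list(
    disposition = rep(list(NULL), n),
    doc = rep(list(NULL), n),
    evidence = rep(list(NULL), n)
  )
  active <- seq_len(n)
  counts <- data.frame(stage = PIPELINE_STAGES, n_in = 0L, n_discarded = 0L,
                       enabled = unname(enabled), stringsAsFactors = FALSE)
  timings <- stats::setNames(numeric(length(PIPELINE_STAGES)), PIPELINE_STAGES)
  n_range <- cfg$ngram_min:cfg$ngram_max
  # lazy extraction so that disabling the extractor stage only shifts work
  ensure_doc <- function(i) {
    if (!is.null(state$doc[[i]])) return(state$doc[[i]])
    out <- extract_text(files[[i]])
    if (is_disposition(out)) return(NULL)
    state$doc[[i]] <<- out
    out
  }

  for (stage in PIPELINE_STAGES) {
    counts$n_in[counts$stage == stage] <- length(active)
    if (!enabled[[stage]] || length(active) == 0L) next
    t0 <- proc.time()[["elapsed"]]
    dropped <- integer(0)

    if (stage == "duplicate_removal") {
      res <- remove_duplicates(files[active])
      for (p in names(res$dispositions)) {
        i <- active[match(p, vapply(files[active], `[[`, "", "path"))]
        state$disposition[[i]] <- res$dispositions[[p]]
        dropped <- c(dropped, i)
      }
    } else if (stage == "title_filter") {
      for (i in active) {
        if (!filter_published_title(files[[i]], resources$title_db)) {
          state$disposition[[i]] <- disposition(
            "title_filter", "discarded",
            sprintf("published title '%s'", files[[i]]$title))
          dropped <- c(dropped, i)
        }
      }
    } else if (stage == "text_extractor") {
      for (i in active) {
        out <- extract_text(files[[i]])
        if (is_disposition(out)) {
          state$disposition[[i]] <- out
          dropped <- c(dropped, i)
        } else {
          state$doc[[i]] <- out
        }
      }
    } else if (stage == "language_id") {
      for (i in active) {
        doc <- ensure_doc(i)
        if (is.null(doc)) {
          # extractor disabled upstream: treat unextractable input as unknown
          state$disposition[[i]] <- disposition(
            "language_id", "discarded", "language unknown (no text)")
          dropped <- c(dropped, i)
          next
        }
        lid <- identify_language(doc, resources$profiles, n_range = n_range,
                                 profile_length = cfg$profile_length,
                                 min_tokens = cfg$min_tokens_language)
        if (!lid$is_english) {
          state$disposition[[i]] <- disposition(
            "language_id", "discarded",
            sprintf("most likely language: %s", lid$language))
          dropped <- c(dropped, i)
        }
      }
    } else if (stage == "content_filter") {
      for (i in active) {
        doc <- ensure_doc(i)
        if (is.null(doc)) next
        hit <- detect_publishable_content(doc, resources$keywords, cfg$prefix_len)
        if (!is.null(hit)) {
          state$disposition[[i]] <- disposition(
            "content_filter", "discarded",
            sprintf("publishable content: %s ('%s')", hit$category, hit$term))
          dropped <- c(dropped, i)
        }
      }
    } else if (stage == "pii_detector") {
      for (i in active) {
        doc <- ensure_doc(i)
        if (is.null(doc)) next
        pii <- tryCatch(run_pii_detector(doc, resources), error = function(e) e)
        if (inherits(pii, "error")) {
          state$disposition[[i]] <- disposition(
            "pii_detector", "discarded",
            sprintf("detector failure: %s", conditionMessage(pii)))
          dropped <- c(dropped, i)
          next
        }
        state$evidence[[i]] <- list(pii = pii)
        if (!pii$pii_flag) {
          state$disposition[[i]] <- disposition(
            "pii_detector", "discarded",
            sprintf("insufficient PII (%d geographic, %d identifiers)",
                    pii$n_geographic, pii$n_identifiers))
          dropped <- c(dropped, i)
        }
      }
    } else if (stage == "health_detector") {
      for (i in active) {
        doc <- ensure_doc(i)
        if (is.null(doc)) next
        pii <- state$evidence[[i]]$pii %||% run_pii_detector(doc, resources)
        health <- detect_health_terms(doc, resources$health_lexicon)
        phi <- evaluate_phi(pii, health, cfg$min_health_terms)
        state$evidence[[i]]$health <- health
        if (phi$phi_flag) {
          state$disposition[[i]] <- disposition(
            "health_detector", "phi_flagged",
            sprintf("PII plus %d distinct health term(s)", phi$n_health_terms))
        } else {
          state$disposition[[i]] <- disposition(
            "health_detector", "discarded",
            "PII present but no qualifying health terms")
          dropped <- c(dropped, i)
          state$evidence[i] <- list(NULL)   # discarded files keep no evidence
        }
      }
      # flagged files leave the active set as terminal outcomes
      active <- setdiff(active, which(!vapply(state$disposition, is.null, TRUE)))
    }

    counts$n_discarded[counts$stage == stage] <- length(dropped)
    active <- setdiff(active, dropped)
    timings[[stage]] <- proc.time()[["elapsed"]] - t0
  }

  # survivors with no terminal disposition (late stages disabled) are retained
  for (i in active) {
    if (is.null(state$disposition[[i]])) {
      state$disposition[[i]] <- disposition("end", "retained", "survived all stages")
    }
  }

  per_file <- data.frame(
    path = rel,
    stage = vapply(state$disposition, `[[`, "", "stage"),
    outcome = vapply(state$disposition, `[[`, "", "outcome"),
    reason = vapply(state$disposition, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  flagged <- per_file$path[per_file$outcome == "phi_flagged"]
  evidence <- stats::setNames(lapply(which(per_file$outcome == "phi_flagged"),
                                     function(i) {
                                       list(pii = state$evidence[[i]]$pii$matches,
                                            health = state$evidence[[i]]$health)
                                     }), flagged)

  structure(
    list(
      input_dir = input_dir,
      n_files = n,
      per_file = per_file,
      evidence = evidence,
      stage_counts = counts,
      config_echo = unclass(cfg),
      timings = as.list(timings)
    ),
    class = "scan_report"
  )
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %d files from %s\n", x$n_files, x$input_dir))
  print(x$stage_counts[, c("stage", "n_in", "n_discarded", "enabled")],
        row.names = FALSE)
  cat(sprintf("phi_flagged: %d, retained: %d\n",
              sum(x$per_file$outcome == "phi_flagged"),
              sum(x$per_file$outcome == "retained")))
  invisible(x)
}

# ---- serialization -----------------------------------------------------------

report_to_list <- function(report) {
  ev <- lapply(names(report$evidence), function(p) {
    e <- report$evidence[[p]]
    list(path = p, pii = e$pii, health = e$health)
  })
  list(
    input_dir = report$input_dir,
    n_files = report$n_files,
    per_file = report$per_file,
    evidence = ev,
    stage_counts = report$stage_counts,
    config_echo = report$config_echo,
    timings = report$timings
  )
}

#' Write / read a scan report
#'
#' JSON reports are schema-stable and round-trip through [read_report()];
#' two runs over the same input and configuration produce byte-identical
#' JSON apart from the `timings` entry. CSV reports have one row per file
#' with stage, outcome, reason, and an evidence summary
#' (`subcategory:text@start-end`, `;`-separated) for flagged files.
#'
#' @param report A `scan_report`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly; `read_report` returns a `scan_report`.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    json <- jsonlite::toJSON(report_to_list(report), dataframe = "rows",
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             null = "null")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(as.character(json)), con)
  } else {
    df <- report$per_file
    df$evidence <- vapply(df$path, function(p) {
      e <- report$evidence[[p]]
      if (is.null(e)) return("")
      spans <- rbind(
        if (nrow(e$pii)) data.frame(what = e$pii$subcategory, text = e$pii$text,
                                    start = e$pii$start, end = e$pii$end),
        if (nrow(e$health)) data.frame(what = e$health$category,
                                       text = e$health$term,
                                       start = e$health$start, end = e$health$end)
      )
      if (is.null(spans)) return("")
      paste(sprintf("%s:%s@%d-%d", spans$what, spans$text, spans$start, spans$end),
            collapse = ";")
    }, character(1))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  fix_df <- function(df, cols) {
    if (is.null(df) || length(df) == 0L) {
      df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                          cols), stringsAsFactors = FALSE)
    }
    df
  }
  ev <- list()
  if (length(x$evidence)) {
    for (i in seq_len(nrow(x$evidence))) {
      ev[[x$evidence$path[i]]] <- list(
        pii = as.data.frame(x$evidence$pii[[i]]),
        health = as.data.frame(x$evidence$health[[i]])
      )
    }
  }
  structure(
    list(
      input_dir = x$input_dir,
      n_files = x$n_files,
      per_file = fix_df(x$per_file, c("path", "stage", "outcome", "reason")),
      evidence = ev,
      stage_counts = x$stage_counts,
      config_echo = x$config_echo,
      timings = x$timings
    ),
    class = "scan_report"
  )
}
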