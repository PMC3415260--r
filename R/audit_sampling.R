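# Binomial detection-probability model and stratified audit sampling of
# discarded files, used to bound the pipeline's false-negative rate.

#' Probability of detecting at least one PHI file in a sample
#'
#' Under a binomial model -- each sampled file independently contains PHI
#' with probability `theta` -- the probability that a random sample of `n`
#' files contains at least one PHI file is `1 - (1 - theta)^n`.
#'
#' @param n Sample size (non-negative integer, vectorized).
#' @param theta Assumed PHI rate, in `[0, 1)`.
#' @return Detection probability in `[0, 1)`.
#' @examples
#' detection_probability(300, 0.01)
#' @export
detection_probability <- function(n, theta) {
  if (!is.numeric(theta) || any(theta < 0 | theta >= 1)) {
    stop("theta must lie in [0, 1)")
  }
  if (!is.numeric(n) || any(n < 0)) stop("n must be a non-negative sample size")
  1 - (1 - theta)^n
}

#' Minimal sample size for a target detection probability
#'
#' The smallest integer `n` with `detection_probability(n, theta) >= power`,
#' i.e. `ceiling(log(1 - power) / log(1 - theta))`, checked and corrected
#' for floating-point edge cases. For the audit's parameters (1% PHI rate,
#' 95% target) this is 299; audits typically round such sizes up to a
#' convenient figure, available via `round_up_to`.
#'
#' @param theta Assumed PHI rate, strictly between 0 and 1.
#' @param power Target detection probability, strictly between 0 and 1.
#' @param round_up_to Optional granularity: the minimal `n` is rounded up to
#'   the next multiple (e.g. `round_up_to = 100` turns 299 into 300).
#'   Default `NULL` returns the exact minimum.
#' @return Integer sample size.
#' @examples
#' sample_size(0.01, 0.95)
#' sample_size(0.01, 0.95, round_up_to = 100)
#' @export
sample_size <- function(theta, power, round_up_to = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("theta must lie strictly between 0 and 1")
  }
  if (!is.numeric(power) || length(power) != 1L || power <= 0 || power >= 1) {
    stop("power must lie strictly between 0 and 1")
  }
  n <- as.integer(ceiling(log(1 - power) / log(1 - theta)))
  while (n > 1L && detection_probability(n - 1L, theta) >= power) n <- n - 1L
  while (detection_probability(n, theta) < power) n <- n + 1L
  if (!is.null(round_up_to)) n <- as.integer(ceiling(n / round_up_to) * round_up_to)
  n
}

#' Default audit strata
#'
#' The discarded files fall into three audit groups mirroring the pipeline
#' architecture: shallow discards (title lookup, text extraction, language
#' identification), content-filter discards, and deep-analysis discards (PII
#' and health detectors). Duplicate-removal discards are excluded: the audit
#' is run with the duplicate filter disabled so every distinct file reaches
#' a substantive stage.
#'
#' @return Named list mapping stratum label to pipeline stage names.
#' @export
default_strata <- function() {
  list(
    shallow = c("title_filter", "text_extractor", "language_id"),
    content = "content_filter",
    deep = c("pii_detector", "health_detector")
  )
}

#' Build a sampling plan
#'
#' @param theta Assumed PHI rate (default 0.01).
#' @param power Target detection probability (default 0.95).
#' @param strata Named list mapping stratum label to stage names.
#' @param per_stratum_n Sample size per stratum; defaults to
#'   `sample_size(theta, power)`.
#' @param seed Integer RNG seed recorded in the plan and the manifest.
#' @return A `sampling_plan`.
#' @export
sampling_plan <- function(theta = 0.01, power = 0.95, strata = default_strata(),
                          per_stratum_n = NULL, seed = 1L) {
  n <- per_stratum_n %||% sample_size(theta, power)
  stopifnot(n >= 1L)
  structure(
    list(theta = theta, power = power, strata = strata,
         per_stratum_n = as.integer(n), seed = as.integer(seed)),
    class = "sampling_plan"
  )
}

#' Draw a stratified audit sample of discarded files
#'
#' For each stratum, samples `per_stratum_n` discarded file paths uniformly
#' without replacement (the whole stratum when it is smaller than the sample
#' size). Sampling is seeded and reproducible; sampled paths are returned
#' sorted, per stratum, ready for a manual-review manifest.
#'
#' @param report A `scan_report`, or a data frame with columns `path`,
#'   `stage`, `outcome` (as in `report$per_file`).
#' @param plan A `sampling_plan`.
#' @return Named list mapping stratum label to sorted sampled paths.
#' @export
draw_stratified_sample <- function(report, plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  per_file <- if (inherits(report, "scan_report")) report$per_file else report
  stopifnot(is.data.frame(per_file),
            all(c("path", "stage", "outcome") %in% names(per_file)))
  discarded <- per_file[per_file$outcome == "discarded", , drop = FALSE]
  known_stages <- unique(per_file$stage)
  out <- list()
  with_rng(plan$seed, {
    for (label in names(plan$strata)) {
      stages <- plan$strata[[label]]
      if (!any(stages %in% known_stages)) {
        stop(sprintf("stratum '%s' matches no report stage (%s)",
                     label, paste(stages, collapse = ", ")))
      }
      pool <- sort_c(discarded$path[discarded$stage %in% stages])
      n <- min(plan$per_stratum_n, length(pool))
      out[[label]] <- if (n == length(pool)) pool else sort_c(sample(pool, n))
    }
  })
  out
}

#' Write an audit-sample manifest
#'
#' CSV with columns `group`, `path`, plus a header comment is avoided for
#' machine readability; the plan's seed, theta, and power are echoed in
#' attribute columns of the first row of each group.
#'
#' @param samples Result of [draw_stratified_sample()].
#' @param plan The `sampling_plan` used.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_manifest <- function(samples, plan, path) {
  df <- do.call(rbind, lapply(names(samples), function(g) {
    if (length(samples[[g]]) == 0L) return(NULL)
    data.frame(group = g, path = samples[[g]], theta = plan$theta,
               power = plan$power, seed = plan$seed, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(group = character(), path = character(), theta = numeric(),
                     power = numeric(), seed = integer())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
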