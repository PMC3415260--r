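test_that("detection probability follows the binomial model", {
  expect_identical(detection_probability(0, 0), 0)
  expect_identical(detection_probability(500, 0), 0)
  expect_equal(detection_probability(1, 0.5), 0.5)
  # 1 - 0.99^300, evaluated directly
  expect_equal(round(detection_probability(300, 0.01), 4), 0.9510)
  expect_error(detection_probability(10, 1), "theta")
  expect_error(detection_probability(10, -0.1), "theta")
  expect_error(detection_probability(-1, 0.1), "sample size")

  # nondecreasing in n and theta
  n <- 0:400
  p <- detection_probability(n, 0.01)
  expect_true(all(diff(p) >= 0))
  th <- seq(0.001, 0.2, by = 0.001)
  expect_true(all(diff(detection_probability(100, th)) >= 0))
})

test_that("sample_size returns the minimal n, with optional rounding", {
  # brute-force oracle: increment n until the target is reached
  brute <- function(theta, power) {
    n <- 1L
    while (1 - (1 - theta)^n < power) n <- n + 1L
    n
  }
  expect_identical(sample_size(0.01, 0.95), 299L)
  expect_identical(brute(0.01, 0.95), 299L)
  expect_identical(sample_size(0.01, 0.95, round_up_to = 100), 300L)
  expect_identical(sample_size(0.5, 0.5), 1L)
  expect_gt(sample_size(0.005, 0.95), sample_size(0.01, 0.95))
  expect_error(sample_size(0, 0.95))
  expect_error(sample_size(0.01, 1))

  # minimality over a parameter grid
  for (theta in c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2)) {
    for (power in c(0.5, 0.8, 0.9, 0.95, 0.99)) {
      n <- sample_size(theta, power)
      expect_identical(n, brute(theta, power))
      expect_gte(detection_probability(n, theta), power)
      if (n > 1L) expect_lt(detection_probability(n - 1L, theta), power)
    }
  }
})

fake_per_file <- function(n_shallow = 20, n_content = 20, n_deep = 20) {
  data.frame(
    path = sprintf("f%04d.txt", seq_len(n_shallow + n_content + n_deep)),
    stage = rep(c("language_id", "content_filter", "pii_detector"),
                c(n_shallow, n_content, n_deep)),
    outcome = "discarded",
    stringsAsFactors = FALSE
  )
}

test_that("stratified samples are seeded, sorted, disjoint, and bounded", {
  pf <- fake_per_file()
  plan <- sampling_plan(per_stratum_n = 5L, seed = 9L)
  s1 <- draw_stratified_sample(pf, plan)
  s2 <- draw_stratified_sample(pf, plan)
  expect_identical(s1, s2)                       # same seed, same sample
  expect_named(s1, c("shallow", "content", "deep"))
  expect_true(all(lengths(s1) == 5L))
  expect_identical(length(unique(unlist(s1))), 15L)   # disjoint across strata
  for (g in names(s1)) expect_identical(s1[[g]], sort(s1[[g]]))

  # exhaustive sample: n >= stratum size returns the whole stratum sorted
  small <- fake_per_file(5, 5, 5)
  s3 <- draw_stratified_sample(small, sampling_plan(per_stratum_n = 50L, seed = 1L))
  expect_identical(s3$content, sort(small$path[small$stage == "content_filter"]))

  # unmatched stratum label errors with its name
  bad_plan <- sampling_plan(strata = list(ghost = "no_such_stage"),
                            per_stratum_n = 1L, seed = 1L)
  expect_error(draw_stratified_sample(pf, bad_plan), "ghost")
})

test_that("the default plan sizes strata from the binomial model", {
  plan <- sampling_plan(theta = 0.01, power = 0.95, seed = 3L)
  expect_identical(plan$per_stratum_n, 299L)
  expect_named(plan$strata, c("shallow", "content", "deep"))
})

test_that("sample manifests record group, path, and plan parameters", {
  pf <- fake_per_file(4, 4, 4)
  plan <- sampling_plan(per_stratum_n = 2L, seed = 11L)
  s <- draw_stratified_sample(pf, plan)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_manifest(s, plan, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(nrow(df), 6L)
  expect_identical(sort(unique(df$group)), c("content", "deep", "shallow"))
  expect_true(all(df$seed == 11L))
  expect_true(all(df$path %in% pf$path))
})
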