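test_that("default profile carries the published cohort margins", {
  p <- ami_profile()
  expect_equal(p$n, 607L)
  expect_equal(p$event_target, 204L)
  expect_equal(p$age_mean, 61.34)
  expect_equal(p$age_sd, 13.46)
  expect_equal(p$binary_props[["male"]], 0.697)
  expect_equal(p$binary_props[["qwave"]], 0.262)
  expect_equal(sum(p$intervention_props), 1.0)
})

test_that("profile validation rejects malformed inputs", {
  expect_error(cohort_profile(n = 0, age_mean = 60, age_sd = 10,
                              binary_props = c(a = 0.5), event_target = 1,
                              baseline_hazard = 0.1, censor_rate = 0.1))
  expect_error(cohort_profile(n = 10, age_mean = 60, age_sd = 10,
                              binary_props = c(a = 1.5), event_target = 3,
                              baseline_hazard = 0.1, censor_rate = 0.1),
               "\\[0, 1\\]")
  expect_error(cohort_profile(n = 10, age_mean = 60, age_sd = 10,
                              binary_props = c(a = 0.5),
                              intervention_props = c(x = 0.6, y = 0.6),
                              event_target = 3, baseline_hazard = 0.1,
                              censor_rate = 0.1),
               "sum to 1")
})

test_that("exact-count mode reproduces every categorical margin and the death count", {
  coh <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 7)
  expect_equal(nrow(coh), 607L)
  expect_equal(sum(coh$status), 204L)
  expect_equal(sum(coh$male), 423L)
  expect_equal(sum(coh$htn), 245L)
  expect_equal(sum(coh$lipid), 135L)
  expect_equal(sum(coh$ihd), 184L)
  expect_equal(sum(coh$dm), 150L)
  expect_equal(sum(coh$smoke), 216L)
  expect_equal(sum(coh$famhx), 63L)
  expect_equal(sum(coh$qwave), 159L)
  expect_equal(sum(coh$sk), 278L)
  expect_equal(as.vector(table(coh$intervention)), c(32L, 36L, 45L, 494L))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 11)
  b <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 11)
  d <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("generated cohorts respect the basic invariants", {
  for (seed in c(1, 2)) {
    coh <- generate_cohort(ami_profile(exact_counts = seed == 1), seed = seed)
    expect_true(all(coh$time > 0))
    expect_true(all(coh$status %in% c(0L, 1L)))
    expect_true(all(coh$age >= 25))
    expect_false(anyNA(coh))
  }
})

test_that("a log hazard ratio of log(2) yields an event-rate ratio of 2", {
  prof <- cohort_profile(
    n = 40000, age_mean = 60, age_sd = 10,
    binary_props = c(grp = 0.5), event_target = 20000,
    baseline_hazard = 0.05, log_hazard_ratios = c(grp = log(2)),
    censor_rate = 1e-9)
  coh <- generate_cohort(prof, seed = 5)
  expect_gt(mean(coh$status), 0.999)  # essentially uncensored
  # exponential MLE of the rate per group; ratio should be exp(beta) = 2
  r1 <- sum(coh$grp == 1) / sum(coh$time[coh$grp == 1])
  r0 <- sum(coh$grp == 0) / sum(coh$time[coh$grp == 0])
  expect_equal(r1 / r0, 2, tolerance = 0.05)
})

test_that("sampled-mode marginals approach the profile (law of large numbers)", {
  prof <- ami_profile()
  big <- cohort_profile(
    n = 20000, age_mean = prof$age_mean, age_sd = prof$age_sd,
    binary_props = prof$binary_props,
    intervention_props = prof$intervention_props,
    event_target = round(20000 * 204 / 607),
    baseline_hazard = prof$baseline_hazard,
    log_hazard_ratios = prof$log_hazard_ratios,
    censor_rate = prof$censor_rate)
  coh <- generate_cohort(big, seed = 2024)
  n <- nrow(coh)
  expect_equal(mean(coh$age), 61.34, tolerance = 3 * 13.46 / sqrt(n) / 61.34)
  for (nm in names(prof$binary_props)) {
    p <- prof$binary_props[[nm]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(coh[[nm]]) - p), 3 * se + 1e-12)
  }
  # death fraction tracks the calibrated target 204/607
  expect_equal(mean(coh$status), 204 / 607, tolerance = 0.02)
})

test_that("profiles load from YAML and JSON configs", {
  skip_if_not_installed("yaml")
  cfg <- list(n = 50, age_mean = 60, age_sd = 9,
              binary_props = list(a = 0.4, b = 0.2),
              intervention_props = list(x = 0.3, y = 0.7),
              event_target = 20, baseline_hazard = 0.05,
              log_hazard_ratios = list(age = 0.5, a = 1),
              censor_rate = 0.1, exact_counts = TRUE)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  p1 <- read_profile(yml)
  expect_s3_class(p1, "cohort_profile")
  expect_equal(p1$binary_props, c(a = 0.4, b = 0.2))
  expect_true(p1$exact_counts)

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE, digits = NA)
  p2 <- read_profile(jsn)
  expect_equal(p2$log_hazard_ratios, c(age = 0.5, a = 1))
  expect_equal(sum(generate_cohort(p2, seed = 1)$status), 20L)
  expect_error(read_profile("profile.txt"), "yaml")
})

test_that("cohorts round-trip through CSV", {
  coh <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.vector(table(back$intervention)),
               as.vector(table(coh$intervention)))
  expect_equal(back$time, coh$time, tolerance = 1e-12)
  expect_identical(back$status, coh$status)
  expect_identical(levels(back$intervention), levels(coh$intervention))
})
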