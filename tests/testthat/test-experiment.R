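test_that("the CV plan yields k*r exact partitions with balanced folds", {
  plan <- make_cv_plan(607, 10, 20, seed = 8)
  expect_equal(nrow(dplyr::distinct(plan, rep, fold)), 200L)
  for (rp in c(1, 20)) {
    f <- plan$fold[plan$rep == rp]
    expect_equal(length(f), 607L)            # every subject in one test fold
    expect_true(all(table(f) %in% c(60L, 61L)))
  }
  # leave-one-out limit
  loo <- make_cv_plan(10, 10, 1, seed = 3)
  expect_true(all(table(loo$fold) == 1L))
  expect_identical(make_cv_plan(20, 4, 2, seed = 5),
                   make_cv_plan(20, 4, 2, seed = 5))
  expect_error(make_cv_plan(5, 10, 1, seed = 1), "at least")
})

test_that("percent change follows the reduction/increase conventions", {
  expect_equal(percent_change(0.872, 0.634, "cindex"), 27)
  expect_equal(percent_change(0.753, 0.699, "cindex"), 7)
  expect_equal(percent_change(0.145, 0.166, "ibs"), 14)
  expect_equal(percent_change(0.5, 0.5, "cindex"), 0)
  expect_equal(percent_change(0.5, 0.5, "ibs"), 0)
  # sub-1% changes keep 2 significant digits
  expect_equal(percent_change(1000, 997.5, "cindex"), 0.25)
  expect_error(percent_change(0, 1, "cindex"), "Zero reference")
})

test_that("summaries report cell means, percentile CIs and percent change", {
  vals <- withr::with_seed(1, runif(200, 0.5, 0.9))
  rec <- tidyr::expand_grid(method = c("ST", "PT", "RSF"),
                            set = c("train", "test")) |>
    tidyr::expand_grid(replicate = 1:200) |>
    dplyr::mutate(cindex = rep(vals, 6), ibs = rep(vals / 4, 6))
  sm <- summarize_records(rec)
  expect_equal(nrow(sm$cells), 12L)  # 3 methods x 2 sets per metric
  cell <- sm$cells[sm$cells$method == "ST" & sm$cells$set == "train" &
                     sm$cells$metric == "cindex", ]
  # order-statistic oracle with linear interpolation: percentile 2.5 of 200
  # values sits between the 5th and 6th order statistics
  s <- sort(vals)
  expect_equal(cell$lower, s[5] + 0.975 * (s[6] - s[5]), tolerance = 1e-12)
  expect_equal(cell$upper, s[195] + 0.025 * (s[196] - s[195]),
               tolerance = 1e-12)
  expect_equal(cell$mean, mean(vals))
  expect_true(all(sm$cells$lower <= sm$cells$mean + 1e-12 &
                    sm$cells$mean <= sm$cells$upper + 1e-12))

  # degenerate distribution: CI collapses onto the mean
  rec2 <- make_records(list(`ST train` = 0.8, `ST test` = 0.6,
                            `PT train` = 0.7, `PT test` = 0.65,
                            `RSF train` = 0.7, `RSF test` = 0.7),
                       spread = 0)
  sm2 <- summarize_records(rec2)
  st <- sm2$cells[sm2$cells$method == "ST" & sm2$cells$metric == "cindex", ]
  expect_equal(st$lower, st$mean)
  expect_equal(st$upper, st$mean)
  pc <- sm2$percent_change
  expect_equal(pc$percent[pc$method == "ST" & pc$metric == "cindex"],
               percent_change(0.8, 0.6, "cindex"))
  expect_error(summarize_records(rec2[rec2$replicate == 1, ]),
               "fewer than 2")
})

test_that("the two-way ANOVA reproduces constructed cell means exactly", {
  # null configuration: identical cells -> all non-intercept terms 0
  rec0 <- make_records(list(`ST train` = 0.7, `ST test` = 0.7,
                            `PT train` = 0.7, `PT test` = 0.7,
                            `RSF train` = 0.7, `RSF test` = 0.7))
  a0 <- anova_two_way(rec0)
  cf0 <- coef(a0$fits$cindex)
  expect_equal(unname(cf0["(Intercept)"]), 0.7, tolerance = 1e-12)
  expect_true(all(abs(cf0[-1]) < 1e-12))

  # one inflated cell: only the matching interaction moves
  rec1 <- make_records(list(`ST train` = 0.9, `ST test` = 0.7,
                            `PT train` = 0.7, `PT test` = 0.7,
                            `RSF train` = 0.7, `RSF test` = 0.7))
  a1 <- anova_two_way(rec1)
  cf1 <- coef(a1$fits$cindex)
  expect_equal(unname(cf1["(Intercept)"]), 0.7, tolerance = 1e-12)
  expect_equal(unname(cf1["methodST"]), 0, tolerance = 1e-12)
  expect_equal(unname(cf1["settrain"]), 0, tolerance = 1e-12)
  expect_equal(unname(cf1["methodST:settrain"]), 0.2, tolerance = 1e-12)

  # saturated two-factor model: fitted values equal the six cell means
  fitted <- anova_cell_means(a1)
  emp <- rec1 |>
    dplyr::group_by(method, set) |>
    dplyr::summarise(cindex = mean(cindex), ibs = mean(ibs),
                     .groups = "drop")
  j <- dplyr::left_join(fitted |>
                          dplyr::mutate(method = as.character(method),
                                        set = as.character(set)),
                        emp, by = c("method", "set"),
                        suffix = c("_fit", "_emp"))
  expect_equal(j$cindex_fit, j$cindex_emp, tolerance = 1e-12)
  expect_equal(j$ibs_fit, j$ibs_emp, tolerance = 1e-12)

  # intercept of the fit is the RSF-test cell mean
  expect_equal(unname(coef(a1$fits$ibs)["(Intercept)"]),
               emp$ibs[emp$method == "RSF" & emp$set == "test"],
               tolerance = 1e-12)

  expect_error(anova_two_way(rec1[rec1$method != "PT", ]), "Empty design")
})

test_that("a small end-to-end study produces consistent bookkeeping", {
  prof <- cohort_profile(
    n = 120, age_mean = 60, age_sd = 10,
    binary_props = c(a = 0.5, b = 0.4, c = 0.3), event_target = 60,
    baseline_hazard = 0.05, log_hazard_ratios = c(age = 0.6, a = 0.8),
    censor_rate = 0.05, exact_counts = TRUE)
  coh <- generate_cohort(prof, seed = 77)
  st <- suppressWarnings(run_study(coh, k = 3, repeats = 2, n_trees = 10,
                                   size_grid = c(1, 5), seed = 42))
  expect_equal(nrow(st$records), 3 * 2 * 3 * 2)  # methods x sets x k x r
  expect_equal(sort(unique(st$records$method)), c("PT", "RSF", "ST"))
  expect_equal(dplyr::count(st$records, method, set)$n, rep(6L, 6))
  expect_true(all(st$records$cindex >= 0 & st$records$cindex <= 1))
  expect_true(all(st$records$ibs >= 0))
  expect_equal(nrow(st$summary$cells), 12L)
  expect_s3_class(st$anova, "performance_anova")
  expect_true(!is.null(st$curves))
  expect_equal(sort(unique(st$curves$method)), c("PT", "RSF", "ST"))

  # deterministic end to end under the master seed
  st2 <- suppressWarnings(run_study(coh, k = 3, repeats = 2, n_trees = 10,
                                    size_grid = c(1, 5), seed = 42))
  expect_equal(st$records, st2$records)

  g <- glance(st)
  expect_equal(nrow(g), 3L)
  rec <- st$records
  st_gap <- mean(rec$cindex[rec$method == "ST" & rec$set == "train"]) -
    mean(rec$cindex[rec$method == "ST" & rec$set == "test"])
  expect_equal(g$gap_cindex[g$method == "ST"], st_gap, tolerance = 1e-12)
})
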