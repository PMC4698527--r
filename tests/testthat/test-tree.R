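test_that("best_split agrees with the brute-force cutoff scan", {
  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(8:30, 1))
    d <- random_cohort(n, seed + 200)
    x <- survoptimism:::cohort_design(d)$x
    or <- oracle_best_split(d$time, d$status, x)
    bs <- best_split(d)
    if (is.null(or)) {
      expect_null(bs)
    } else {
      expect_equal(bs$variable, colnames(x)[or$var])
      expect_equal(bs$threshold, or$cut)
      expect_equal(bs$statistic, or$stat, tolerance = 1e-10)
    }
  }
})

test_that("a perfectly separating indicator is chosen at the root", {
  # group 1 dies early, group 0 is censored late
  d <- tibble::tibble(
    time = c(1, 2, 3, 20, 21, 22),
    status = c(1, 1, 1, 0, 0, 1),
    noise = c(0, 1, 0, 1, 0, 1),
    marker = c(1, 1, 1, 0, 0, 0))
  bs <- best_split(d)
  expect_equal(bs$variable, "marker")
})

test_that("nodes with constant covariates admit no split", {
  d <- tibble::tibble(time = c(1, 2, 3), status = c(1, 1, 0),
                      a = c(1, 1, 1), b = c(0, 0, 0))
  expect_null(best_split(d))
  tr <- grow_tree(d)
  expect_equal(n_leaves(tr), 1L)
})

test_that("exactly tied splits break toward the lower variable index then cutoff", {
  d <- tibble::tibble(time = c(1, 2, 5, 6), status = c(1, 1, 1, 1),
                      a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  bs <- best_split(d)
  expect_equal(bs$variable, "a")  # identical columns: first one wins
  # same statistic must arise for both
  expect_equal(logrank_statistic(d$time, d$status, d$a),
               logrank_statistic(d$time, d$status, d$b))
})

test_that("saturated trees keep at least one death per terminal node", {
  for (seed in c(3, 4)) {
    d <- random_cohort(60, seed)
    tr <- grow_tree(d)
    leaves <- tr$nodes[tr$nodes$terminal, ]
    expect_true(all(leaves$n_events >= 1))
    # terminal nodes partition the cohort
    expect_equal(sum(leaves$n), nrow(d))
    expect_equal(sort(unique(tr$leaf_of_training)), sort(leaves$id))
    expect_equal(as.vector(table(tr$leaf_of_training)[as.character(leaves$id)]),
                 leaves$n)
  }
})

test_that("training subjects route back to their own terminal node", {
  d <- random_cohort(80, 9)
  tr <- grow_tree(d)
  expect_equal(survoptimism:::predict_leaf(tr, d), tr$leaf_of_training)
  chfs <- predict_chf(tr, d)
  # each subject receives the CHF of the node that contains it
  i <- 17
  own <- tr$leaf_chf[[as.character(tr$leaf_of_training[i])]]
  expect_identical(chfs[[i]], own)
})

test_that("a subject at exactly a numeric threshold routes left", {
  d <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                      status = c(1, 1, 1, 1, 1, 1),
                      z = c(1, 2, 3, 7, 8, 9))
  tr <- grow_tree(d, min_node_size = 3)
  root <- tr$nodes[1, ]
  expect_equal(root$variable, "z")
  at_thr <- tibble::tibble(z = root$threshold)
  just_below <- tibble::tibble(z = root$threshold - 1e-9)
  expect_equal(survoptimism:::predict_leaf(tr, at_thr),
               survoptimism:::predict_leaf(tr, just_below))
  expect_error(predict_chf(tr, tibble::tibble(w = 1)), "lacks split")
})

test_that("the root split recovers the true variable on signal-bearing cohorts", {
  hits <- 0
  for (seed in 1:20) {
    prof <- cohort_profile(
      n = 500, age_mean = 60, age_sd = 10,
      binary_props = c(signal = 0.5, noise = 0.5), event_target = 250,
      baseline_hazard = 0.05, log_hazard_ratios = c(signal = 1.5),
      censor_rate = 0.05)
    coh <- generate_cohort(prof, seed = seed)
    coh$age <- NULL  # two binary covariates only
    bs <- best_split(coh)
    if (bs$variable == "signal") hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of seeds
})

test_that("pruning with a single-size grid returns the saturated tree", {
  d <- random_cohort(100, 21)
  pr <- prune_tree(d[1:70, ], d[71:100, ], size_grid = 1)
  expect_equal(pr$min_node_size, 1L)
  expect_equal(nrow(pr$curve), 1L)
  expect_equal(n_leaves(pr$tree), n_leaves(grow_tree(d[1:70, ])))
})

test_that("pruning shrinks overfit trees and reports a full error curve", {
  grid <- c(1, 2, 3, 5, 8, 13, 21)
  shrunk <- 0
  sat_wins <- 0
  for (seed in 1:20) {
    prof <- cohort_profile(
      n = 450, age_mean = 60, age_sd = 10,
      binary_props = c(signal = 0.5, n1 = 0.5, n2 = 0.5, n3 = 0.5),
      event_target = 200, baseline_hazard = 0.04,
      log_hazard_ratios = c(signal = 0.9), censor_rate = 0.05)
    coh <- generate_cohort(prof, seed = 300 + seed)
    train <- coh[1:300, ]
    test <- coh[301:450, ]
    pr <- prune_tree(train, test, size_grid = grid)
    expect_equal(nrow(pr$curve), length(grid))
    expect_equal(pr$curve$min_node_size, grid)
    if (pr$min_node_size > 1) shrunk <- shrunk + 1

    # monotone optimism: the saturated tree fits training data at least as
    # well as the selected pruned tree
    st <- grow_tree(train)
    et <- sort(unique(train$time[train$status == 1]))
    c_st <- c_index(train$time, train$status,
                    rowSums(survoptimism:::tree_chf_matrix(st, train, et)))
    c_pt <- c_index(train$time, train$status,
                    rowSums(survoptimism:::tree_chf_matrix(pr$tree, train, et)))
    if (c_st >= c_pt - 1e-12) sat_wins <- sat_wins + 1
  }
  expect_gt(shrunk, 10)   # majority of seeds select a non-saturated tree
  expect_gte(sat_wins, 18)
})

test_that("tree accessors expose the fit as tidy tables", {
  d <- random_cohort(50, 31)
  tr <- grow_tree(d)
  nd <- tidy(tr)
  expect_true(all(c("variable", "threshold", "left", "right", "n_events")
                  %in% names(nd)))
  g <- glance(tr)
  expect_equal(g$n, 50L)
  expect_equal(g$n_leaves, n_leaves(tr))
})
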