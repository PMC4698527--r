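#' Repeated k-fold cross-validation plan
#'
#' `r` independent unstratified random partitions of `n` subjects into `k`
#' folds with sizes differing by at most 1, giving `k * r` (train, test)
#' pairs (200 at the study scale `k = 10`, `r = 20`).
#'
#' @param n number of subjects (`n >= k`).
#' @param k number of folds (`k >= 2`).
#' @param r number of repetitions.
#' @param seed integer seed; the plan is deterministic under it.
#' @return A tibble with columns `rep`, `id`, `fold`.
#' @export
make_cv_plan <- function(n, k, r, seed) {
  stopifnot(k >= 2, r >= 1)
  if (n < k) abort("`n` must be at least `k`.")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(r), function(rp) {
      tibble::tibble(rep = rp, id = seq_len(n),
                     fold = sample(rep(seq_len(k), length.out = n)))
    })
  })
}

#' Train-test percent change of a performance statistic
#'
#' For the concordance index the reported change is the *reduction* from
#' training to test, `100 * (train - test) / train`; for the integrated
#' Brier score it is the *increase*, `100 * (test - train) / train`.
#' Values with magnitude at least 1 are rounded to the nearest integer,
#' smaller ones to 2 significant digits.
#'
#' @param train,test the statistic on the training and test sets.
#' @param metric `"cindex"` or `"ibs"`.
#' @return The rounded percent change.
#' @examples
#' percent_change(0.872, 0.634, "cindex")  # 27
#' percent_change(0.145, 0.166, "ibs")     # 14
#' @export
percent_change <- function(train, test, metric = c("cindex", "ibs")) {
  metric <- match.arg(metric)
  if (train == 0) abort("Zero reference value; percent change undefined.")
  pc <- switch(metric,
               cindex = 100 * (train - test) / train,
               ibs = 100 * (test - train) / train)
  if (abs(pc) >= 1) round(pc) else signif(pc, 2)
}

#' Summarise performance records
#'
#' Per (method, set, metric) cell: the mean across replicates and an
#' empirical 95% interval from the 2.5th and 97.5th percentiles
#' (linear-interpolation percentile definition); plus, per (method,
#' metric), the train-to-test [percent_change()] of the cell means.
#'
#' @param records a tibble with columns `method`, `set`, `replicate`,
#'   `cindex`, `ibs` (as produced by [run_study()]).
#' @return A `performance_summary` list: `$cells` (method, set, metric,
#'   mean, lower, upper) and `$percent_change` (method, metric, percent).
#' @export
summarize_records <- function(records) {
  long <- tidyr::pivot_longer(records, cols = c("cindex", "ibs"),
                              names_to = "metric", values_to = "value")
  counts <- dplyr::count(long, .data$method, .data$set, .data$metric)
  if (any(counts$n < 2)) {
    bad <- counts[counts$n < 2, ]
    abort(paste0("Cell with fewer than 2 replicates: ",
                 paste(bad$method, bad$set, bad$metric, collapse = "; ")))
  }
  cells <- long |>
    dplyr::group_by(.data$method, .data$set, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     lower = quantile(.data$value, 0.025, names = FALSE),
                     upper = quantile(.data$value, 0.975, names = FALSE),
                     .groups = "drop")
  pc <- cells |>
    dplyr::select("method", "set", "metric", "mean") |>
    tidyr::pivot_wider(names_from = "set", values_from = "mean") |>
    dplyr::rowwise() |>
    dplyr::mutate(percent = percent_change(
      .data$train, .data$test,
      metric = ifelse(.data$metric == "ibs", "ibs", "cindex"))) |>
    dplyr::ungroup() |>
    dplyr::select("method", "metric", "percent")
  structure(list(cells = cells, percent_change = pc),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("Performance summary (mean [2.5%, 97.5%] across replicates):\n")
  print(x$cells, n = Inf)
  cat("\nTrain-to-test percent change:\n")
  print(x$percent_change, n = Inf)
  invisible(x)
}

#' Two-way ANOVA on performance records
#'
#' Fits, for each response (concordance index and integrated Brier score),
#' an ordinary least-squares model with dummy-coded main effects for
#' construction method (ST, PT; reference RSF) and evaluation set (train;
#' reference test) plus their interactions, on the replicate-level records.
#' The model is saturated for the 3 x 2 design, so fitted values reproduce
#' the six cell means exactly and the intercept is the RSF-test mean.
#'
#' @param records as in [summarize_records()]; all six cells must be
#'   populated.
#' @return A `performance_anova` object; see [tidy.performance_anova()].
#' @export
anova_two_way <- function(records) {
  need <- tidyr::expand_grid(method = c("RSF", "ST", "PT"),
                             set = c("test", "train"))
  have <- dplyr::distinct(records, .data$method, .data$set)
  missing_cells <- dplyr::anti_join(need, have, by = c("method", "set"))
  if (nrow(missing_cells) > 0) {
    abort(paste0("Empty design cell(s): ",
                 paste(missing_cells$method, missing_cells$set,
                       collapse = "; ")))
  }
  df <- dplyr::mutate(records,
                      method = factor(.data$method,
                                      levels = c("RSF", "ST", "PT")),
                      set = factor(.data$set, levels = c("test", "train")))
  fits <- list(cindex = lm(cindex ~ method * set, data = df),
               ibs = lm(ibs ~ method * set, data = df))
  structure(list(fits = fits, n = nrow(df)), class = "performance_anova")
}

#' Tidy a two-way performance ANOVA
#'
#' @param x a [anova_two_way()] fit.
#' @param ... unused.
#' @return A tibble with `metric`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.performance_anova <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(m) {
    cf <- summary(x$fits[[m]])$coefficients
    tibble::tibble(metric = m, term = rownames(cf), estimate = cf[, 1],
                   std.error = cf[, 2], statistic = cf[, 3],
                   p.value = cf[, 4])
  })
}

#' @export
glance.performance_anova <- function(x, ...) {
  purrr::map_dfr(names(x$fits), function(m) {
    s <- summary(x$fits[[m]])
    tibble::tibble(metric = m, r.squared = s$r.squared,
                   sigma = s$sigma, df.residual = x$fits[[m]]$df.residual,
                   nobs = x$n)
  })
}

#' @export
print.performance_anova <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Fitted cell means of a performance ANOVA
#' @param x a [anova_two_way()] fit.
#' @return A tibble with one row per (method, set) cell and the fitted mean
#'   per metric.
#' @export
anova_cell_means <- function(x) {
  grid <- tidyr::expand_grid(
    method = factor(c("RSF", "ST", "PT"), levels = c("RSF", "ST", "PT")),
    set = factor(c("test", "train"), levels = c("test", "train")))
  dplyr::mutate(grid,
                cindex = as.numeric(predict(x$fits$cindex, grid)),
                ibs = as.numeric(predict(x$fits$ibs, grid)))
}

# ---- study runner -----------------------------------------------------

# Metrics of one method on one evaluation set, from the subjects-by-times
# CHF matrix evaluated at the set's unique event times.
eval_metrics <- function(H_et, data, cens_surv) {
  et <- sort(unique(data$time[data$status == 1L]))
  scores <- rowSums(H_et)
  ci <- c_index(data$time, data$status, scores)
  curve <- prediction_error_curve(exp(-H_et), data$time, data$status,
                                  cens_surv = cens_surv, grid = et)
  list(cindex = ci, ibs = integrated_brier(curve, max(data$time)),
       curve = curve)
}

tree_eval <- function(tree, data, cens_surv) {
  et <- sort(unique(data$time[data$status == 1L]))
  eval_metrics(tree_chf_matrix(tree, data, et), data, cens_surv)
}

chfset_eval <- function(chfs, data, cens_surv) {
  keep <- seq_len(nrow(chfs$H))
  excl <- attr(chfs, "excluded")
  if (length(excl) > 0) keep <- setdiff(keep, excl)
  data <- data[keep, , drop = FALSE]
  et <- sort(unique(data$time[data$status == 1L]))
  H <- chf_eval_matrix(chfs, et)[keep, , drop = FALSE]
  eval_metrics(H, data, cens_surv)
}

#' Run the full tree-versus-forest optimism study
#'
#' Repeated k-fold cross-validation over three model-construction methods:
#' the saturated survival tree (`ST`), the size-pruned tree (`PT`,
#' [prune_tree()] against the fold's test set), and the random survival
#' forest (`RSF`). For each of the `k * r` (train, test) pairs every method
#' is fitted on the training part and its concordance index and integrated
#' Brier score are recorded on both parts — the forest's "training"
#' performance is its out-of-bag ensemble performance, its test performance
#' the all-tree ensemble. Censoring weights for the Brier score come from
#' the training part of each pair. One designated replicate's
#' prediction-error curves are kept for plotting.
#'
#' The defaults (`repeats = 3`, `n_trees = 100`) are a scaled-down profile
#' running the identical code path as the study scale (`repeats = 20`,
#' `n_trees = 1000`).
#'
#' @param cohort a cohort tibble (see [generate_cohort()]).
#' @param k folds per repetition.
#' @param repeats repetitions of the k-fold split.
#' @param n_trees forest size per fold.
#' @param mtry forest candidate variables per node (default
#'   `ceiling(sqrt(p))`).
#' @param size_grid pruning grid of minimum terminal-node sizes.
#' @param forest_min_node_size minimum terminal-node size of forest trees.
#' @param seed master seed; the CV plan and every forest derive their seeds
#'   from it, making the run deterministic end to end.
#' @param curve_replicate replicate (1-based index into the `k * r` pairs)
#'   whose prediction-error curves are stored.
#' @param verbose print per-fold progress with timing.
#' @return An `optimism_study` list: `$records` (method, set, rep, fold,
#'   replicate, cindex, ibs), `$summary` ([summarize_records()]), `$anova`
#'   ([anova_two_way()]), `$curves` (tibble: method, set, time, brier), and
#'   `$config`.
#' @export
run_study <- function(cohort, k = 10, repeats = 3, n_trees = 100,
                      mtry = NULL, size_grid = c(1, 2, 3, 5, 8, 13, 21, 34, 55),
                      forest_min_node_size = 3, seed = 1,
                      curve_replicate = 1, verbose = FALSE) {
  n <- nrow(cohort)
  plan <- make_cv_plan(n, k, repeats, seed)
  records <- vector("list", k * repeats * 6L)
  curves <- NULL
  ri <- 0L

  for (rp in seq_len(repeats)) {
    folds <- plan$fold[plan$rep == rp]
    folds <- ensure_events_per_fold(folds, cohort$status, k,
                                    seed + 500000L + rp)
    for (fd in seq_len(k)) {
      t0 <- Sys.time()
      train <- cohort[folds != fd, , drop = FALSE]
      test <- cohort[folds == fd, , drop = FALSE]
      G <- km_censoring(train$time, train$status)
      replicate_id <- (rp - 1L) * k + fd

      st <- grow_tree(train)
      st_train <- tree_eval(st, train, G)
      st_test <- tree_eval(st, test, G)

      pt <- prune_tree(train, test, size_grid = size_grid)
      pt_train <- tree_eval(pt$tree, train, G)
      pt_test <- tree_eval(pt$tree, test, G)

      rsf <- grow_forest(train, n_trees = n_trees, mtry = mtry,
                         min_node_size = forest_min_node_size,
                         seed = seed + 1009L * rp + fd)
      rsf_train <- chfset_eval(oob_chf(rsf), train, G)
      rsf_test <- chfset_eval(ensemble_chf(rsf, test), test, G)

      res <- list(ST = list(train = st_train, test = st_test),
                  PT = list(train = pt_train, test = pt_test),
                  RSF = list(train = rsf_train, test = rsf_test))
      for (m in names(res)) {
        for (s in names(res[[m]])) {
          ri <- ri + 1L
          records[[ri]] <- tibble::tibble(
            method = m, set = s, rep = rp, fold = fd,
            replicate = replicate_id,
            cindex = res[[m]][[s]]$cindex, ibs = res[[m]][[s]]$ibs)
        }
      }
      if (replicate_id == curve_replicate) {
        curves <- purrr::map_dfr(names(res), function(m) {
          purrr::map_dfr(names(res[[m]]), function(s) {
            cv <- res[[m]][[s]]$curve
            tibble::tibble(method = m, set = s, time = c(0, cv$time),
                           brier = c(cv$v0, cv$value))
          })
        })
      }
      if (verbose) {
        message(sprintf("rep %d fold %d done in %.1fs", rp, fd,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      }
    }
  }
  records <- dplyr::bind_rows(records)
  structure(list(records = records, summary = summarize_records(records),
                 anova = anova_two_way(records), curves = curves,
                 config = list(k = k, repeats = repeats, n_trees = n_trees,
                               mtry = mtry, size_grid = size_grid,
                               forest_min_node_size = forest_min_node_size,
                               seed = seed)),
            class = "optimism_study")
}

# Redraw a repetition's partition (bounded retries) until every fold has at
# least one event in both its training and test part.
ensure_events_per_fold <- function(folds, status, k, seed) {
  ok <- function(f) {
    all(vapply(seq_len(k), function(fd) {
      sum(status[f == fd]) > 0 && sum(status[f != fd]) > 0
    }, logical(1)))
  }
  if (ok(folds)) return(folds)
  for (attempt in seq_len(100L)) {
    folds <- withr::with_seed(seed + attempt, {
      sample(rep(seq_len(k), length.out = length(status)))
    })
    if (ok(folds)) {
      warn(sprintf("Fold partition redrawn (%d attempt(s)): empty-event fold.",
                   attempt))
      return(folds)
    }
  }
  abort("Could not draw a fold partition with events in every fold.")
}

#' @export
print.optimism_study <- function(x, ...) {
  cat("<optimism_study> ", nrow(x$records), " performance records (",
      x$config$repeats, " x ", x$config$k, "-fold CV, ",
      x$config$n_trees, " trees per forest)\n\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.optimism_study <- function(x, ...) x$records

#' @export
glance.optimism_study <- function(x, ...) {
  gaps <- x$records |>
    tidyr::pivot_longer(c("cindex", "ibs"), names_to = "metric") |>
    dplyr::group_by(.data$method, .data$metric, .data$set) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "set", values_from = "mean") |>
    dplyr::mutate(gap = ifelse(.data$metric == "cindex",
                               .data$train - .data$test,
                               .data$test - .data$train))
  tidyr::pivot_wider(
    dplyr::select(gaps, "method", "metric", "gap"),
    names_from = "metric", values_from = "gap", names_prefix = "gap_")
}
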