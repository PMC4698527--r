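#' Bootstrap in-bag count matrix
#'
#' Draws `B` bootstrap samples of size `n` with replacement and returns the
#' subjects-by-samples matrix of in-bag counts. A subject absent from a
#' sample (count 0) is out-of-bag (OOB) for it; asymptotically each subject
#' is in-bag in a fraction `1 - (1 - 1/n)^n` (about 63%) of samples, hence
#' OOB about 37% of them.
#'
#' @param n subjects per sample.
#' @param B number of bootstrap samples.
#' @param seed optional integer seed.
#' @return An `n x B` integer matrix of in-bag counts (columns sum to `n`).
#' @export
draw_bootstrap <- function(n, B, seed = NULL) {
  draw <- function() {
    vapply(seq_len(B), function(b) tabulate(sample.int(n, n, replace = TRUE),
                                            nbins = n),
           integer(n))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Grow a random survival forest
#'
#' For each of `n_trees` bootstrap samples of size `n` (drawn with
#' replacement), grows a log-rank survival tree in which every node's split
#' search sees a fresh uniform random subset of `mtry` design-matrix
#' columns. Bootstrap samples containing no events are redrawn (bounded
#' retries) so the number of trees stays fixed. The in-bag count matrix is
#' kept so out-of-bag ensemble predictions can be formed.
#'
#' @inheritParams grow_tree
#' @param n_trees number of bootstrap trees (the study-scale default is
#'   1000; scaled-down runs use fewer).
#' @param mtry candidate variables per node; default `ceiling(sqrt(p))`
#'   over the dummy-encoded design columns.
#' @param min_node_size minimum subjects per terminal node (default 3, with
#'   at least one death — forest trees are deep but not fully saturated).
#' @param seed integer seed making bootstrap draws and per-node variable
#'   subsets reproducible.
#' @param bootstrap set to `"identity"` to replace every bootstrap draw by
#'   the identity resample (each subject once) — a testing hook that, with
#'   `mtry = p` and `n_trees = 1`, reduces the forest to a single
#'   [grow_tree()] fit.
#' @return A `survival_forest`: the member trees, the in-bag count matrix,
#'   and the training data snapshot used for out-of-bag prediction.
#' @export
grow_forest <- function(data, n_trees = 1000L, mtry = NULL,
                        min_node_size = 3L, min_deaths = 1L, seed = NULL,
                        bootstrap = c("resample", "identity")) {
  bootstrap <- match.arg(bootstrap)
  stopifnot(n_trees >= 1L)
  dm <- cohort_design(data)
  if (sum(dm$status) == 0L) {
    abort("No events in the data.", class = "survoptimism_no_events")
  }
  n <- length(dm$time)
  p <- ncol(dm$x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  stopifnot(mtry >= 1L, mtry <= p)

  fit <- function() {
    inbag <- matrix(0L, n, n_trees)
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      rows <- NULL
      if (bootstrap == "identity") {
        rows <- seq_len(n)
      } else {
        for (try in seq_len(100L)) {
          cand <- sample.int(n, n, replace = TRUE)
          if (sum(dm$status[cand]) > 0L) {
            rows <- cand
            break
          }
        }
        if (is.null(rows)) {
          abort("Could not draw a bootstrap sample containing an event.")
        }
        if (try > 1L) {
          warn(sprintf("Bootstrap sample %d redrawn %d time(s) (no events).",
                       b, try - 1L))
        }
      }
      inbag[, b] <- tabulate(rows, nbins = n)
      trees[[b]] <- grow_tree(data, min_node_size = min_node_size,
                              min_deaths = min_deaths,
                              mtry = if (mtry < p) mtry else NULL,
                              rows = rows)
    }
    list(trees = trees, inbag = inbag)
  }
  res <- if (is.null(seed)) fit() else withr::with_seed(seed, fit())

  structure(list(trees = res$trees, inbag = res$inbag,
                 oob = res$inbag == 0L, mtry = as.integer(mtry),
                 min_node_size = as.integer(min_node_size),
                 min_deaths = as.integer(min_deaths), seed = seed,
                 data = data, vars = dm$vars, n = n),
            class = "survival_forest")
}

#' @export
print.survival_forest <- function(x, ...) {
  cat("<survival_forest> ", length(x$trees), " tree(s), mtry=", x$mtry,
      ", min_node_size=", x$min_node_size, ", n=", x$n, "\n", sep = "")
  invisible(x)
}

# Shared evaluation grid: union of all member trees' jump times (these are
# all training event times, so the union stays small).
forest_grid <- function(forest) {
  sort(unique(unlist(lapply(forest$trees, function(tr) {
    unlist(lapply(tr$leaf_chf, `[[`, "time"), use.names = FALSE)
  }), use.names = FALSE)))
}

# Sum of member-tree CHF matrices over a subset of trees, for given rows of
# `newdata`, on grid `times`; optionally masked per subject by an indicator
# matrix (subjects x trees).
forest_accumulate <- function(forest, newdata, times, tree_idx,
                              mask = NULL) {
  x <- align_design(forest$vars, newdata)
  n <- nrow(x)
  acc <- matrix(0, n, length(times))
  cnt <- if (is.null(mask)) rep(length(tree_idx), n) else rep(0, n)
  for (b in tree_idx) {
    tr <- forest$trees[[b]]
    leaves <- cpp_predict_leaf(tr$var_idx, tr$thr, tr$left_idx,
                               tr$right_idx, x) + 1L
    leaf_vals <- chf_eval_matrix(tr$leaf_chf, times)
    rownames(leaf_vals) <- names(tr$leaf_chf)
    hb <- leaf_vals[as.character(leaves), , drop = FALSE]
    if (is.null(mask)) {
      acc <- acc + hb
    } else {
      w <- mask[, b]
      acc <- acc + hb * w
      cnt <- cnt + w
    }
  }
  list(acc = acc, cnt = cnt)
}

#' Out-of-bag ensemble cumulative hazard
#'
#' For each training subject `i`, averages the member trees' predicted
#' cumulative hazards over exactly the trees whose bootstrap sample omitted
#' `i` (`H*(t|x_i) = sum_b I_ib H_b(t|x_i) / sum_b I_ib`), pointwise on the
#' union of the member trees' jump times. Subjects that are never
#' out-of-bag are excluded with a warning (an error if more than 5% are).
#'
#' @param forest a [grow_forest()] fit.
#' @return A [chf_set()] over the training subjects, with attribute
#'   `excluded` holding the row indices of never-OOB subjects (their rows
#'   are `NA`).
#' @export
oob_chf <- function(forest) {
  stopifnot(inherits(forest, "survival_forest"))
  grid <- forest_grid(forest)
  oob_counts <- rowSums(forest$oob)
  excluded <- which(oob_counts == 0L)
  if (length(excluded) > forest$n * 0.05) {
    abort(sprintf(
      "%d of %d subjects are never out-of-bag; grow more trees.",
      length(excluded), forest$n))
  }
  if (length(excluded) > 0L) {
    warn(sprintf(
      "%d subject(s) never out-of-bag; excluded from OOB performance.",
      length(excluded)))
  }
  res <- forest_accumulate(forest, forest$data, grid,
                           seq_along(forest$trees),
                           mask = forest$oob * 1)
  H <- res$acc / ifelse(res$cnt == 0, NA_real_, res$cnt)
  out <- chf_set(grid, H)
  attr(out, "excluded") <- excluded
  out
}

#' Ensemble cumulative hazard for new subjects
#'
#' Averages the predicted cumulative hazard over all member trees (a new
#' subject is out-of-bag for every tree by definition), pointwise on the
#' union of the member trees' jump times.
#'
#' @param forest a [grow_forest()] fit.
#' @param newdata data frame of covariates.
#' @return A [chf_set()], one row per row of `newdata`.
#' @export
ensemble_chf <- function(forest, newdata) {
  stopifnot(inherits(forest, "survival_forest"))
  grid <- forest_grid(forest)
  res <- forest_accumulate(forest, newdata, grid, seq_along(forest$trees))
  chf_set(grid, res$acc / length(forest$trees))
}

#' @export
predict_chf.survival_forest <- function(object, newdata, ...) {
  out <- ensemble_chf(object, newdata)
  lapply(seq_len(nrow(out$H)), function(i) chf_subject(out, i))
}

#' Ensemble survival curve
#'
#' `S(t) = exp(-H(t))` applied to an ensemble (or any) cumulative hazard;
#' the averaged-CHF route to a subject's final survival curve.
#'
#' @param chf a [survstep()] or [chf_set()] cumulative hazard.
#' @return The induced survival object (same shape as the input).
#' @export
ensemble_survival <- function(chf) chf_to_survival(chf)

#' One-row summary of a forest
#' @param x a `survival_forest`.
#' @param ... unused.
#' @export
glance.survival_forest <- function(x, ...) {
  tibble::tibble(n = x$n, n_trees = length(x$trees), mtry = x$mtry,
                 min_node_size = x$min_node_size,
                 mean_inbag_fraction = mean(colMeans(x$inbag > 0)),
                 mean_oob_count = mean(rowSums(x$oob)))
}

#' Per-tree summary of a forest
#' @param x a `survival_forest`.
#' @param ... unused.
#' @return A tibble with one row per member tree.
#' @export
tidy.survival_forest <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$trees), function(b) {
    dplyr::mutate(glance(x$trees[[b]]), tree = b, .before = 1)
  }))
}
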