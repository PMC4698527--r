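#' Best log-rank split of a node
#'
#' Evaluates every admissible cutoff of every candidate variable — numeric
#' variables at the midpoints between consecutive distinct sorted values,
#' 0/1 indicators at their single split — and returns the one maximising
#' the two-sample log-rank statistic, subject to both children containing
#' at least `min_deaths` deaths and `min_node_size` subjects. Exactly tied
#' statistics are broken toward the lower variable index, then the lower
#' cutoff. Subjects with `x <= threshold` go left.
#'
#' @param data a data frame with `time`, `status` and covariate columns
#'   (factors are dummy-encoded; see [cohort_design()]).
#' @param vars candidate variable names (design-matrix column names);
#'   default all.
#' @param min_node_size minimum subjects per child.
#' @param min_deaths minimum deaths per child.
#' @return A tibble with one row (`variable`, `threshold`, `statistic`), or
#'   `NULL` if no admissible split exists.
#' @export
best_split <- function(data, vars = NULL, min_node_size = 1L,
                       min_deaths = 1L) {
  dm <- cohort_design(data)
  if (is.null(vars)) vars <- dm$vars
  miss <- setdiff(vars, dm$vars)
  if (length(miss) > 0) {
    abort(paste0("Unknown variables: ", paste(miss, collapse = ", ")))
  }
  if (length(vars) == 0L) return(NULL)
  cand0 <- match(vars, dm$vars) - 1L
  res <- cpp_best_split(dm$time, dm$status, dm$x,
                        seq_along(dm$time) - 1L, cand0,
                        as.integer(min_node_size), as.integer(min_deaths))
  if (!res$found) return(NULL)
  tibble::tibble(variable = dm$vars[res$var + 1L],
                 threshold = res$threshold, statistic = res$statistic)
}

#' Grow a log-rank survival tree
#'
#' Recursively splits via [best_split()] until no admissible split remains.
#' With the defaults (`min_node_size = 1`, `min_deaths = 1`) this is the
#' saturated tree: every terminal node retains at least one death and
#' splitting continues as long as any cutoff keeps that true. Each terminal
#' node carries the Nelson-Aalen cumulative hazard of exactly its own
#' subjects.
#'
#' @inheritParams best_split
#' @param mtry if not `NULL`, a fresh uniform random subset of `mtry`
#'   design-matrix columns is offered to every node (the forest's per-node
#'   randomisation); `NULL` offers all variables.
#' @param rows optional row indices (with multiplicity) to grow on, e.g. a
#'   bootstrap resample; defaults to all rows once.
#' @return A `survival_tree`: node table, per-terminal-node cumulative
#'   hazards, and the training-row routing.
#' @examples
#' coh <- generate_cohort(ami_profile(), seed = 1)
#' tr <- grow_tree(coh[1:80, ])
#' tr
#' @export
grow_tree <- function(data, min_node_size = 1L, min_deaths = 1L, mtry = NULL,
                      rows = NULL) {
  dm <- cohort_design(data)
  if (is.null(rows)) rows <- seq_along(dm$time)
  if (sum(dm$status[rows]) == 0L) {
    abort("No events among the training rows.",
          class = "survoptimism_no_events")
  }
  if (min_deaths < 1L) abort("`min_deaths` must be >= 1.")
  mtry_c <- if (is.null(mtry)) 0L else as.integer(mtry)
  if (mtry_c < 0L || mtry_c > ncol(dm$x)) {
    abort("`mtry` must be between 1 and the number of design columns.")
  }
  fit <- cpp_grow_tree(dm$time, dm$status, dm$x, as.integer(rows) - 1L,
                       mtry_c, as.integer(min_node_size),
                       as.integer(min_deaths))
  leaf_ids <- sort(unique(fit$leaf_of)) + 1L
  leaf_chf <- lapply(leaf_ids, function(id) {
    mem <- rows[fit$leaf_of + 1L == id]
    nelson_aalen(dm$time[mem], dm$status[mem])
  })
  names(leaf_chf) <- leaf_ids
  nodes <- tibble::tibble(
    id = seq_along(fit$var),
    variable = c(NA_character_, dm$vars)[fit$var + 2L],
    threshold = fit$threshold, statistic = fit$statistic,
    left = ifelse(fit$left >= 0L, fit$left + 1L, NA_integer_),
    right = ifelse(fit$right >= 0L, fit$right + 1L, NA_integer_),
    n = fit$n, n_events = fit$n_events,
    terminal = fit$var < 0L
  )
  structure(list(nodes = nodes, leaf_chf = leaf_chf,
                 leaf_of_training = fit$leaf_of + 1L, rows = rows,
                 vars = dm$vars, min_node_size = as.integer(min_node_size),
                 min_deaths = as.integer(min_deaths), mtry = mtry,
                 var_idx = fit$var, thr = fit$threshold,
                 left_idx = fit$left, right_idx = fit$right),
            class = "survival_tree")
}

#' @export
print.survival_tree <- function(x, ...) {
  cat("<survival_tree> ", sum(x$nodes$terminal), " terminal node(s), ",
      nrow(x$nodes), " node(s) total; n=", x$nodes$n[1],
      ", events=", x$nodes$n_events[1], "\n", sep = "")
  invisible(x)
}

#' @describeIn grow_tree number of terminal nodes.
#' @param tree a `survival_tree`.
#' @export
n_leaves <- function(tree) sum(tree$nodes$terminal)

# Design matrix for new data, aligned to the tree's training columns.
align_design <- function(vars, newdata) {
  dm <- cohort_design_newdata(newdata)
  miss <- setdiff(vars, colnames(dm))
  if (length(miss) > 0) {
    abort(paste0("`newdata` lacks split variable(s): ",
                 paste(miss, collapse = ", ")))
  }
  dm[, vars, drop = FALSE]
}

# Like cohort_design() but without requiring time/status (prediction only).
cohort_design_newdata <- function(data) {
  covs <- setdiff(names(data), c("id", "time", "status"))
  cols <- list()
  for (nm in covs) {
    v <- data[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      f <- if (is.factor(v)) v else factor(v)
      for (lv in levels(f)) cols[[paste0(nm, "_", lv)]] <- as.numeric(f == lv)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  x
}

# Terminal node id per row of newdata.
predict_leaf <- function(tree, newdata) {
  x <- align_design(tree$vars, newdata)
  var_idx <- match_var_idx(tree, colnames(x))
  cpp_predict_leaf(var_idx, tree$thr, tree$left_idx, tree$right_idx, x) + 1L
}

# The stored var_idx refers to the training design columns; when newdata is
# aligned to tree$vars the indices coincide.
match_var_idx <- function(tree, cols) {
  stopifnot(identical(cols, tree$vars))
  tree$var_idx
}

#' Predict a subject's cumulative hazard from a tree
#'
#' Routes each row of `newdata` from the root by the split rules (`x <=
#' threshold` goes left, including exact ties) and returns the reached
#' terminal node's Nelson-Aalen cumulative hazard.
#'
#' @param object a `survival_tree` or `survival_forest`.
#' @param newdata data frame of covariates (all split variables required).
#' @param ... unused.
#' @return A list of [survstep()] cumulative hazards, one per row (shared
#'   objects for subjects reaching the same node).
#' @export
predict_chf <- function(object, newdata, ...) UseMethod("predict_chf")

#' @export
predict_chf.survival_tree <- function(object, newdata, ...) {
  leaves <- predict_leaf(object, newdata)
  unname(object$leaf_chf[as.character(leaves)])
}

# Subjects-by-times CHF matrix for a tree: evaluate each terminal once.
tree_chf_matrix <- function(tree, newdata, times, leaves = NULL) {
  if (is.null(leaves)) leaves <- predict_leaf(tree, newdata)
  ids <- names(tree$leaf_chf)
  leaf_vals <- chf_eval_matrix(tree$leaf_chf, times)
  rownames(leaf_vals) <- ids
  leaf_vals[as.character(leaves), , drop = FALSE]
}

#' Prune a survival tree against held-out error
#'
#' Tree complexity is indexed by the minimum terminal-node size: one tree is
#' grown per value in `size_grid` (each still keeping at least one death per
#' terminal node), its error `1 - C` is measured on `test` using the
#' pair-counting concordance index on mortality scores, and the tree
#' minimising test error is returned. Ties are broken toward the smaller
#' tree (larger minimum node size).
#'
#' @param train,test data frames with `time`, `status` and covariates.
#' @param size_grid minimum-terminal-node-size values to try; the default
#'   covers sizes 1 (the saturated tree) up to roughly n/10.
#' @param min_deaths minimum deaths per terminal node (kept at 1).
#' @return A `pruned_survival_tree`: the selected `tree`, the chosen
#'   `min_node_size`, and the full `curve` tibble
#'   (`min_node_size`, `n_leaves`, `error`).
#' @export
prune_tree <- function(train, test, size_grid = c(1, 2, 3, 5, 8, 13, 21, 34, 55),
                       min_deaths = 1L) {
  stopifnot(length(size_grid) > 0)
  size_grid <- sort(unique(as.integer(size_grid)))
  et <- sort(unique(test$time[test$status == 1]))
  fits <- lapply(size_grid, function(s) {
    tr <- grow_tree(train, min_node_size = s, min_deaths = min_deaths)
    sc <- rowSums(tree_chf_matrix(tr, test, et))
    list(tree = tr, error = 1 - c_index(test$time, test$status, sc))
  })
  err <- vapply(fits, `[[`, numeric(1), "error")
  # ties toward the larger minimum node size (smaller tree)
  best <- max(which(err == min(err)))
  curve <- tibble::tibble(
    min_node_size = size_grid,
    n_leaves = vapply(fits, function(f) n_leaves(f$tree), 0L),
    error = err
  )
  structure(list(tree = fits[[best]]$tree,
                 min_node_size = size_grid[best], curve = curve),
            class = "pruned_survival_tree")
}

#' @export
print.pruned_survival_tree <- function(x, ...) {
  cat("<pruned_survival_tree> selected min_node_size=", x$min_node_size,
      " (", n_leaves(x$tree), " leaves)\n", sep = "")
  invisible(x)
}

#' @export
predict_chf.pruned_survival_tree <- function(object, newdata, ...) {
  predict_chf(object$tree, newdata, ...)
}

#' Tidy a survival tree's node table
#' @param x a `survival_tree`.
#' @param ... unused.
#' @return The node tibble: one row per node with split rule, children,
#'   size and death count.
#' @export
tidy.survival_tree <- function(x, ...) x$nodes

#' One-row summary of a survival tree
#' @param x a `survival_tree`.
#' @param ... unused.
#' @export
glance.survival_tree <- function(x, ...) {
  tibble::tibble(n = x$nodes$n[1], n_events = x$nodes$n_events[1],
                 n_nodes = nrow(x$nodes), n_leaves = n_leaves(x),
                 min_node_size = x$min_node_size, min_deaths = x$min_deaths)
}

#' @export
tidy.pruned_survival_tree <- function(x, ...) x$curve

#' @export
glance.pruned_survival_tree <- function(x, ...) {
  dplyr::mutate(glance(x$tree), selected_min_node_size = x$min_node_size,
                test_error = min(x$curve$error))
}
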