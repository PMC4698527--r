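#' Mortality scores from cumulative hazards
#'
#' The predicted-risk ranking value used by the concordance index: for each
#' subject, the sum of its predicted cumulative hazard over the evaluation
#' set's unique event times, `score_i = sum_l H(t_l | x_i)`. Larger means
#' predicted higher risk. For a forest the (out-of-bag) ensemble cumulative
#' hazard plays the role of `H`.
#'
#' @param chfs per-subject cumulative hazards: a [chf_set()] or a list of
#'   [survstep()].
#' @param event_times the evaluation set's event times (deduplicated and
#'   sorted internally); must be non-empty.
#' @return Numeric score per subject.
#' @export
mortality_scores <- function(chfs, event_times) {
  event_times <- sort(unique(event_times))
  if (length(event_times) == 0L) abort("`event_times` must be non-empty.")
  rowSums(chf_eval_matrix(chfs, event_times))
}

#' Pair-counting concordance index
#'
#' Forms all subject pairs and drops the non-permissible ones: pairs whose
#' shorter follow-up time is censored, and tied-time pairs with no death.
#' Each permissible pair contributes: unequal times — 1 if the
#' shorter-lived subject has the higher score, 0.5 on a score tie, else 0;
#' equal times, both deaths — 1 if the scores tie, else 0.5; equal times,
#' exactly one death — 1 if the death has the higher score, else 0.5. The
#' index is the summed contribution over the permissible pair count: 0.5 is
#' chance level, 1 perfect discrimination. Score ties are detected with
#' absolute tolerance `1e-12`.
#'
#' @inheritParams risk_table
#' @param scores predicted risk scores (larger = higher risk), e.g. from
#'   [mortality_scores()].
#' @return Scalar in `[0, 1]`.
#' @export
c_index <- function(time, status, scores) {
  check_surv(time, status)
  stopifnot(length(scores) == length(time))
  if (anyNA(scores) || any(!is.finite(scores))) {
    abort("`scores` must be finite and non-missing.")
  }
  n <- length(time)
  pr <- which(lower.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pr[, 2L]
  j <- pr[, 1L]
  ti <- time[i]; tj <- time[j]
  si <- status[i]; sj <- status[j]
  sci <- scores[i]; scj <- scores[j]

  drop <- (ti < tj & si == 0L) | (tj < ti & sj == 0L) |
    (ti == tj & si == 0L & sj == 0L)
  keep <- !drop
  if (!any(keep)) {
    abort("No permissible pairs: every pair has its shorter time censored or is a tied censored pair.",
          class = "survoptimism_no_permissible_pairs")
  }
  ti <- ti[keep]; tj <- tj[keep]; si <- si[keep]; sj <- sj[keep]
  sci <- sci[keep]; scj <- scj[keep]

  tie_sc <- abs(sci - scj) <= 1e-12
  contrib <- numeric(length(ti))

  uneq <- ti != tj
  short_i <- uneq & ti < tj
  short_j <- uneq & tj < ti
  contrib[short_i] <- ifelse(tie_sc[short_i], 0.5,
                             as.numeric(sci[short_i] > scj[short_i]))
  contrib[short_j] <- ifelse(tie_sc[short_j], 0.5,
                             as.numeric(scj[short_j] > sci[short_j]))

  both_d <- !uneq & si == 1L & sj == 1L
  contrib[both_d] <- ifelse(tie_sc[both_d], 1, 0.5)

  one_d <- !uneq & (si + sj == 1L)
  death_hi <- ifelse(si[one_d] == 1L, sci[one_d] > scj[one_d] + 1e-12,
                     scj[one_d] > sci[one_d] + 1e-12)
  contrib[one_d] <- ifelse(death_hi, 1, 0.5)

  sum(contrib) / length(contrib)
}

#' Inverse-probability-of-censoring-weighted Brier score at a time
#'
#' The expected squared prediction error at horizon `t`, reweighted for
#' censoring (Graf decomposition): subjects who died by `t` contribute
#' `S(t|x)^2 / G(T-)`, subjects still under observation at `t` contribute
#' `(1 - S(t|x))^2 / G(t)`, and subjects censored by `t` contribute 0,
#' where `G` is the Kaplan-Meier censoring survival curve (evaluated as a
#' left limit for past events). Contributing subjects whose weight would
#' divide by `G = 0` are dropped with a warning. Division is by the full
#' `n`.
#'
#' @param t evaluation horizon (scalar).
#' @param surv predicted survival probabilities at `t`: a numeric vector, a
#'   [chf_set()] of survival curves ([chf_to_survival()]), or a list of
#'   survival [survstep()]s.
#' @inheritParams risk_table
#' @param cens_surv censoring survival [survstep()], usually
#'   [km_censoring()] on the *training* data (`NULL` recomputes it from
#'   `time`/`status`).
#' @return Non-negative scalar.
#' @export
brier_score <- function(t, surv, time, status, cens_surv = NULL) {
  check_surv(time, status)
  if (is.null(cens_surv)) cens_surv <- km_censoring(time, status)
  s_t <- surv_at(surv, t, length(time))
  n <- length(time)

  died <- time <= t & status == 1L
  alive <- time > t
  w <- numeric(n)
  w[died] <- step_eval(cens_surv, time[died], left = TRUE)
  w[alive] <- step_eval(cens_surv, t)
  bad <- (died | alive) & w <= 0
  if (any(bad)) {
    warn(sprintf("%d subject(s) dropped from the Brier score (zero censoring weight).",
                 sum(bad)))
  }
  term <- numeric(n)
  ok_d <- died & !bad
  ok_a <- alive & !bad
  term[ok_d] <- s_t[ok_d]^2 / w[ok_d]
  term[ok_a] <- (1 - s_t[ok_a])^2 / w[ok_a]
  sum(term) / n
}

surv_at <- function(surv, t, n) {
  if (is.numeric(surv)) {
    stopifnot(length(surv) == n)
    return(surv)
  }
  drop(chf_eval_matrix(surv, t))
}

#' Prediction error curve
#'
#' The Brier score evaluated across time: `BS(t)` at each grid time
#' (default grid: the evaluation set's unique event times), returned as a
#' right-continuous step function whose pre-grid value is `BS(0)`.
#'
#' @param surv per-subject predicted survival curves: a [chf_set()] of
#'   survival values or a list of survival [survstep()]s.
#' @inheritParams brier_score
#' @param grid evaluation times (non-empty; default unique event times).
#' @return A [survstep()]; also see [integrated_brier()].
#' @export
prediction_error_curve <- function(surv, time, status, cens_surv = NULL,
                                   grid = NULL) {
  if (is.null(grid)) grid <- sort(unique(time[status == 1L]))
  grid <- sort(unique(grid))
  if (length(grid) == 0L) abort("Empty evaluation grid.")
  if (is.null(cens_surv)) cens_surv <- km_censoring(time, status)
  s_mat <- if (is.numeric(surv) && is.matrix(surv)) {
    stopifnot(ncol(surv) == length(grid))
    surv
  } else {
    chf_eval_matrix(surv, grid)
  }
  bs <- vapply(seq_along(grid), function(k) {
    brier_score(grid[k], s_mat[, k], time, status, cens_surv)
  }, numeric(1))
  bs0 <- brier_score(0, surv_at0(surv, nrow(s_mat)), time, status, cens_surv)
  survstep(grid, bs, v0 = bs0)
}

surv_at0 <- function(surv, n) {
  if (is.numeric(surv) && is.matrix(surv)) return(rep(1, n))
  drop(chf_eval_matrix(surv, 0))
}

#' Integrated Brier score
#'
#' The time-average of the prediction error curve,
#' `IBS = (1/t_max) * integral of BS(t) dt on [0, t_max]`, computed as the
#' exact integral of the right-continuous step curve. Lower is better.
#'
#' @param curve a prediction error curve ([survstep()]).
#' @param t_max upper limit (> 0); conventionally the maximum observed time
#'   of the evaluation set.
#' @return Non-negative scalar.
#' @export
integrated_brier <- function(curve, t_max) {
  stopifnot(t_max > 0)
  step_integral(curve, t_max) / t_max
}
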