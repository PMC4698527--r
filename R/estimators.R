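#' Risk table at the distinct event times
#'
#' Tabulates, for each distinct event (death) time `t_l`, the number of
#' deaths `d_l` and the number at risk `Y_l` (subjects with `T >= t_l`;
#' censorings tied with an event time are still counted at risk there).
#'
#' @param time follow-up times (days, > 0).
#' @param status event indicators: 1 = death, 0 = censored.
#' @return A tibble with columns `time`, `n_event`, `n_risk`.
#' @examples
#' risk_table(c(2, 2, 5), c(1, 1, 0))
#' @export
risk_table <- function(time, status) {
  check_surv(time, status)
  if (sum(status) == 0L) {
    abort("No events in the data; a risk table needs at least one death.",
          class = "survoptimism_no_events")
  }
  et <- sort(unique(time[status == 1]))
  d <- vapply(et, function(t0) sum(time == t0 & status == 1), 0L)
  y <- vapply(et, function(t0) sum(time >= t0), 0L)
  tibble::tibble(time = et, n_event = d, n_risk = y)
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' `H(t) = sum over event times t_l <= t of d_l / Y_l`; 0 before the first
#' event time. This is the per-node hazard estimate attached to every
#' terminal node of a survival tree.
#'
#' @inheritParams risk_table
#' @return A [survstep()] cumulative hazard (non-decreasing, `H(0) = 0`).
#' @examples
#' H <- nelson_aalen(c(2, 1, 3), c(1, 1, 1))
#' step_eval(H, c(1, 2, 3))   # 1/3, 1/3 + 1/2, 11/6
#' @export
nelson_aalen <- function(time, status) {
  rt <- risk_table(time, status)
  survstep(rt$time, cumsum(rt$n_event / rt$n_risk), v0 = 0)
}

#' Kaplan-Meier estimate of the censoring survival function
#'
#' The product-limit estimator applied with censorings treated as the
#' events: `G(t) = P(C > t)`, used as the inverse-probability-of-censoring
#' weight in the Brier score. With no censorings `G` is identically 1.
#'
#' @inheritParams risk_table
#' @return A [survstep()] with `G(0) = 1`, non-increasing in `[0, 1]`.
#' @export
km_censoring <- function(time, status) {
  check_surv(time, status)
  cens <- 1L - status
  if (sum(cens) == 0L) return(survstep(numeric(0), numeric(0), v0 = 1))
  ct <- sort(unique(time[cens == 1]))
  d <- vapply(ct, function(t0) sum(time == t0 & cens == 1), 0L)
  y <- vapply(ct, function(t0) sum(time >= t0), 0L)
  survstep(ct, cumprod(1 - d / y), v0 = 1)
}

#' Two-sample log-rank chi-square statistic
#'
#' The split criterion of the survival trees: across the pooled distinct
#' event times, the squared difference between observed and expected deaths
#' in group 1 divided by the sum of hypergeometric variances (with the
#' usual ties correction). Zero variance returns 0 by convention.
#'
#' @inheritParams risk_table
#' @param group binary group labels (two non-empty groups).
#' @return Non-negative scalar; invariant to relabelling the groups.
#' @export
logrank_statistic <- function(time, status, group) {
  check_surv(time, status)
  stopifnot(length(group) == length(time))
  g <- as.integer(as.factor(group)) - 1L
  if (length(unique(g)) != 2L) {
    abort("`group` must define exactly two non-empty groups.",
          class = "survoptimism_invalid_split")
  }
  if (sum(status) == 0L) {
    abort("No events; the log-rank statistic is undefined.",
          class = "survoptimism_no_events")
  }
  et <- sort(unique(time[status == 1]))
  O1 <- E1 <- V <- 0
  for (t0 in et) {
    at_risk <- time >= t0
    Y <- sum(at_risk)
    Y1 <- sum(at_risk & g == 1L)
    ev <- time == t0 & status == 1
    d <- sum(ev)
    O1 <- O1 + sum(ev & g == 1L)
    E1 <- E1 + d * Y1 / Y
    if (Y > 1) V <- V + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  if (V <= 1e-12) return(0)
  (O1 - E1)^2 / V
}

check_surv <- function(time, status) {
  if (length(time) != length(status)) {
    abort("`time` and `status` must have equal length.")
  }
  if (anyNA(time) || anyNA(status)) abort("Missing values are not allowed.")
  if (any(time <= 0)) abort("All follow-up times must be positive.")
  if (!all(status %in% c(0, 1))) abort("`status` must be 0/1.")
  invisible(TRUE)
}
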