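#' Right-continuous step functions on time
#'
#' The estimators in this package (Nelson-Aalen cumulative hazards,
#' Kaplan-Meier censoring survival, prediction-error curves) are all
#' right-continuous piecewise-constant functions of follow-up time. A
#' `survstep` stores the strictly increasing jump times, the value taken at
#' and after each jump, and the value before the first jump (`v0`; 0 for a
#' cumulative hazard, 1 for a survival function).
#'
#' @param time strictly increasing numeric vector of jump times (days).
#' @param value function value at/after each jump time.
#' @param v0 value on `[0, time[1])`.
#' @return A `survstep` object.
#' @examples
#' H <- survstep(c(2, 5), c(0.5, 1.25), v0 = 0)
#' step_eval(H, c(0, 2, 4.9, 5, 10))
#' @export
survstep <- function(time, value, v0) {
  stopifnot(length(time) == length(value), length(v0) == 1L)
  if (length(time) > 1L && any(diff(time) <= 0)) {
    abort("`time` must be strictly increasing.")
  }
  structure(list(time = as.numeric(time), value = as.numeric(value),
                 v0 = as.numeric(v0)),
            class = "survstep")
}

#' Evaluate a step function
#'
#' @param sf a [survstep()].
#' @param t numeric times (>= 0).
#' @param left if `TRUE`, return the left limit `f(t-)` instead of the
#'   right-continuous value `f(t)`. IPCW weighting of past events uses the
#'   left limit of the censoring survival curve.
#' @return Numeric vector of function values.
#' @export
step_eval <- function(sf, t, left = FALSE) {
  stopifnot(inherits(sf, "survstep"))
  idx <- findInterval(t, sf$time, left.open = left)
  c(sf$v0, sf$value)[idx + 1L]
}

#' Exact integral of a step function over [0, upper]
#'
#' Integrates the right-continuous piecewise-constant function exactly:
#' each inter-knot interval contributes its width times the value on it.
#' Beyond the last knot the last value is extended.
#'
#' @param sf a [survstep()].
#' @param upper upper limit of integration (> 0).
#' @return The integral, a scalar.
#' @export
step_integral <- function(sf, upper) {
  stopifnot(inherits(sf, "survstep"), upper > 0)
  knots <- c(0, sf$time[sf$time < upper], upper)
  vals <- c(sf$v0, sf$value[sf$time < upper])
  sum(vals * diff(knots))
}

#' Survival curve induced by a cumulative hazard
#'
#' Applies `S(t) = exp(-H(t))` pointwise; the CHF's non-decrease makes the
#' result a valid non-increasing survival curve with `S(0) = 1`.
#'
#' @param chf a cumulative hazard `survstep` (or a [chf_set]).
#' @return An object of the same shape with values `exp(-H)`.
#' @export
chf_to_survival <- function(chf) {
  if (inherits(chf, "chf_set")) {
    out <- chf
    out$H <- exp(-chf$H)
    class(out) <- c("surv_set", "chf_set")
    return(out)
  }
  stopifnot(inherits(chf, "survstep"))
  survstep(chf$time, exp(-chf$value), exp(-chf$v0))
}

#' @export
print.survstep <- function(x, ...) {
  cat("<survstep> ", length(x$time), " jump(s); value ", format(x$v0),
      " before t=", format(x$time[1] %||% Inf), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.survstep <- function(x, ...) {
  data.frame(time = c(0, x$time), value = c(x$v0, x$value))
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.survstep <- function(x, ...) {
  tibble::tibble(time = c(0, x$time), value = c(x$v0, x$value))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Per-subject cumulative hazards on a common time grid
#'
#' Ensemble predictions evaluate many subjects' CHFs on one shared grid (the
#' union of the member trees' jump times); a `chf_set` stores that grid and a
#' subjects-by-times value matrix. `v0` is 0 for CHFs.
#'
#' @param time common grid of jump times.
#' @param H numeric matrix, one row per subject, `ncol == length(time)`.
#' @param v0 value before the first jump (default 0).
#' @return A `chf_set`.
#' @export
chf_set <- function(time, H, v0 = 0) {
  H <- as.matrix(H)
  stopifnot(ncol(H) == length(time))
  structure(list(time = as.numeric(time), H = H, v0 = v0), class = "chf_set")
}

#' @export
print.chf_set <- function(x, ...) {
  cat("<chf_set> ", nrow(x$H), " subject(s) on a grid of ", length(x$time),
      " times\n", sep = "")
  invisible(x)
}

#' Extract one subject's step function from a `chf_set`
#' @param x a [chf_set()].
#' @param i subject row index.
#' @return A [survstep()].
#' @export
chf_subject <- function(x, i) {
  stopifnot(inherits(x, "chf_set"))
  survstep(x$time, x$H[i, ], v0 = x$v0)
}

# Evaluate per-subject CHFs at arbitrary times -> subjects x times matrix.
# Accepts a chf_set or a list of survstep.
chf_eval_matrix <- function(chfs, times, left = FALSE) {
  if (inherits(chfs, "chf_set")) {
    idx <- findInterval(times, chfs$time, left.open = left)
    full <- cbind(chfs$v0, chfs$H)
    return(full[, idx + 1L, drop = FALSE])
  }
  stopifnot(is.list(chfs))
  m <- vapply(chfs, step_eval, numeric(length(times)), t = times, left = left)
  if (length(times) == 1L) matrix(m, ncol = 1L) else t(m)
}
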