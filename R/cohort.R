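#' Cohort generation profile
#'
#' A `cohort_profile` bundles everything the synthetic-cohort generator
#' needs: sample size, the marginal distribution of each covariate, the
#' exponential proportional-hazards event-time model (baseline rate per day
#' plus log hazard ratios), and an independent exponential "discharge"
#' (censoring) rate. With `exact_counts = TRUE` the categorical margins and
#' the event count are matched exactly rather than sampled.
#'
#' @param n number of subjects (>= 1).
#' @param age_mean,age_sd age marginal, years (`age_sd > 0`). Ages are drawn
#'   from a normal truncated at 25 years whose location is adjusted so the
#'   post-truncation mean equals `age_mean`.
#' @param binary_props named probabilities of "yes" for the binary
#'   covariates, each in `[0, 1]`.
#' @param intervention_props named probabilities of the 4-level intervention
#'   factor, summing to 1 (or `NULL` for no intervention column).
#' @param event_target expected number of deaths.
#' @param baseline_hazard exponential event rate per day for a reference
#'   subject (all covariates 0, age at its mean).
#' @param log_hazard_ratios named log hazard ratios; age acts per standard
#'   deviation (it is standardised before its coefficient is applied).
#' @param censor_rate exponential censoring ("discharge") rate per day.
#' @param exact_counts if `TRUE`, categorical columns get exactly
#'   `round(p * n)` (half-up) members per level and exactly `event_target`
#'   subjects are events.
#' @return A validated `cohort_profile` list.
#' @seealso [ami_profile()] for the calibrated default, [generate_cohort()].
#' @export
cohort_profile <- function(n, age_mean, age_sd, binary_props,
                           intervention_props = NULL, event_target,
                           baseline_hazard, log_hazard_ratios = numeric(),
                           censor_rate, exact_counts = FALSE) {
  stopifnot(n >= 1, age_sd > 0, baseline_hazard > 0, censor_rate > 0,
            event_target >= 1, event_target <= n)
  if (any(binary_props < 0 | binary_props > 1)) {
    abort("All binary proportions must lie in [0, 1].")
  }
  if (is.null(names(binary_props)) || anyDuplicated(names(binary_props))) {
    abort("`binary_props` must have unique names.")
  }
  if (!is.null(intervention_props)) {
    if (any(intervention_props < 0 | intervention_props > 1)) {
      abort("Intervention proportions must lie in [0, 1].")
    }
    if (abs(sum(intervention_props) - 1) > 1e-9) {
      abort("`intervention_props` must sum to 1.")
    }
  }
  extra <- setdiff(names(log_hazard_ratios), c("age", names(binary_props)))
  if (length(extra) > 0) {
    abort(paste0("Unknown covariates in `log_hazard_ratios`: ",
                 paste(extra, collapse = ", ")))
  }
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 binary_props = binary_props,
                 intervention_props = intervention_props,
                 event_target = as.integer(event_target),
                 baseline_hazard = baseline_hazard,
                 log_hazard_ratios = log_hazard_ratios,
                 censor_rate = censor_rate,
                 exact_counts = isTRUE(exact_counts)),
            class = "cohort_profile")
}

#' Default profile: an AMI coronary-care cohort
#'
#' The generator's default conditions: 607 subjects, mean age 61.34 years
#' (SD 13.46), 204 in-hospital deaths, nine binary risk factors and a
#' 4-level intervention with the marginal frequencies of a published acute
#' myocardial infarction registry. Event times follow an exponential
#' proportional-hazards model in which age (per SD) and a pathologic Q wave
#' carry moderate positive effects, so grown trees have true structure to
#' recover; censoring is an independent exponential discharge time with
#' mean stay 7 days, and the baseline hazard is calibrated so the expected
#' death count equals the target.
#'
#' @param exact_counts match category counts and the death count exactly
#'   (stratified assignment) instead of sampling them.
#' @return A [cohort_profile()].
#' @examples
#' prof <- ami_profile()
#' prof$n              # 607
#' prof$event_target   # 204
#' @export
ami_profile <- function(exact_counts = FALSE) {
  cohort_profile(
    n = 607,
    age_mean = 61.34,
    age_sd = 13.46,
    binary_props = c(male = 0.697, htn = 0.404, lipid = 0.222, ihd = 0.303,
                     dm = 0.247, smoke = 0.356, famhx = 0.104, qwave = 0.262,
                     sk = 0.458),
    intervention_props = c(angioplasty = 0.053, pacemaker = 0.059,
                           bypass = 0.074, drug = 0.814),
    event_target = 204,
    baseline_hazard = 0.0572,
    log_hazard_ratios = c(age = 0.5, qwave = 0.7),
    censor_rate = 1 / 7,
    exact_counts = exact_counts
  )
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile> n=", x$n, ", target deaths=", x$event_target,
      if (x$exact_counts) " (exact counts)" else "", "\n", sep = "")
  invisible(x)
}

# Location of a normal(mu, sd) truncated below at `lower` such that the
# truncated mean equals `target_mean`.
trunc_normal_location <- function(target_mean, sd, lower = 25) {
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * exp(stats::dnorm(a, log = TRUE) -
                    stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  uniroot(function(mu) tmean(mu) - target_mean,
          lower = target_mean - 10 * sd, upper = target_mean,
          tol = 1e-10)$root
}

rtrunc_normal <- function(n, mu, sd, lower = 25) {
  plo <- pnorm(lower, mu, sd)
  qnorm(runif(n, plo, 1), mu, sd)
}

# Half-up integer rounding of p * n.
round_half_up <- function(x) floor(x + 0.5)

# Expected death fraction under exponential PH event times with
# exponential censoring: P(E < C | eta) = lam / (lam + c).
expected_event_fraction <- function(baseline_hazard, eta, censor_rate) {
  lam <- baseline_hazard * exp(eta)
  mean(lam / (lam + censor_rate))
}

# Bisect the baseline hazard so the expected death count hits the target.
tune_baseline_hazard <- function(eta, censor_rate, target_fraction,
                                 max_iter = 200) {
  f <- function(l0) expected_event_fraction(l0, eta, censor_rate)
  lo <- 1e-12
  hi <- 1
  it <- 0
  while (f(hi) < target_fraction) {
    hi <- hi * 10
    it <- it + 1
    if (it > 30) abort("Baseline-hazard bisection failed to bracket.")
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    if (f(mid) < target_fraction) lo <- mid else hi <- mid
    if (hi / lo < 1 + 1e-12) break
  }
  sqrt(lo * hi)
}

#' Generate a right-censored synthetic cohort
#'
#' Draws covariates independently from the profile's marginals (truncated
#' normal age; Bernoulli binaries; categorical intervention), exponential
#' proportional-hazards event times with rate
#' `baseline_hazard * exp(sum(beta_k x_k))` (age standardised before its
#' coefficient applies), and independent exponential censoring times;
#' follow-up is the earlier of the two. In `exact_counts` mode every
#' categorical column is a permuted vector with exactly `round(p * n)`
#' (half-up) ones — the intervention's largest level absorbs the rounding
#' remainder — the baseline hazard is re-tuned by bisection so the expected
#' death count equals `event_target`, and exactly `event_target` subjects
#' become events: those with the smallest `log(E_i) - log(C_i)` (a
#' thresholding of the latent times that reduces to the natural `min()`
#' mechanism at the tuned hazard).
#'
#' @param profile a [cohort_profile()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A tibble with columns `id`, `time` (days), `status`
#'   (1 = death, 0 = censored/discharged), `age`, one 0/1 column per binary
#'   covariate, and `intervention` (factor), if the profile has one.
#' @examples
#' coh <- generate_cohort(ami_profile(exact_counts = TRUE), seed = 7)
#' sum(coh$status)  # exactly 204
#' @export
generate_cohort <- function(profile, seed) {
  stopifnot(inherits(profile, "cohort_profile"))
  withr::with_seed(seed, generate_cohort_impl(profile))
}

generate_cohort_impl <- function(profile) {
  n <- profile$n
  mu <- trunc_normal_location(profile$age_mean, profile$age_sd)
  age <- rtrunc_normal(n, mu, profile$age_sd)

  bp <- profile$binary_props
  if (profile$exact_counts) {
    bins <- lapply(bp, function(p) {
      k <- round_half_up(p * n)
      sample(rep(c(1L, 0L), c(k, n - k)))
    })
  } else {
    bins <- lapply(bp, function(p) rbinom(n, 1L, p))
  }
  names(bins) <- names(bp)

  interv <- NULL
  ip <- profile$intervention_props
  if (!is.null(ip)) {
    lv <- names(ip)
    if (profile$exact_counts) {
      k <- round_half_up(ip * n)
      big <- which.max(ip)
      k[big] <- k[big] + (n - sum(k))
      interv <- factor(sample(rep(lv, k)), levels = lv)
    } else {
      interv <- factor(sample(lv, n, replace = TRUE, prob = ip), levels = lv)
    }
  }

  beta <- profile$log_hazard_ratios
  eta <- rep(0, n)
  if ("age" %in% names(beta)) {
    eta <- eta + beta[["age"]] * (age - profile$age_mean) / profile$age_sd
  }
  for (nm in intersect(names(beta), names(bins))) {
    eta <- eta + beta[[nm]] * bins[[nm]]
  }

  lam0 <- profile$baseline_hazard
  if (profile$exact_counts) {
    lam0 <- tune_baseline_hazard(eta, profile$censor_rate,
                                 profile$event_target / n)
  }
  e_time <- rexp(n, rate = lam0 * exp(eta))
  c_time <- rexp(n, rate = profile$censor_rate)

  if (profile$exact_counts) {
    delta <- log(e_time) - log(c_time)
    ev <- rep(0L, n)
    ev[order(delta)[seq_len(profile$event_target)]] <- 1L
    time <- ifelse(ev == 1L, e_time, c_time)
  } else {
    ev <- as.integer(e_time <= c_time)
    time <- pmin(e_time, c_time)
  }

  out <- tibble::tibble(id = seq_len(n), time = time, status = ev, age = age)
  for (nm in names(bins)) out[[nm]] <- bins[[nm]]
  if (!is.null(interv)) out$intervention <- interv
  out
}

#' Read a generation profile from a YAML or JSON config file
#'
#' The file holds the fields of [cohort_profile()] by name (maps for
#' `binary_props`, `intervention_props` and `log_hazard_ratios`); missing
#' optional fields fall back to the constructor defaults. The extension
#' selects the parser (`.yaml`/`.yml` or `.json`).
#'
#' @param path path to the config file.
#' @return A validated [cohort_profile()].
#' @export
read_profile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    abort("Profile config must be .yaml, .yml or .json."))
  as_named <- function(x) if (is.null(x)) NULL else unlist(x)
  cohort_profile(
    n = raw$n, age_mean = raw$age_mean, age_sd = raw$age_sd,
    binary_props = as_named(raw$binary_props),
    intervention_props = as_named(raw$intervention_props),
    event_target = raw$event_target,
    baseline_hazard = raw$baseline_hazard,
    log_hazard_ratios = as_named(raw$log_hazard_ratios) %||% numeric(),
    censor_rate = raw$censor_rate,
    exact_counts = isTRUE(raw$exact_counts))
}

#' Write / read a cohort as CSV
#'
#' The intervention factor is serialised as its category name and restored
#' as a factor (levels in first-appearance order of the default profile when
#' they match, otherwise sorted).
#'
#' @param cohort a cohort tibble as produced by [generate_cohort()].
#' @param path file path.
#' @return `write_cohort()` returns `cohort` invisibly; `read_cohort()`
#'   returns the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  if ("intervention" %in% names(out)) {
    default_lv <- c("angioplasty", "pacemaker", "bypass", "drug")
    lv <- if (all(unique(out$intervention) %in% default_lv)) {
      default_lv
    } else {
      sort(unique(out$intervention))
    }
    out$intervention <- factor(out$intervention, levels = lv)
  }
  out
}

#' Design matrix for tree fitting
#'
#' Builds the numeric covariate matrix the tree and forest fitters use:
#' numeric columns pass through, factor/character columns are expanded into
#' one 0/1 indicator per level (full dummy coding, so a 4-level intervention
#' becomes 4 indicators). `id`, `time` and `status` are excluded.
#'
#' @param data a data frame with `time` and `status` columns plus covariates.
#' @return A list with `time`, `status`, the matrix `x` and `vars`
#'   (column names).
#' @export
cohort_design <- function(data) {
  stopifnot(is.data.frame(data), all(c("time", "status") %in% names(data)))
  check_surv(data$time, data$status)
  covs <- setdiff(names(data), c("id", "time", "status"))
  if (length(covs) == 0L) abort("No covariate columns found.")
  cols <- list()
  for (nm in covs) {
    v <- data[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      f <- if (is.factor(v)) v else factor(v)
      for (lv in levels(f)) {
        cols[[paste0(nm, "_", lv)]] <- as.numeric(f == lv)
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  list(time = as.numeric(data$time), status = as.integer(data$status),
       x = x, vars = colnames(x))
}
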