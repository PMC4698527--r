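# Brute-force reference implementations used to cross-check the package.
# These deliberately favour literal, naive computation over speed and share
# no code with the implementation under test.

# Two-sample log-rank chi-square by explicit per-event-time tabulation.
oracle_logrank <- function(time, status, group) {
  g <- as.integer(as.factor(group)) - 1L
  event_times <- sort(unique(time[status == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t0 in event_times) {
    risk <- which(time >= t0)
    Y <- length(risk)
    Y1 <- sum(g[risk] == 1L)
    dead <- which(time == t0 & status == 1)
    d <- length(dead)
    O1 <- O1 + sum(g[dead] == 1L)
    E1 <- E1 + d * Y1 / Y
    if (Y > 1) {
      V <- V + d * (Y1 / Y) * ((Y - Y1) / Y) * ((Y - d) / (Y - 1))
    }
  }
  if (V <= 1e-12) return(0)
  (O1 - E1)^2 / V
}

# Pair-counting concordance by exhaustive enumeration of all pairs,
# applying the counting rules one pair at a time.
oracle_cindex <- function(time, status, scores) {
  n <- length(time)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- time[i]; tj <- time[j]
      si <- status[i]; sj <- status[j]
      if (ti < tj && si == 0) next
      if (tj < ti && sj == 0) next
      if (ti == tj && si == 0 && sj == 0) next
      den <- den + 1
      tie <- abs(scores[i] - scores[j]) <= 1e-12
      if (ti != tj) {
        shorter <- if (ti < tj) i else j
        longer <- if (ti < tj) j else i
        if (tie) num <- num + 0.5
        else if (scores[shorter] > scores[longer]) num <- num + 1
      } else if (si == 1 && sj == 1) {
        num <- num + if (tie) 1 else 0.5
      } else {
        death <- if (si == 1) i else j
        other <- if (si == 1) j else i
        if (!tie && scores[death] > scores[other]) num <- num + 1
        else num <- num + 0.5
      }
    }
  }
  num / den
}

# Exhaustive (variable, cutoff) scan maximising oracle_logrank, subject to
# both children holding >= min_deaths deaths and >= min_size subjects.
# x is a plain numeric matrix. Ties keep the earliest (variable, cutoff).
oracle_best_split <- function(time, status, x, min_size = 1, min_deaths = 1) {
  best <- NULL
  for (v in seq_len(ncol(x))) {
    vals <- sort(unique(x[, v]))
    if (length(vals) < 2) next
    cuts <- (vals[-length(vals)] + vals[-1]) / 2
    for (cc in cuts) {
      left <- x[, v] <= cc
      if (sum(left) < min_size || sum(!left) < min_size) next
      if (sum(status[left]) < min_deaths || sum(status[!left]) < min_deaths) next
      stat <- oracle_logrank(time, status, left)
      if (is.null(best) || stat > best$stat) {
        best <- list(var = v, cut = cc, stat = stat)
      }
    }
  }
  best
}

# Small random right-censored datasets with ties in both time and score.
random_surv_data <- function(n, seed, tie_heavy = TRUE) {
  withr::with_seed(seed, {
    time <- if (tie_heavy) sample(1:5, n, replace = TRUE) else round(rexp(n, 0.2), 2) + 0.01
    status <- rbinom(n, 1, 0.7)
    if (sum(status) == 0) status[sample(n, 1)] <- 1L
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    list(time = time, status = status, scores = scores)
  })
}

# Small random cohorts (data frame form) for split/tree checks.
random_cohort <- function(n, seed, p_bin = 2, p_num = 1) {
  withr::with_seed(seed, {
    df <- tibble::tibble(
      time = round(rexp(n, 0.1), 1) + 0.1,
      status = rbinom(n, 1, 0.6)
    )
    if (sum(df$status) == 0) df$status[sample(n, 1)] <- 1L
    for (k in seq_len(p_bin)) df[[paste0("b", k)]] <- rbinom(n, 1, 0.5)
    for (k in seq_len(p_num)) df[[paste0("z", k)]] <- round(rnorm(n), 1)
    df
  })
}

# Balanced synthetic performance records with exact cell means.
make_records <- function(cell_means, reps = 4, spread = 0.01) {
  # two symmetric replicates around each target mean keep the mean exact
  grid <- tidyr::expand_grid(method = c("ST", "PT", "RSF"),
                             set = c("train", "test"))
  purrr::pmap_dfr(grid, function(method, set) {
    m <- cell_means[[paste(method, set)]]
    dev <- rep(c(-spread, spread), length.out = reps)
    tibble::tibble(method = method, set = set, replicate = seq_len(reps),
                   cindex = m + dev, ibs = (m / 2) + dev)
  })
}

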