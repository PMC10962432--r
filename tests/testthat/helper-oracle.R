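# Independent oracles, deliberately written as plain enumeration so they
# share no code path with the package implementation.

# Explicit window-membership + exact median for one evaluation time.
oracle_window_median <- function(t_rel, log_level, t, window_width) {
  vals <- c()
  for (i in seq_along(t_rel)) {
    tr <- t_rel[i]
    inside <-
      if (t < 0) tr < 0 && tr >= t - window_width / 2 && tr <= t + window_width / 2
      else if (t == 0) tr == 0
      else tr > 0 && tr >= t - window_width / 2 && tr <= t + window_width / 2
    if (inside) vals <- c(vals, log_level[i])
  }
  n <- length(vals)
  med <- if (n == 0) NA_real_ else {
    v <- sort(vals)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  list(median = med, n = n)
}

# Textbook one-way ANOVA from explicit sums of squares.
oracle_anova <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  N <- length(x)
  grand <- mean(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    v <- x[g == lev]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fstat, p = stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE))
}

# Random aligned sample set with all three segments occupied.
random_aligned_fixture <- function(n_donors = 10) {
  n_pre <- sample(1:n_donors, 1)
  n_post <- sample(1:n_donors, 1)
  n_zero <- sample(1:n_donors, 1)
  data.frame(
    donor_id = sprintf("D%02d", seq_len(n_pre + n_zero + n_post)),
    marker = "M",
    t_rel = c(-runif(n_pre, 0.01, 22), rep(0, n_zero), runif(n_post, 0.01, 42)),
    log_level = rnorm(n_pre + n_zero + n_post, 3, 1),
    stringsAsFactors = FALSE
  )
}

# Minimal hand-built donor table for cohort tests.
toy_donors <- function(n, bd_duration = rep(15, n), age = rep(50, n),
                       consent = rep(TRUE, n),
                       cause = rep("ICH", n),
                       full = rep(TRUE, n),
                       inflamed = rep(FALSE, n)) {
  data.frame(
    donor_id = sprintf("T%03d", seq_len(n)),
    age = age, sex = rep(c("M", "F"), length.out = n),
    bmi = rep(27, n), hypertension = rep(FALSE, n), diabetes = rep(FALSE, n),
    cause_of_death = cause, consent = consent,
    systemic_inflammation = inflamed, bd_duration = bd_duration,
    has_full_sample_set = full, stringsAsFactors = FALSE
  )
}

marker_truth_labels <- function() {
  c(`TNF-a` = "declining", `IL-6` = "plateau_then_decline",
    C5a = "constant_elevated", NSE = "constant_elevated",
    GFAP = "step_increase")
}
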