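#' Inclusion/exclusion filtering of a donor table
#'
#' Applies the cohort's eligibility criteria in order and records how many
#' donors each criterion removed. The built-in criteria are:
#'
#' * `"consent"` — valid consent recorded;
#' * `"full_sample_set"` — all three serum samples (DB1, DB2, DB3) are
#'   available. When `samples` is supplied this is checked against the
#'   sample table (every time-point label present for the donor); otherwise
#'   the donor table's `has_full_sample_set` column is used;
#' * `"cause_ich"` — intracranial haemorrhage as the cause leading to brain
#'   death (other causes — hypoxic injury, trauma, ischaemia, infection —
#'   are excluded);
#' * `"documented_bd_duration"` — a non-missing brain-death duration;
#' * `"no_systemic_inflammation"` — no documented systemic source of
#'   elevated inflammatory markers (trauma, pneumonia, urinary infection,
#'   ...), represented as a boolean flag column.
#'
#' @param donors donor table (one row per donor).
#' @param samples optional sample table used to verify sample availability.
#' @param criteria character vector of criterion names, applied in order.
#' @return list with `eligible` (the filtered donor table) and `audit`
#'   (data.frame of `criterion` and `removed` counts, in application order).
#' @export
apply_inclusion_exclusion <- function(donors, samples = NULL,
                                      criteria = c("consent",
                                                   "full_sample_set",
                                                   "cause_ich",
                                                   "documented_bd_duration",
                                                   "no_systemic_inflammation")) {
  needed <- list(
    consent = "consent",
    full_sample_set = if (is.null(samples)) "has_full_sample_set" else character(),
    cause_ich = "cause_of_death",
    documented_bd_duration = "bd_duration",
    no_systemic_inflammation = "systemic_inflammation"
  )
  unknown <- setdiff(criteria, names(needed))
  if (length(unknown))
    stop("unknown criteria: ", paste(unknown, collapse = ", "), call. = FALSE)
  miss <- setdiff(unlist(needed[criteria]), names(donors))
  if (length(miss))
    stop("criteria reference absent donor columns: ",
         paste(miss, collapse = ", "), call. = FALSE)

  keep_fun <- list(
    consent = function(d) d$consent %in% TRUE,
    full_sample_set = function(d) {
      if (is.null(samples)) return(d$has_full_sample_set %in% TRUE)
      ok_ids <- Filter(function(id) {
        all(c("DB1", "DB2", "DB3") %in%
              samples$timepoint[samples$donor_id == id])
      }, d$donor_id)
      d$donor_id %in% ok_ids
    },
    cause_ich = function(d) !is.na(d$cause_of_death) & d$cause_of_death == "ICH",
    documented_bd_duration = function(d) !is.na(d$bd_duration),
    no_systemic_inflammation = function(d) !(d$systemic_inflammation %in% TRUE)
  )

  removed <- integer(length(criteria))
  for (i in seq_along(criteria)) {
    keep <- if (nrow(donors)) keep_fun[[criteria[i]]](donors) else logical(0)
    removed[i] <- sum(!keep)
    donors <- donors[keep, , drop = FALSE]
  }
  list(eligible = donors,
       audit = data.frame(criterion = criteria, removed = removed,
                          stringsAsFactors = FALSE))
}

#' Assign brain-death durations to 5-hour blocks
#'
#' The 10-30 h core study window is broken into four 5-h blocks; durations
#' below 10 h form the "short" extreme and durations of 30 h or more the
#' "long" extreme. Intervals are half-open `[lo, hi)` so every duration
#' lands in exactly one block (a duration of exactly 15 h is in the
#' 15-20 h block).
#'
#' @param bd_duration numeric vector of durations in hours (no missing
#'   values; a missing duration violates the inclusion criteria upstream).
#' @return character vector of block labels, levels `short`, `10-15`,
#'   `15-20`, `20-25`, `25-30`, `long`.
#' @export
bd_block <- function(bd_duration) {
  if (any(is.na(bd_duration)))
    stop("missing bd_duration: donors without a documented duration of ",
         "brain death are not eligible", call. = FALSE)
  cut(bd_duration, breaks = c(-Inf, 10, 15, 20, 25, 30, Inf),
      labels = bd_block_levels(), right = FALSE) |> as.character()
}

bd_block_levels <- function() c("short", "10-15", "15-20", "20-25", "25-30", "long")
core_blocks <- function() c("10-15", "15-20", "20-25", "25-30")

#' Stratify an eligible donor table by brain-death duration
#'
#' @param donors donor table with a `bd_duration` column.
#' @return data.frame with `donor_id` and `block` (see [bd_block()]).
#' @export
stratify_by_bd_blocks <- function(donors) {
  if (!"bd_duration" %in% names(donors))
    stop("`donors` lacks a bd_duration column", call. = FALSE)
  data.frame(donor_id = donors$donor_id,
             block = bd_block(donors$bd_duration),
             stringsAsFactors = FALSE)
}

# Covariate imbalance of one candidate subset against pooled targets:
# continuous -> |SMD| = |mean - target centre| / pooled SD with the pooled
# median as centre (robust, so stray extreme candidates do not drag the
# target towards themselves); binary -> |proportion difference|.
imbalance_score <- function(d, covariates, targets) {
  s <- 0
  for (cv in covariates) {
    x <- d[[cv]]
    tg <- targets[[cv]]
    if (tg$type == "binary") {
      s <- s + abs(mean(x %in% tg$level) - tg$p)
    } else if (tg$sd > 0) {
      s <- s + abs(mean(x) - tg$center) / tg$sd
    }
  }
  s
}

covariate_targets <- function(pool, covariates) {
  targets <- list()
  for (cv in covariates) {
    x <- pool[[cv]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      targets[[cv]] <- list(type = "continuous", center = stats::median(x),
                            sd = stats::sd(x))
    } else {
      lev <- if (is.logical(x)) TRUE else sort(unique(as.character(x)))[1]
      targets[[cv]] <- list(type = "binary", level = lev,
                            p = mean(x %in% lev))
    }
  }
  targets
}

#' Select a balanced study cohort across brain-death duration blocks
#'
#' From each core 5-h block, selects exactly `group_size` donors so that the
#' selected groups resemble the pooled eligible population on the matching
#' covariates; donors in the "short" and "long" extremes bypass balancing
#' and are all included. The imbalance score of a candidate group is the sum
#' over covariates of the absolute standardized mean difference (continuous)
#' or absolute proportion difference (binary) against the pooled core-block
#' candidates. Blocks with at most 8 candidates are optimised by exhaustive
#' enumeration; larger blocks by a seeded greedy-swap descent (deterministic
#' given `seed`). Ties break on sorted donor id, so shuffling input rows
#' does not change the selection.
#'
#' @param donors eligible donor table.
#' @param covariates columns to balance on (default: age, BMI, sex,
#'   hypertension, diabetes).
#' @param group_size donors per core block (default 5).
#' @param seed integer seed for the greedy-swap initialisation.
#' @param include_extremes include all short/long-extreme donors (default
#'   TRUE).
#' @return object of class `cohort_definition`: selected donor ids, block
#'   assignment, the selected donor table, per-covariate one-way ANOVA
#'   balance statistics across blocks (continuous covariates), the audit of
#'   group sizes, and the seed.
#' @export
select_balanced <- function(donors,
                            covariates = c("age", "bmi", "sex",
                                           "hypertension", "diabetes"),
                            group_size = 5, seed = 1L,
                            include_extremes = TRUE) {
  miss <- setdiff(c("donor_id", "bd_duration", covariates), names(donors))
  if (length(miss))
    stop("donor table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  donors <- donors[order(donors$donor_id), , drop = FALSE]
  strata <- stratify_by_bd_blocks(donors)
  donors$block <- strata$block[match(donors$donor_id, strata$donor_id)]

  core <- core_blocks()
  n_by_block <- vapply(core, function(b) sum(donors$block == b), integer(1))
  deficient <- core[n_by_block < group_size]
  if (length(deficient))
    stop("infeasible group_size ", group_size, ": block(s) ",
         paste(deficient, collapse = ", "), " have fewer candidates",
         call. = FALSE)

  pool <- donors[donors$block %in% core, , drop = FALSE]
  targets <- covariate_targets(pool, covariates)

  selected <- character(0)
  for (b in core) {
    cand <- donors[donors$block == b, , drop = FALSE]
    n_b <- nrow(cand)
    if (n_b == group_size) {
      selected <- c(selected, cand$donor_id)
      next
    }
    if (n_b <= 8) {
      combos <- utils::combn(n_b, group_size)
      scores <- apply(combos, 2, function(ix)
        imbalance_score(cand[ix, , drop = FALSE], covariates, targets))
      best <- combos[, which.min(scores)]
    } else {
      best <- with_seed(seed + match(b, core), {
        cur <- sort(sample.int(n_b, group_size))
        cur_score <- imbalance_score(cand[cur, , drop = FALSE],
                                     covariates, targets)
        repeat {
          improved <- FALSE
          for (out_i in cur) {
            for (in_i in setdiff(seq_len(n_b), cur)) {
              trial <- sort(c(setdiff(cur, out_i), in_i))
              sc <- imbalance_score(cand[trial, , drop = FALSE],
                                    covariates, targets)
              if (sc < cur_score - 1e-12) {
                cur <- trial; cur_score <- sc; improved <- TRUE
                break  # restart the scan from the new subset
              }
            }
            if (improved) break
          }
          if (!improved) break
        }
        cur
      })
    }
    selected <- c(selected, cand$donor_id[best])
  }
  if (include_extremes)
    selected <- c(selected,
                  donors$donor_id[donors$block %in% c("short", "long")])

  sel <- donors[donors$donor_id %in% selected, , drop = FALSE]
  balance <- list()
  for (cv in covariates) {
    x <- sel[[cv]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      core_sel <- sel[sel$block %in% core, , drop = FALSE]
      balance[[cv]] <- tryCatch(
        balance_anova(core_sel[[cv]], core_sel$block),
        error = function(e) list(F = NA_real_, p = NA_real_))
    }
  }
  structure(
    list(selected_donor_ids = sort(sel$donor_id),
         block_assignment = data.frame(donor_id = sel$donor_id,
                                       block = sel$block,
                                       stringsAsFactors = FALSE),
         donors = sel,
         balance_stats = balance,
         group_sizes = table(factor(sel$block, levels = bd_block_levels())),
         group_size = group_size, covariates = covariates, seed = seed),
    class = "cohort_definition"
  )
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat("Balanced study cohort:", length(x$selected_donor_ids), "donors\n")
  print(x$group_sizes)
  if (length(x$balance_stats)) {
    cat("Balance (one-way ANOVA across core blocks):\n")
    for (cv in names(x$balance_stats))
      cat(sprintf("  %-14s F = %.3f, p = %.3f\n", cv,
                  x$balance_stats[[cv]]$F, x$balance_stats[[cv]]$p))
  }
  invisible(x)
}

#' One-way ANOVA balance check for a continuous covariate
#'
#' Fixed-effects one-way ANOVA of a covariate across cohort groups, used to
#' confirm that the block groups are balanced (a large p supports balance).
#'
#' @param x numeric covariate values.
#' @param g group labels (coerced to factor).
#' @return list with `F` and `p`.
#' @export
balance_anova <- function(x, g) {
  g <- factor(g)
  if (nlevels(droplevels(g)) < 2)
    stop("degenerate input: ANOVA needs at least two groups", call. = FALSE)
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (ssw == 0 || !is.finite(ssw))
    stop("degenerate input: zero within-group variance", call. = FALSE)
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Correlation between donor age and brain-death duration
#'
#' Pearson correlation, its square, and the two-sided p value for the
#' association between donor age and the duration of brain death — the
#' diagnostic used to detect the clinical anticorrelation whereby older
#' donors tend to have shorter donor-management periods.
#'
#' @param donors donor table with `age` and `bd_duration` columns.
#' @return list with `r`, `r_squared`, and `p`.
#' @export
age_bd_correlation <- function(donors) {
  ok <- stats::complete.cases(donors$age, donors$bd_duration)
  age <- donors$age[ok]; dur <- donors$bd_duration[ok]
  if (length(age) < 3)
    stop("need at least 3 donors with age and bd_duration", call. = FALSE)
  if (stats::sd(age) == 0 || stats::sd(dur) == 0)
    stop("zero variance in age or bd_duration", call. = FALSE)
  ct <- stats::cor.test(age, dur, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value)
}
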