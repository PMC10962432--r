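test_that("inclusion/exclusion applies criteria in order with an audit trail", {
  d <- toy_donors(10)
  d$consent[1:2] <- FALSE
  d$cause_of_death[3] <- "trauma"
  res <- apply_inclusion_exclusion(d)
  expect_equal(nrow(res$eligible), 7)
  expect_equal(res$audit$removed[res$audit$criterion == "consent"], 2L)
  expect_equal(res$audit$removed[res$audit$criterion == "cause_ich"], 1L)
  expect_equal(sum(res$audit$removed), 10 - nrow(res$eligible))
})

test_that("inclusion/exclusion is idempotent and handles empty tables", {
  d <- toy_donors(8)
  d$has_full_sample_set[5] <- FALSE
  once <- apply_inclusion_exclusion(d)
  twice <- apply_inclusion_exclusion(once$eligible)
  expect_identical(twice$eligible, once$eligible)
  expect_equal(sum(twice$audit$removed), 0L)

  empty <- apply_inclusion_exclusion(d[0, ])
  expect_equal(nrow(empty$eligible), 0)
  expect_true(all(empty$audit$removed == 0))
})

test_that("full-sample availability can be verified from the sample table", {
  p <- simulate_donor_panel(synthetic_config(n_donors = 4, seed = 11))
  s <- p$samples[!(p$samples$donor_id == "D002" &
                     p$samples$timepoint == "DB1"), ]
  res <- apply_inclusion_exclusion(p$donors, s)
  expect_false("D002" %in% res$eligible$donor_id)
  expect_equal(res$audit$removed[res$audit$criterion == "full_sample_set"], 1L)
})

test_that("criteria referencing absent columns are rejected", {
  d <- toy_donors(3)
  d$consent <- NULL
  expect_error(apply_inclusion_exclusion(d), "absent donor columns")
  expect_error(apply_inclusion_exclusion(toy_donors(3), criteria = "ph"),
               "unknown criteria")
})

test_that("5-hour blocks use half-open intervals with short/long extremes", {
  expect_equal(bd_block(c(7, 15.0, 29.99, 10, 30, 9.999, 33)),
               c("short", "15-20", "25-30", "10-15", "long", "short", "long"))
  expect_error(bd_block(c(12, NA)), "missing bd_duration")
  blocks <- stratify_by_bd_blocks(toy_donors(4, bd_duration = c(5, 12, 22, 40)))
  expect_equal(blocks$block, c("short", "10-15", "20-25", "long"))
})

test_that("block assignment partitions the eligible donors", {
  p <- simulate_donor_panel(synthetic_config(n_donors = 30, seed = 12,
                                             bd_duration_range = c(2, 40)))
  blocks <- stratify_by_bd_blocks(p$donors)
  expect_equal(sort(blocks$donor_id), sort(p$donors$donor_id))
  expect_true(all(blocks$block %in%
                    c("short", "10-15", "15-20", "20-25", "25-30", "long")))
})

test_that("balanced selection returns the designed cohort of 27", {
  p <- simulate_study_panel(seed = 13)
  sel <- select_balanced(p$donors, seed = 1)
  expect_s3_class(sel, "cohort_definition")
  expect_equal(length(sel$selected_donor_ids), 27)
  expect_equal(unname(as.vector(sel$group_sizes)), c(2, 5, 5, 5, 5, 5))
  # blocks partition the selected donors
  expect_equal(sort(sel$block_assignment$donor_id),
               sel$selected_donor_ids)
})

test_that("selection is deterministic and insensitive to input row order", {
  # 7 candidates per block: exhaustive search path
  p <- simulate_study_panel(seed = 14, group_size = 7)
  d <- p$donors
  s1 <- select_balanced(d, group_size = 5, seed = 3)
  s2 <- select_balanced(d[sample(nrow(d)), ], group_size = 5, seed = 3)
  expect_identical(s1$selected_donor_ids, s2$selected_donor_ids)

  # 10 candidates per block: greedy-swap path
  p2 <- simulate_study_panel(seed = 15, group_size = 10)
  g1 <- select_balanced(p2$donors, group_size = 5, seed = 3)
  g2 <- select_balanced(p2$donors[sample(nrow(p2$donors)), ],
                        group_size = 5, seed = 3)
  expect_identical(g1$selected_donor_ids, g2$selected_donor_ids)
  expect_equal(unname(as.vector(g1$group_sizes)), c(2, 5, 5, 5, 5, 5))
})

test_that("exhaustive search avoids the covariate-shifted donor when it can", {
  # per block: 6 candidates, one with a strongly shifted age
  set.seed(21)
  dur <- c(runif(6, 10, 15), runif(6, 15, 20), runif(6, 20, 25),
           runif(6, 25, 30))
  d <- toy_donors(24, bd_duration = dur,
                  age = rep(c(50, 51, 52, 49, 48, 90), 4))
  d$bmi <- rnorm(24, 27, 1)
  sel <- select_balanced(d, group_size = 5, seed = 1,
                         include_extremes = FALSE)
  shifted <- d$donor_id[d$age == 90]
  expect_length(intersect(sel$selected_donor_ids, shifted), 0)
})

test_that("infeasible group sizes name the deficient blocks", {
  d <- toy_donors(8, bd_duration = c(11, 12, 16, 17, 21, 22, 26, 27))
  expect_error(select_balanced(d, group_size = 5, seed = 1),
               "infeasible group_size")
})

test_that("one-way ANOVA balance matches the sum-of-squares oracle", {
  expect_equal(balance_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)),
               list(F = 0, p = 1), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    n <- sample(2:5, k, replace = TRUE)
    x <- rnorm(sum(n), mean = rep(rnorm(k, 0, 2), n))
    g <- rep(letters[1:k], n)
    got <- balance_anova(x, g)
    want <- oracle_anova(x, g)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("ANOVA separates jittered extreme groups and rejects degenerate input", {
  set.seed(32)
  x <- c(rnorm(3, 0, 1e-3), rnorm(3, 10, 1e-3))
  g <- rep(c("lo", "hi"), each = 3)
  expect_lt(balance_anova(x, g)$p, 0.001)
  expect_error(balance_anova(1:5, rep("a", 5)), "two groups")
  expect_error(balance_anova(rep(1, 6), rep(c("a", "b"), 3)),
               "zero within-group variance")
})

test_that("age/BD-duration correlation recovers r, R-squared and p", {
  d <- toy_donors(3, bd_duration = c(30, 20, 10), age = c(30, 40, 50))
  res <- age_bd_correlation(d)
  expect_equal(res$r, -1)
  expect_equal(res$r_squared, 1)
  expect_error(age_bd_correlation(
    toy_donors(3, bd_duration = c(10, 10, 10), age = c(30, 40, 50))),
    "zero variance")

  # generator plants the anticorrelation; the estimate should land inside
  # the Fisher CI of the target in most draws
  hits <- 0
  for (i in 1:20) {
    p <- simulate_donor_panel(synthetic_config(n_donors = 24, seed = 600 + i))
    r <- age_bd_correlation(p$donors)$r
    z <- atanh(r); zt <- atanh(-0.57); se <- 1 / sqrt(24 - 3)
    hits <- hits + (abs(z - zt) <= 1.96 * se)
  }
  expect_gte(hits, 17)
})
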