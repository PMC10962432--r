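test_that("alignment anchors DB2 at exactly zero and propagates flags", {
  p <- simulate_donor_panel(synthetic_config(n_donors = 6, seed = 51))
  s <- align_to_bd(p$samples, p$donors)
  expect_true(all(s$t_rel[s$timepoint == "DB2"] == 0))
  i <- which(s$timepoint == "DB3")[1]
  d <- match(s$donor_id[i], p$donors$donor_id)
  expect_equal(s$t_rel[i], s$t_sample[i] - p$donors$t_bd_confirm[d])
  expect_true("db1_time_imputed" %in% names(s))

  no_anchor <- p$samples[p$samples$timepoint != "DB2" |
                           p$samples$donor_id != "D003", ]
  expect_error(align_to_bd(no_anchor, p$donors), "without a DB2 anchor")
  expect_error(align_to_bd(p$samples, p$donors[-1, ]), "absent from the donor")
})

test_that("a hand-checked pre-event window reproduces its median", {
  s <- data.frame(donor_id = c("a", "b", "c", "d"), marker = "M",
                  t_rel = c(-15, -5, -1, 8), log_level = c(2, 4, 6, 1))
  s <- rbind(s, data.frame(donor_id = "e", marker = "M", t_rel = 0,
                           log_level = 3))
  fit <- bd_timecourse(s, min_window_n = 1)
  co <- fit$courses$M
  # at t = -10 the 20-h window holds the three pre samples {2, 4, 6}
  expect_equal(co$median[co$t == -10], 4)
  expect_equal(co$n[co$t == -10], 3L)
  # even-count window: midpoint of the two central order statistics
  expect_equal(co$median[co$t == -3], (4 + 6) / 2)
  expect_equal(fit$value_at_zero[["M"]], 3)
})

test_that("constant data yield a constant time course wherever defined", {
  s <- data.frame(donor_id = sprintf("d%d", 1:9), marker = "M",
                  t_rel = c(-12, -6, -2, 0, 0, 0, 5, 14, 25),
                  log_level = 2.5)
  fit <- bd_timecourse(s, min_window_n = 1)
  med <- fit$courses$M$median
  expect_true(all(med[!is.na(med)] == 2.5))
})

test_that("moving median equals the brute-force oracle on random fixtures", {
  set.seed(52)
  for (i in 1:200) {
    s <- random_aligned_fixture(n_donors = 30)
    w <- sample(c(10, 20, 26), 1)
    fit <- bd_timecourse(s, window_width = w, min_window_n = 1)
    co <- fit$courses$M
    for (j in seq_len(nrow(co))) {
      want <- oracle_window_median(s$t_rel, s$log_level, co$t[j], w)
      expect_identical(co$n[j], as.integer(want$n))
      if (want$n == 0) expect_true(is.na(co$median[j]))
      else expect_equal(co$median[j], want$median, tolerance = 1e-12)
    }
  }
})

test_that("window occupancy gating reports sparse stretches as undefined", {
  set.seed(53)
  s <- random_aligned_fixture(n_donors = 12)
  fit <- bd_timecourse(s, min_window_n = 3)
  co <- fit$courses$M
  sparse <- co$n < 3 & co$t != 0
  expect_true(all(is.na(co$median[sparse])))
  expect_true(all(!is.na(co$median[!sparse & (co$n > 0 | co$t == 0)]) |
                    co$t[!sparse] == 0))
  # t = 0 is exempt from the occupancy minimum
  expect_false(is.na(co$median[co$t == 0]))
})

test_that("pre- and post-event segments are strictly isolated", {
  set.seed(54)
  for (i in 1:100) {
    s <- random_aligned_fixture(n_donors = 15)
    fit <- bd_timecourse(s, min_window_n = 1)
    pre0 <- fit$courses$M$median[fit$courses$M$t < 0]
    zero0 <- fit$value_at_zero[["M"]]
    post0 <- fit$courses$M$median[fit$courses$M$t > 0]

    s_post <- s
    ip <- s_post$t_rel > 0
    s_post$log_level[ip] <- s_post$log_level[ip] + rnorm(sum(ip), 0, 50)
    fit2 <- bd_timecourse(s_post, min_window_n = 1)
    expect_identical(fit2$courses$M$median[fit2$courses$M$t < 0], pre0)
    expect_identical(fit2$value_at_zero[["M"]], zero0)

    s_pre <- s
    in_ <- s_pre$t_rel < 0
    s_pre$log_level[in_] <- s_pre$log_level[in_] + rnorm(sum(in_), 0, 50)
    fit3 <- bd_timecourse(s_pre, min_window_n = 1)
    expect_identical(fit3$courses$M$median[fit3$courses$M$t > 0], post0)
    expect_identical(fit3$value_at_zero[["M"]], zero0)
  }
})

test_that("samples at exactly t = 0 never enter pre or post windows", {
  s <- data.frame(donor_id = sprintf("d%d", 1:7), marker = "M",
                  t_rel = c(-9, -3, 0, 0, 0, 4, 9),
                  log_level = c(1, 1, 100, 100, 100, 1, 1))
  fit <- bd_timecourse(s, min_window_n = 1)
  co <- fit$courses$M
  expect_true(all(co$median[co$t != 0] == 1, na.rm = TRUE))
  expect_equal(co$median[co$t == 0], 100)
})

test_that("a single wild value moves a window median by at most one order-statistic gap", {
  set.seed(55)
  s <- random_aligned_fixture(n_donors = 20)
  fit <- bd_timecourse(s, min_window_n = 1)
  co <- fit$courses$M
  idx <- sample(which(s$t_rel < 0), 1)
  s2 <- s
  s2$log_level[idx] <- 1e9
  co2 <- bd_timecourse(s2, min_window_n = 1)$courses$M
  for (j in which(co$t < 0 & co$n >= 2)) {
    inw <- s$t_rel < 0 & abs(s$t_rel - co$t[j]) <= 10
    gap <- max(diff(sort(s$log_level[inw])))
    expect_lte(abs(co2$median[j] - co$median[j]), gap + 1e-9)
  }
})

test_that("the moving median of a monotone noiseless trajectory is monotone", {
  cfg <- synthetic_config(
    n_donors = 24, noise_sd = 0, donor_effect_sd = 0, duplicate_cv = 0,
    marker_shapes = list(M = shape_params("decline", baseline = 4,
                                          slope_pre = -0.05)),
    seed = 56)
  p <- simulate_donor_panel(cfg)
  s <- align_to_bd(preprocess_samples(p$samples), p$donors)
  co <- bd_timecourse(s)$courses$M
  def <- co[!is.na(co$median), ]
  for (side in split(def, def$t >= 0))
    expect_true(all(diff(side$median) <= 1e-9))
})

test_that("trailing post-event windows exclude later samples", {
  s <- data.frame(donor_id = sprintf("d%d", 1:5), marker = "M",
                  t_rel = c(-5, 0, 2, 10, 18), log_level = c(1, 1, 2, 4, 8))
  fit_c <- bd_timecourse(s, min_window_n = 1, post_window = "centered")
  fit_t <- bd_timecourse(s, min_window_n = 1, post_window = "trailing")
  # at t = 5: centered window [-5,15] holds {2,4}; trailing [-15,5] holds {2}
  expect_equal(fit_c$courses$M$median[fit_c$courses$M$t == 5], 3)
  expect_equal(fit_t$courses$M$median[fit_t$courses$M$t == 5], 2)
})

test_that("empty segments are rejected naming the segment", {
  s <- data.frame(donor_id = c("a", "b"), marker = "M",
                  t_rel = c(-3, 0), log_level = c(1, 2))
  expect_error(bd_timecourse(s), "post")
})

test_that("model methods: print, summary, predict, fitted, residuals", {
  p <- simulate_donor_panel(synthetic_config(n_donors = 24, seed = 57))
  s <- align_to_bd(preprocess_samples(p$samples), p$donors)
  fit <- bd_timecourse(s)
  expect_output(print(fit), "moving-median")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.bd_timecourse")
  expect_output(print(sm), "trend")
  expect_setequal(sm$table$marker, unique(s$marker))

  pr <- predict(fit, c(-10, 0, 10), marker = "GFAP")
  expect_length(pr, 3)
  expect_equal(pr[2], fit$value_at_zero[["GFAP"]])
  expect_error(predict(fit, 0, marker = "nope"), "unknown marker")

  res <- residuals(fit)
  expect_length(res, nrow(s))
  expect_equal(res, s$log_level - fitted(fit))
})

test_that("trend classification recovers the generator's shapes", {
  truth <- marker_truth_labels()
  # noiseless: exact labels
  cfg0 <- synthetic_config(n_donors = 24, noise_sd = 0, donor_effect_sd = 0,
                           duplicate_cv = 0, seed = 58)
  p0 <- simulate_donor_panel(cfg0)
  s0 <- align_to_bd(preprocess_samples(p0$samples), p0$donors)
  expect_identical(classify_trend(bd_timecourse(s0))[names(truth)], truth)

  # flat constant marker, zero noise
  cfgc <- synthetic_config(
    n_donors = 24, noise_sd = 0, donor_effect_sd = 0, duplicate_cv = 0,
    marker_shapes = list(M = shape_params("constant", baseline = 3)),
    seed = 59)
  pc <- simulate_donor_panel(cfgc)
  sc <- align_to_bd(preprocess_samples(pc$samples), pc$donors)
  expect_identical(unname(classify_trend(bd_timecourse(sc))),
                   "constant_elevated")
})

test_that("classification requires enough defined grid points", {
  s <- data.frame(donor_id = sprintf("d%d", 1:5), marker = "M",
                  t_rel = c(-5, -4, 0, 3, 4), log_level = 1:5)
  fit <- bd_timecourse(s, min_window_n = 5)
  expect_error(classify_trend(fit), "insufficient defined grid points")
})
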