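test_that("label distributions reproduce published-style percentage cells", {
  # single-worker task: 4220/283/1071 of 5574
  d1 <- label_distribution(rep(c("TRUE", "FALSE", "EXCLUDE"),
                               c(4220, 283, 1071)))
  expect_equal(c(d1$pct_true, d1$pct_false, d1$pct_excluded),
               c(75.71, 5.08, 19.21))
  expect_equal(d1$n_kept, 4503)
  expect_equal(d1$pct_kept, 80.79)

  # expert-reviewed task: 1281/343/765 of 2389
  d2 <- label_distribution(rep(c("TRUE", "FALSE", "EXCLUDE"),
                               c(1281, 343, 765)))
  expect_equal(c(d2$pct_true, d2$pct_false, d2$pct_excluded),
               c(53.62, 14.36, 32.02))
  expect_equal(d2$n_kept, 1624)
  expect_equal(d2$pct_kept, 67.98)

  all_excluded <- label_distribution(rep("EXCLUDE", 10))
  expect_equal(c(all_excluded$pct_true, all_excluded$pct_false,
                 all_excluded$pct_excluded), c(0, 0, 100))

  expect_error(label_distribution(rep("TRUE", 5), original_total = 4),
               "exceed")
})

test_that("distribution percentages always sum to 100 within rounding slack", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(50:5000, 1)
    labels <- sample(c("TRUE", "FALSE", "EXCLUDE"), n, replace = TRUE,
                     prob = runif(3))
    d <- label_distribution(labels)
    expect_lte(abs(d$pct_true + d$pct_false + d$pct_excluded - 100), 0.02)
  }
})

test_that("campaign cost reproduces the published totals in exact cents", {
  expect_equal(cost_total(cost_config(5574, 1, reward = 0.02,
                                      base_fee = 0.01)), 167.22)
  expect_equal(cost_total(cost_config(2389, 7, reward = 0.02,
                                      base_fee = 0.01)), 501.69)
  expect_equal(cost_total(cost_config(0, 7)), 0)

  # Masters surcharge is absorbed by the cent rounding of the billed fee
  with_sur <- cost_total(cost_config(5574, 1, reward = 0.02, base_fee = 0.01,
                                     masters_surcharge = 0.001))
  without <- cost_total(cost_config(5574, 1, reward = 0.02, base_fee = 0.01,
                                    masters_surcharge = 0))
  expect_equal(with_sur, without)
  # ...but pushes a sub-cent base fee up to the next cent
  expect_equal(cost_total(cost_config(100, 1, reward = 0.02,
                                      base_fee = 0.004,
                                      masters_surcharge = 0.001)), 3)
})

test_that("cost is linear in tasks and in assignments", {
  base <- cost_total(cost_config(100, 1))
  expect_equal(cost_total(cost_config(300, 1)), 3 * base)
  expect_equal(cost_total(cost_config(100, 5)), 5 * base)
})

test_that("worker summary counts workers, assignments and missing ids", {
  # 22,255 assignments spread over 64 workers
  votes <- vote_set(tibble::tibble(
    relation_id = sprintf("r%05d", 1:22255),
    worker_id = sprintf("w%02d", rep_len(1:64, 22255)),
    answer = "TRUE",
    work_time = 10,
    rater_source = "CROWD"
  ))
  s <- worker_summary(votes)
  expect_equal(s$n_workers, 64)
  expect_equal(s$n_assignments, 22255)
  expect_equal(s$assignments_per_worker, 348)

  single <- worker_summary(vote_set(tibble::tibble(
    relation_id = "r1", worker_id = "w1", answer = "TRUE",
    work_time = 10, rater_source = "CROWD"
  )))
  expect_equal(single$time_mean, 10)
  expect_equal(single$n_under_cutoff, 1)

  missing <- vote_set(tibble::tibble(
    relation_id = c("r1", "r2"), worker_id = c("w1", NA),
    answer = "TRUE", work_time = c(10, 20), rater_source = "CROWD"
  ), strict = FALSE)
  expect_equal(worker_summary(missing)$n_missing_worker_id, 1)

  unattributed <- vote_set(tibble::tibble(
    relation_id = "r1", worker_id = NA_character_, answer = "TRUE",
    work_time = 1, rater_source = "CROWD"
  ), strict = FALSE)
  expect_error(worker_summary(unattributed), "no attributed workers")
})

test_that("time statistics under the cutoff match the truncated-distribution oracle", {
  pool <- lapply(1:10, function(i) {
    worker_profile(sprintf("w%02d", i), accuracy = 0.8, break_prob = 0)
  })
  camp <- sample_campaign(
    campaign_config(n_items = 3000, n_workers = 10, assignments_per_item = 7,
                    seed = 31),
    profiles = pool
  )
  s <- worker_summary(camp$votes, cutoff = 50)
  truncated <- oracle_truncated_lnorm_mean(2.4, 0.6, 50)
  expect_lte(abs(s$time_mean - truncated) / truncated, 0.05)
  expect_equal(sum(s$histogram), s$n_under_cutoff)
  # module consistency: summarising filtered votes gives the same time stats
  filtered <- worker_summary(filter_by_time(camp$votes, 50), cutoff = 50)
  expect_equal(filtered$time_mean, s$time_mean)
  expect_equal(filtered$n_under_cutoff, s$n_under_cutoff)
})

test_that("the class-weight multiplier is the true:false ratio", {
  expect_equal(class_weight_multiplier(4220, 283), 14.9)
  expect_equal(class_weight_multiplier(100, 100), 1.0)
  expect_equal(class_weight_multiplier(100, 25), 4.0)
  expect_equal(class_weight_multiplier(100, 30, digits = NULL), 10 / 3)
  expect_error(class_weight_multiplier(10, 0), "positive")
})

test_that("F-measure aggregation reproduces the published averages and delta", {
  scores <- deep_learning_scores()
  expect_equal(nrow(scores), 12)
  agg <- fmeasure_aggregation(scores, baseline_tag = "original")
  expect_equal(agg$avg_other, 0.8179)
  expect_equal(agg$avg_baseline, 0.4685)
  expect_equal(agg$delta, 0.3494)

  same <- tibble::tibble(method = "m", experiment = c("base", "x", "y"),
                         fmeasure = 0.5)
  agg0 <- fmeasure_aggregation(same, "base")
  expect_equal(agg0$delta, 0)

  two <- tibble::tibble(method = "m", experiment = c("base", "x"),
                        fmeasure = c(0.4, 0.9))
  expect_equal(fmeasure_aggregation(two, "base")$delta, 0.5)
  expect_error(fmeasure_aggregation(two, "nope"), "baseline")
})

test_that("half-up rounding breaks ties upward at every scale", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(347.734375), 348)
  expect_equal(round_half_up(19.214567, 2), 19.21)
})
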